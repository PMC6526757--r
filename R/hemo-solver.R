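#' Poiseuille hydraulic resistance of a cylindrical lumen
#'
#' R = 128 mu L / (pi d^4), converted to mmHg.s/mL.
#'
#' @param length_mm Lumen length in mm.
#' @param diameter_mm Lumen diameter in mm.
#' @param mu Dynamic viscosity in Pa.s.
#' @return Resistance in mmHg.s/mL.
#' @export
poiseuille_resistance <- function(length_mm, diameter_mm, mu) {
  r_si <- 128 * mu * (length_mm * .M_PER_MM) / (pi * (diameter_mm * .M_PER_MM)^4)
  r_si * .R_SI_TO_MMHG_ML
}

#' Hydraulic resistance of a tree segment
#'
#' Poiseuille resistance evaluated at the segment's mean diameter — the 0D
#' surrogate for the 3D viscous loss of a mildly tapering vessel.
#'
#' @param segment A single segment row (or list) with `length_mm`,
#'   `d_prox_mm`, `d_dist_mm`.
#' @param mu Dynamic viscosity in Pa.s.
#' @return Resistance in mmHg.s/mL.
#' @export
segment_resistance <- function(segment, mu) {
  d_mean <- (segment$d_prox_mm + segment$d_dist_mm) / 2
  poiseuille_resistance(segment$length_mm, d_mean, mu)
}

#' Lesion geometry
#'
#' An axisymmetric virtual stenosis anchored at a fractional position of a
#' segment. Severity is percent diameter reduction relative to the local
#' healthy (linearly interpolated) diameter.
#'
#' @param site_segment_id Segment carrying the lesion.
#' @param position Fraction in \[0, 1\] from the proximal end.
#' @param severity_pct Percent diameter reduction in \[0, 100).
#' @param lesion_length_mm Lesion length in mm (must not exceed the segment
#'   length).
#' @param d_reference_mm Local healthy diameter at the site, mm.
#' @return A `lesion_geometry` object; `d_min_mm = d_reference_mm *
#'   (1 - severity_pct/100)`.
#' @export
lesion_geometry <- function(site_segment_id, position, severity_pct,
                            lesion_length_mm, d_reference_mm) {
  if (severity_pct < 0 || severity_pct >= 100)
    stop("invalid lesion: severity_pct must be in [0, 100)")
  stopifnot(position >= 0, position <= 1, lesion_length_mm > 0,
            d_reference_mm > 0)
  structure(list(site_segment_id = site_segment_id, position = position,
                 severity_pct = severity_pct,
                 lesion_length_mm = lesion_length_mm,
                 d_reference_mm = d_reference_mm,
                 d_min_mm = d_reference_mm * (1 - severity_pct / 100)),
            class = "lesion_geometry")
}

# Linear and quadratic loss coefficients of a lesion:
#   dP [mmHg] = R_visc * q + b * q * |q|,  q in mL/s.
# Viscous part: Young-type K_v = 32 (L/d_ref) (A_ref/A_min)^2 applied to the
# mean reference-area velocity, which reduces algebraically to
# (d_ref/d_min)^4 times the Poiseuille resistance of the lesion length at
# d_ref — exact Poiseuille at severity 0. Turbulent/expansion part:
# K_t (rho/2) (A_ref/A_min - 1)^2 V |V| with empirical K_t.
.lesion_coefficients <- function(lesion, params, kt = 1.52) {
  area_ratio <- (lesion$d_reference_mm / lesion$d_min_mm)^2
  r_visc <- area_ratio^2 *
    poiseuille_resistance(lesion$lesion_length_mm, lesion$d_reference_mm,
                          params$mu)
  a_ref <- pi * (lesion$d_reference_mm * .M_PER_MM)^2 / 4
  b_si <- kt * (params$rho / 2) * (area_ratio - 1)^2 / a_ref^2
  b <- b_si * .M3_PER_ML^2 / .PA_PER_MMHG
  list(r_visc = r_visc, b = b)
}

#' Pressure drop across a virtual stenosis
#'
#' Reduced-order lesion loss with a viscous term and an empirical
#' turbulent/expansion term:
#' \deqn{\Delta P = K_v (\mu/d) V + K_t (\rho/2) (A_{ref}/A_{min} - 1)^2 V |V|}
#' with V the mean velocity at the reference area,
#' K_v = 32 (L/d)(A_ref/A_min)^2 and K_t = 1.52. At severity 0 this reduces
#' exactly to the Poiseuille drop of the lesion length.
#'
#' @param lesion A `lesion_geometry`.
#' @param q Flow in mL/s (sign = direction).
#' @param params A `perfusion_params` (viscosity, density).
#' @param kt Empirical turbulent loss coefficient (default 1.52).
#' @return Pressure drop in mmHg (same sign as `q`).
#' @export
stenosis_pressure_drop <- function(lesion, q, params, kt = 1.52) {
  cf <- .lesion_coefficients(lesion, params, kt = kt)
  cf$r_visc * q + cf$b * q * abs(q)
}

# invert dP = R q + b q|q| for q (closed form, monotone branch)
.flow_from_dp <- function(dp, r, b) {
  if (b <= 0) return(dp / r)
  sign(dp) * (-r + sqrt(r^2 + 4 * b * abs(dp))) / (2 * b)
}

# Build the per-segment network table used by the solver: linear resistance
# (with any lesion's baseline Poiseuille portion swapped for its viscous
# coefficient) and quadratic coefficient b.
.network_elements <- function(tree, lesions, params, kt = 1.52) {
  s <- tree$segments
  r_lin <- vapply(seq_len(nrow(s)), function(i)
    segment_resistance(s[i, ], params$mu), numeric(1))
  b <- numeric(nrow(s))
  for (les in lesions) {
    i <- match(les$site_segment_id, s$id)
    if (is.na(i)) stop("lesion site segment not in tree: ", les$site_segment_id)
    if (les$lesion_length_mm > s$length_mm[i])
      stop("invalid lesion: lesion_length exceeds segment length on '",
           s$id[i], "'")
    cf <- .lesion_coefficients(les, params, kt = kt)
    baseline <- poiseuille_resistance(les$lesion_length_mm,
                                      les$d_reference_mm, params$mu)
    r_lin[i] <- max(r_lin[i] - baseline, 0) + cf$r_visc
    b[i] <- b[i] + cf$b
  }
  list(ids = s$id, parent = s$parent_id, r_lin = r_lin, b = b)
}

#' Steady-state 0D network solve
#'
#' Solves nodal pressures of the coronary network under a steady inlet
#' pressure: Poiseuille losses along segments, a quadratic Young-type loss
#' at each lesion, and lumped resistive outlets to the venous reference at
#' every terminal segment. Mass is conserved at every junction. The
#' nonlinear system is solved by damped Newton iteration on the distal
#' nodal pressures (analytic Jacobian, damping halved while the residual
#' increases); collateral switches are re-evaluated every iteration.
#'
#' @param tree A `coronary_tree`.
#' @param outlets `outlet_boundaries` from [distribute_to_outlets()].
#' @param lesions List of `lesion_geometry` objects (possibly empty).
#' @param inlet_pressure Inlet (aortic) pressure, mmHg, applied identically
#'   at each artery root.
#' @param params A `perfusion_params`.
#' @param tol Convergence tolerance on the maximum junction flow residual,
#'   relative to max(1, total outlet flow); default 1e-10.
#' @param max_iter Maximum Newton iterations (default 100).
#' @return A `flow_state`: named `node_pressures` (distal pressure of each
#'   segment, mmHg), named `segment_flows` (mL/s), `inlet_pressure`,
#'   `venous_pressure`, `time`, `iterations`, `residual` (max junction
#'   imbalance, mL/s).
#' @export
solve_steady <- function(tree, outlets, lesions = list(), inlet_pressure,
                         params, tol = 1e-10, max_iter = 100) {
  if (inherits(lesions, "lesion_geometry")) lesions <- list(lesions)
  s <- tree$segments
  n <- nrow(s)
  if (n == 0) stop("degenerate network: tree has no segments")
  if (all(!is.finite(outlets$resistance)))
    stop("degenerate network: all outlet resistances are infinite")
  el <- .network_elements(tree, lesions, params)
  idx <- stats::setNames(seq_len(n), s$id)
  parent_idx <- ifelse(is.na(el$parent), 0L, idx[el$parent])
  children <- lapply(seq_len(n), function(i) which(parent_idx == i))
  out_row <- match(s$id, outlets$outlet_segment_id)
  pv <- params$venous_pressure

  seg_flows <- function(x) {
    pp <- ifelse(parent_idx == 0L, inlet_pressure, x[pmax(parent_idx, 1L)])
    vapply(seq_len(n), function(i)
      .flow_from_dp(pp[i] - x[i], el$r_lin[i], el$b[i]), numeric(1))
  }
  outlet_g <- function(x) {
    g <- numeric(n)
    for (i in which(!is.na(out_row))) {
      r_eff <- collateral_adjust(outlets[out_row[i], ], x[i])
      g[i] <- if (is.finite(r_eff)) 1 / r_eff else 0
    }
    g
  }
  residual <- function(x, q, g) {
    vapply(seq_len(n), function(i)
      q[i] - sum(q[children[[i]]]) - g[i] * (x[i] - pv), numeric(1))
  }

  x <- rep(inlet_pressure, n)
  lambda <- 1
  q <- seg_flows(x); g <- outlet_g(x)
  f <- residual(x, q, g)
  res <- max(abs(f))
  iter <- 0L
  repeat {
    scale <- max(1, sum(abs(g * (x - pv))))
    if (res < tol * scale || iter >= max_iter) break
    iter <- iter + 1L
    # analytic Jacobian: dq/d(dP) = 1 / (r + 2 b |q|)
    dq <- 1 / (el$r_lin + 2 * el$b * abs(q))
    jac <- matrix(0, n, n)
    for (i in seq_len(n)) {
      jac[i, i] <- -dq[i] - g[i]
      if (parent_idx[i] > 0L) jac[i, parent_idx[i]] <- dq[i]
      for (c in children[[i]]) {
        jac[i, c] <- jac[i, c] + dq[c]
        jac[i, i] <- jac[i, i] - dq[c]
      }
    }
    step <- solve(jac, -f)
    lambda <- 1
    repeat {
      x_new <- x + lambda * step
      q_new <- seg_flows(x_new); g_new <- outlet_g(x_new)
      f_new <- residual(x_new, q_new, g_new)
      if (max(abs(f_new)) <= res || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    x <- x_new; q <- q_new; g <- g_new; f <- f_new
    res <- max(abs(f))
  }
  scale <- max(1, sum(abs(g * (x - pv))))
  if (res >= tol * scale)
    stop(sprintf("solver did not converge in %d iterations (residual %.3e mL/s)",
                 max_iter, res))
  structure(list(node_pressures = stats::setNames(x, s$id),
                 segment_flows = stats::setNames(q, s$id),
                 inlet_pressure = inlet_pressure, venous_pressure = pv,
                 time = 0, iterations = iter, residual = res),
            class = "flow_state")
}

#' @export
print.flow_state <- function(x, ...) {
  cat(sprintf("flow_state: %d nodes, inlet %.4g mmHg\n",
              length(x$node_pressures), x$inlet_pressure))
  cat(sprintf("  converged in %d iteration(s), residual %.2e mL/s\n",
              x$iterations, x$residual))
  invisible(x)
}

#' Quasi-static pulsatile solve over an inlet pressure waveform
#'
#' The network is purely resistive (no compliance or inertance), so the
#' pulsatile response is a sequence of steady solves, one per waveform
#' sample. Cycle averages of pressures and flows are computed by the sample
#' mean over one period.
#'
#' @inheritParams solve_steady
#' @param waveform An `inlet_waveform` from [generate_waveform()] (periodic,
#'   at least 32 samples per cycle).
#' @return A `pulsatile_result`: list of per-sample `flow_state`s plus
#'   `mean_pressures`, `mean_flows`, `mean_inlet_pressure`.
#' @export
solve_pulsatile <- function(tree, outlets, lesions = list(), waveform,
                            params, tol = 1e-10, max_iter = 100) {
  stopifnot(inherits(waveform, "inlet_waveform"))
  if (length(waveform$pressure) < 32)
    stop("waveform must have at least 32 samples per cycle")
  states <- lapply(seq_along(waveform$pressure), function(i) {
    st <- solve_steady(tree, outlets, lesions, waveform$pressure[i], params,
                       tol = tol, max_iter = max_iter)
    st$time <- waveform$time[i]
    st
  })
  p_mat <- do.call(rbind, lapply(states, `[[`, "node_pressures"))
  q_mat <- do.call(rbind, lapply(states, `[[`, "segment_flows"))
  structure(list(states = states,
                 mean_pressures = colMeans(p_mat),
                 mean_flows = colMeans(q_mat),
                 mean_inlet_pressure = mean(waveform$pressure),
                 venous_pressure = params$venous_pressure),
            class = "pulsatile_result")
}

#' Maximum wall shear stress at a lesion throat
#'
#' Poiseuille wall shear evaluated at the minimal lumen:
#' WSSmax = 32 mu |q| / (pi d_min^3), in Pa. For a lesion-free site use the
#' local diameter as `d_min`.
#'
#' @param lesion A `lesion_geometry`, or a numeric diameter in mm.
#' @param q Flow through the lesion, mL/s.
#' @param mu Dynamic viscosity, Pa.s.
#' @return WSSmax in Pa (multiply by 10 for dyn/cm^2, see [pa_to_dyn_cm2()]).
#' @export
compute_wss_max <- function(lesion, q, mu) {
  d_mm <- if (inherits(lesion, "lesion_geometry")) lesion$d_min_mm
          else as.numeric(lesion)
  32 * mu * abs(q * .M3_PER_ML) / (pi * (d_mm * .M_PER_MM)^3)
}

#' Fractional flow reserve at a site
#'
#' FFR = (P_distal - P_venous) / (P_inlet - P_venous), taken at the node
#' just distal to the lesion (the distal node of the site's segment). For a
#' pulsatile result the ratio of cycle-averaged pressures is used.
#'
#' @param state A `flow_state` or `pulsatile_result`.
#' @param site_segment_id Segment id whose distal node defines P_distal.
#' @return FFR, dimensionless in (0, 1\].
#' @export
compute_ffr <- function(state, site_segment_id) {
  if (inherits(state, "pulsatile_result")) {
    p <- state$mean_pressures
    pin <- state$mean_inlet_pressure
    pv <- state$venous_pressure
  } else {
    p <- state$node_pressures
    pin <- state$inlet_pressure
    pv <- state$venous_pressure
  }
  if (!site_segment_id %in% names(p))
    stop("unknown site segment id: ", site_segment_id)
  unname((p[site_segment_id] - pv) / (pin - pv))
}
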