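# Independent brute-force reference solver for the 0D network equations.
# Everything here is coded from the physical definitions, without reusing
# the package's solver internals: Poiseuille resistances and lesion losses
# are rebuilt from first principles, the per-segment flow is inverted from
# the pressure drop by bisection (uniroot), and the nodal system is solved
# by a generic root-finder (pracma::fsolve).

oracle_pois_r <- function(length_mm, d_mm, mu) {
  # Pa.s/m^3, then mmHg.s/mL
  (128 * mu * (length_mm / 1000)) / (pi * (d_mm / 1000)^4) / 133.322 / 1e6
}

# total pressure drop over a segment (with optional lesion) at flow q mL/s
oracle_segment_dp <- function(seg, lesion, q, mu, rho, kt = 1.52) {
  d_mean <- (seg$d_prox_mm + seg$d_dist_mm) / 2
  dp <- oracle_pois_r(seg$length_mm, d_mean, mu) * q
  if (!is.null(lesion)) {
    dp <- dp - oracle_pois_r(lesion$lesion_length_mm, lesion$d_reference_mm, mu) * q
    d_ref <- lesion$d_reference_mm / 1000
    d_min <- lesion$d_min_mm / 1000
    a_ref <- pi * d_ref^2 / 4
    a_min <- pi * d_min^2 / 4
    v <- (q * 1e-6) / a_ref
    kv <- 32 * (lesion$lesion_length_mm / 1000 / d_ref) * (a_ref / a_min)^2
    dp_pa <- kv * (mu / d_ref) * v +
      kt * (rho / 2) * (a_ref / a_min - 1)^2 * v * abs(v)
    dp <- dp + dp_pa / 133.322
  }
  dp
}

oracle_flow_from_dp <- function(seg, lesion, dp, mu, rho) {
  if (dp == 0) return(0)
  f <- function(q) oracle_segment_dp(seg, lesion, q, mu, rho) - dp
  stats::uniroot(f, c(-1e4, 1e4), tol = 1e-14, maxiter = 2000)$root
}

# Solve the lesioned network with a generic nonlinear root-finder on the
# junction balance equations; returns distal nodal pressures named by id.
oracle_solve <- function(tree, outlets, lesions, inlet_pressure, params) {
  s <- tree$segments
  n <- nrow(s)
  lesion_of <- stats::setNames(vector("list", n), s$id)
  for (les in lesions) lesion_of[[les$site_segment_id]] <- les
  pv <- params$venous_pressure
  balance <- function(x) {
    names(x) <- s$id
    vapply(seq_len(n), function(i) {
      id <- s$id[i]
      pp <- if (is.na(s$parent_id[i])) inlet_pressure else x[[s$parent_id[i]]]
      q_in <- oracle_flow_from_dp(s[i, ], lesion_of[[id]], pp - x[[id]],
                                  params$mu, params$rho)
      kids <- s$id[!is.na(s$parent_id) & s$parent_id == id]
      q_kids <- sum(vapply(kids, function(k) {
        ki <- match(k, s$id)
        oracle_flow_from_dp(s[ki, ], lesion_of[[k]], x[[id]] - x[[k]],
                            params$mu, params$rho)
      }, numeric(1)), 0)
      q_out <- 0
      j <- match(id, outlets$outlet_segment_id)
      if (!is.na(j) && is.finite(outlets$resistance[j]))
        q_out <- (x[[id]] - pv) / outlets$resistance[j]
      q_in - q_kids - q_out
    }, numeric(1))
  }
  x0 <- rep(inlet_pressure * 0.95, n)
  sol <- pracma::fsolve(balance, x0, tol = 1e-13)
  stats::setNames(sol$x, s$id)
}

# brute-force OLS slope: covariance over variance
oracle_ols_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}
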