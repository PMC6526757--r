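#' Physiologic perfusion parameters
#'
#' Bundles the hemodynamic constants of the lumped-parameter outlet model.
#' `delta_P` is the aorta-to-coronary-vein pressure difference and `Q_total`
#' the total hyperemic coronary flow; together with the summed qualifying
#' vessel lengths they fix the proportionality constant `k` of the
#' length-based resistance allocation. `alpha` (> 1) down-weights the
#' influence of RV-feeding RCA length on RCA flow; its default 3.45 is a
#' typical LV-to-RV muscle volume ratio.
#'
#' @param delta_P Aorta-to-vein pressure difference, mmHg (default 90).
#' @param Q_total Total hyperemic coronary flow, mL/s (default 14).
#' @param alpha RV-length down-weighting constant, dimensionless > 1
#'   (default 3.45).
#' @param mu Blood dynamic viscosity, Pa.s (default 0.0035).
#' @param rho Blood density, kg/m^3 (default 1060).
#' @param venous_pressure Coronary venous reference pressure, mmHg
#'   (default 0).
#' @param diameter_threshold Diameter qualification threshold for summed
#'   lengths, mm (default 1.5).
#' @param collateral List with `enabled` (default `FALSE`),
#'   `threshold_mmHg` (switch-on distal pressure, default 30) and
#'   `resistance_factor` (collateral resistance as a multiple of the outlet
#'   resistance, default 10).
#' @return An object of class `perfusion_params`.
#' @export
perfusion_params <- function(delta_P = 90, Q_total = 14, alpha = 3.45,
                             mu = 0.0035, rho = 1060, venous_pressure = 0,
                             diameter_threshold = 1.5,
                             collateral = list(enabled = FALSE,
                                               threshold_mmHg = 30,
                                               resistance_factor = 10)) {
  stopifnot(delta_P > 0, Q_total > 0, alpha > 1, mu > 0, rho > 0,
            diameter_threshold > 0)
  coll <- utils::modifyList(list(enabled = FALSE, threshold_mmHg = 30,
                                 resistance_factor = 10), collateral)
  if (isTRUE(coll$enabled)) {
    stopifnot(coll$resistance_factor > 0, coll$threshold_mmHg > 0,
              coll$threshold_mmHg < delta_P)
  }
  structure(list(delta_P = delta_P, Q_total = Q_total, alpha = alpha,
                 mu = mu, rho = rho, venous_pressure = venous_pressure,
                 diameter_threshold = diameter_threshold, collateral = coll),
            class = "perfusion_params")
}

#' @export
print.perfusion_params <- function(x, ...) {
  cat(sprintf(paste0("perfusion_params: dP = %g mmHg, Q = %g mL/s, ",
                     "alpha = %g, mu = %g Pa.s, rho = %g kg/m^3\n"),
              x$delta_P, x$Q_total, x$alpha, x$mu, x$rho))
  cat(sprintf("  venous pressure %g mmHg, diameter threshold %g mm, collateral %s\n",
              x$venous_pressure, x$diameter_threshold,
              if (isTRUE(x$collateral$enabled)) "on" else "off"))
  invisible(x)
}

#' Read perfusion parameters from a JSON config file
#'
#' Recognized keys: `delta_P_mmHg`, `Q_total_mL_s`, `alpha`, `mu_Pa_s`,
#' `rho_kg_m3`, `venous_pressure_mmHg`, `diameter_threshold_mm`, and a
#' `collateral` object with `enabled`, `threshold_mmHg`,
#' `resistance_factor`. Absent keys take the [perfusion_params()] defaults.
#'
#' @param path Path to a JSON config file.
#' @return A `perfusion_params` object.
#' @export
load_perfusion_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  d <- perfusion_params()
  get_or <- function(key, def) if (!is.null(cfg[[key]])) cfg[[key]] else def
  coll <- d$collateral
  if (!is.null(cfg$collateral))
    coll <- utils::modifyList(coll, as.list(cfg$collateral))
  perfusion_params(delta_P = get_or("delta_P_mmHg", d$delta_P),
                   Q_total = get_or("Q_total_mL_s", d$Q_total),
                   alpha = get_or("alpha", d$alpha),
                   mu = get_or("mu_Pa_s", d$mu),
                   rho = get_or("rho_kg_m3", d$rho),
                   venous_pressure = get_or("venous_pressure_mmHg",
                                            d$venous_pressure),
                   diameter_threshold = get_or("diameter_threshold_mm",
                                               d$diameter_threshold),
                   collateral = coll)
}

#' Proportionality constant of the length-based resistance model
#'
#' With summed qualifying lengths l_LAD, l_LCX and the RV/LV split of the
#' RCA length, the pressure-flow relation of the three arteries in parallel
#' fixes
#' \deqn{k = (\Delta P / Q)\,[\,l_{LAD} + l_{LCX} +
#'   l_{RV} l_{LV} / (l_{RV} + \alpha l_{LV})\,].}
#' The RCA term is the series combination alpha*k/l_RV + k/l_LV expressed as
#' an equivalent conductance length; it is 0 when either RCA territory
#' length is 0 (open branch).
#'
#' @param lengths A `summed_lengths` object (see [summed_lengths()]).
#' @param params A `perfusion_params` object.
#' @return `k` in mmHg.s.mm/mL.
#' @export
compute_k <- function(lengths, params) {
  l_rv <- lengths$l_RCA_RV
  l_lv <- lengths$l_RCA_LV
  rca_term <- if (l_rv > 0 && l_lv > 0)
    l_rv * l_lv / (l_rv + params$alpha * l_lv) else 0
  s <- lengths$l_LAD + lengths$l_LCX + rca_term
  if (s <= 0)
    stop("degenerate network: all summed vessel lengths are zero")
  (params$delta_P / params$Q_total) * s
}

#' Allocate per-artery outlet resistances from vessel lengths
#'
#' Longer vessels feed more muscle mass and receive lower microvascular
#' resistance: R_LAD = k/l_LAD, R_LCX = k/l_LCX, and for the RCA the series
#' sum of its RV- and LV-territory terms,
#' R_RCA = alpha*k/l_RV + k/l_LV. An artery with zero qualifying length gets
#' an infinite-resistance sentinel (no flow) so network assembly stays
#' uniform.
#'
#' @inheritParams compute_k
#' @return A `resistance_allocation` with `k`, `R_LAD`, `R_LCX`, `R_RCA`,
#'   and the RCA component terms `R_RCA_RV`, `R_RCA_LV` (mmHg.s/mL).
#' @export
allocate_resistances <- function(lengths, params) {
  k <- compute_k(lengths, params)
  div <- function(num, l) if (l > 0) num / l else Inf
  r_rv <- div(params$alpha * k, lengths$l_RCA_RV)
  r_lv <- div(k, lengths$l_RCA_LV)
  structure(list(k = k,
                 R_LAD = div(k, lengths$l_LAD),
                 R_LCX = div(k, lengths$l_LCX),
                 R_RCA = r_rv + r_lv,
                 R_RCA_RV = r_rv, R_RCA_LV = r_lv,
                 alpha = params$alpha),
            class = "resistance_allocation")
}

#' @export
print.resistance_allocation <- function(x, ...) {
  cat(sprintf("resistance_allocation: k = %.4g mmHg.s.mm/mL (alpha = %g)\n",
              x$k, x$alpha))
  cat(sprintf("  R_LAD = %.4g, R_LCX = %.4g, R_RCA = %.4g mmHg.s/mL\n",
              x$R_LAD, x$R_LCX, x$R_RCA))
  invisible(x)
}

#' Distribute per-artery resistance to terminal outlets
#'
#' Each artery's allocated resistance is split over its terminal segments so
#' that the parallel combination of outlet resistances equals the artery
#' resistance. Split weights are proportional to each outlet's downstream
#' summed length, applying the same length-based principle recursively at
#' every bifurcation: a segment's conductance share is divided among its
#' child subtrees in proportion to subtree total length.
#'
#' @param tree A `coronary_tree`.
#' @param alloc A `resistance_allocation` from [allocate_resistances()].
#' @param params Optional `perfusion_params`; when its collateral switch is
#'   enabled the outlet rows carry collateral settings (collateral
#'   resistance = `resistance_factor` x outlet resistance).
#' @return An `outlet_boundaries` data.frame with columns
#'   `outlet_segment_id`, `artery`, `resistance`, `collateral_enabled`,
#'   `collateral_threshold`, `collateral_resistance`.
#' @export
distribute_to_outlets <- function(tree, alloc, params = NULL) {
  rows <- list()
  for (a in c("RCA", "LAD", "LCX")) {
    r_art <- alloc[[paste0("R_", a)]]
    terms <- terminal_segments(tree, a)
    present <- any(tree$segments$artery == a)
    if (!present) {
      if (is.finite(r_art))
        stop("topology error: artery ", a,
             " has finite allocated resistance but no terminal segment")
      next
    }
    # recursive conductance split: G at the artery root, divided at each
    # node among child subtrees by subtree length
    g_root <- if (is.finite(r_art)) 1 / r_art else 0
    root <- tree$segments$id[tree$segments$artery == a &
                               is.na(tree$segments$parent_id)]
    out_g <- numeric(0)
    walk <- function(seg_id, g) {
      kids <- tree$segments$id[!is.na(tree$segments$parent_id) &
                                 tree$segments$parent_id == seg_id]
      if (length(kids) == 0) {
        out_g[[seg_id]] <<- g
      } else {
        w <- vapply(kids, function(k) .subtree_length(tree, k), numeric(1))
        for (j in seq_along(kids)) walk(kids[j], g * w[j] / sum(w))
      }
    }
    walk(root, g_root)
    for (id in names(out_g)) {
      r_out <- if (out_g[[id]] > 0) 1 / out_g[[id]] else Inf
      rows[[id]] <- data.frame(outlet_segment_id = id, artery = a,
                               resistance = r_out, stringsAsFactors = FALSE)
    }
  }
  ob <- do.call(rbind, rows)
  rownames(ob) <- NULL
  coll_on <- !is.null(params) && isTRUE(params$collateral$enabled)
  ob$collateral_enabled <- coll_on
  ob$collateral_threshold <- if (coll_on) params$collateral$threshold_mmHg else NA_real_
  ob$collateral_resistance <- if (coll_on)
    params$collateral$resistance_factor * ob$resistance else NA_real_
  class(ob) <- c("outlet_boundaries", "data.frame")
  ob
}

#' Effective outlet resistance under the collateral switch
#'
#' Collateral circulation is modeled as an on-off switched resistance in
#' parallel with the outlet: when the coronary distal pressure falls below
#' the switch threshold the collateral path opens, otherwise the outlet
#' resistance is unchanged.
#'
#' @param outlet A single outlet row (or list) with fields `resistance`,
#'   `collateral_enabled`, `collateral_threshold`, `collateral_resistance`.
#' @param distal_pressure Coronary distal pressure at the outlet, mmHg.
#' @return Effective resistance in mmHg.s/mL.
#' @export
collateral_adjust <- function(outlet, distal_pressure) {
  r <- outlet$resistance
  if (!isTRUE(outlet$collateral_enabled)) return(r)
  if (distal_pressure >= outlet$collateral_threshold) return(r)
  rc <- outlet$collateral_resistance
  1 / (1 / r + 1 / rc)
}
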