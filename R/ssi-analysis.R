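#' Stenosis susceptibility index from a severity sweep
#'
#' The SSI at a site is the magnitude of the slope of maximum wall shear
#' stress against FFR across virtual stenosis severities: WSSmax rises and
#' FFR falls as the lesion tightens, so the ordinary-least-squares slope of
#' WSSmax (y) on FFR (x) is negative and SSI = -slope is positive. A small
#' SSI means severe stenosis is needed before wall shear reaches the
#' vasodilation-triggering level, i.e. the site is susceptible to plaque
#' deposition.
#'
#' @param sweep A `severity_sweep` with at least 2 points and non-constant
#'   FFR.
#' @param units WSS units for the slope: `"dyn_cm2"` (default) or `"pa"`.
#' @return An `ssi_record`: `site`, `ssi`, `r_squared` (NA with fewer than
#'   3 points), `n_points`, `units`, `method = "slope_fit"`.
#' @export
ssi_from_sweep <- function(sweep, units = c("dyn_cm2", "pa")) {
  units <- match.arg(units)
  p <- sweep$points
  if (nrow(p) < 2) stop("severity sweep must contain at least 2 points")
  if (stats::var(p$ffr) == 0)
    stop("degenerate fit: all FFR values identical (zero variance)")
  y <- if (units == "dyn_cm2") pa_to_dyn_cm2(p$wss_max_pa) else p$wss_max_pa
  fit <- stats::lm(y ~ ffr, data = data.frame(ffr = p$ffr, y = y))
  slope <- unname(stats::coef(fit)[2])
  r2 <- if (nrow(p) >= 3) summary(fit)$r.squared else NA_real_
  structure(list(site = sweep$site, ssi = -slope, r_squared = r2,
                 n_points = nrow(p), units = units, method = "slope_fit"),
            class = "ssi_record")
}

#' Simplified (single-point) SSI
#'
#' Under the normalization that the non-stenosed model has WSSmax 0 and
#' FFR 1, the slope reduces to SSI = WSSmax / (1 - FFR) of the stenosed
#' model alone.
#'
#' @param wss_max Maximum wall shear stress of the stenosed model (any
#'   units; the SSI inherits them).
#' @param ffr FFR of the stenosed model, strictly below 1.
#' @return SSI in the units of `wss_max` per unit FFR.
#' @export
ssi_simplified <- function(wss_max, ffr) {
  if (any(ffr >= 1)) stop("simplified SSI requires FFR < 1")
  wss_max / (1 - ffr)
}

#' @export
print.ssi_record <- function(x, ...) {
  cat(sprintf("ssi_record: site '%s', SSI = %.4g %s per FFR unit (%s, n = %d",
              x$site$site_id, x$ssi,
              if (x$units == "dyn_cm2") "dyn/cm^2" else "Pa",
              x$method, x$n_points))
  if (!is.na(x$r_squared)) cat(sprintf(", r^2 = %.4f", x$r_squared))
  cat(")\n")
  invisible(x)
}

#' Collect SSI records into a table
#'
#' @param records List of `ssi_record` objects.
#' @param tree Optional `coronary_tree` used to attach the artery label of
#'   each site's segment.
#' @return data.frame with columns `site_id`, `segment_id`, `position`,
#'   `artery` (NA without a tree), `ssi`, `r_squared`.
#' @export
ssi_table <- function(records, tree = NULL) {
  do.call(rbind, lapply(records, function(r) {
    artery <- if (!is.null(tree))
      tree$segments$artery[match(r$site$segment_id, tree$segments$id)]
    else NA_character_
    data.frame(site_id = r$site$site_id, segment_id = r$site$segment_id,
               position = r$site$position, artery = artery, ssi = r$ssi,
               r_squared = r$r_squared, stringsAsFactors = FALSE)
  }))
}

#' Rank candidate sites by SSI
#'
#' Finds the minimum-SSI site per artery and the global minimum across
#' arteries — the predicted most plaque-susceptible site. Ties are broken
#' by artery order (RCA, LAD, LCX) then by proximal-most position, and
#' flagged.
#'
#' @param records A data.frame with columns `artery`, `ssi` and ideally
#'   `site_id`/`position` (as from [ssi_table()]), or a list of
#'   `ssi_record`s plus a `tree` to label arteries.
#' @param tree Optional `coronary_tree` (when `records` is a list).
#' @return An `ssi_ranking`: `per_artery` (one row per artery, its minimum),
#'   `global` (single row), `tied` flag.
#' @export
rank_sites <- function(records, tree = NULL) {
  df <- if (is.data.frame(records)) records else ssi_table(records, tree)
  if (nrow(df) == 0) stop("rank_sites requires at least one SSI record")
  if (any(is.na(df$artery))) stop("records must carry an artery label")
  if (is.null(df$position)) df$position <- NA_real_
  if (is.null(df$site_id)) df$site_id <- NA_character_
  df$artery <- factor(df$artery, levels = c("RCA", "LAD", "LCX"))
  ord <- order(df$ssi, as.integer(df$artery), df$position)
  df_s <- df[ord, , drop = FALSE]
  per_artery <- do.call(rbind, lapply(levels(droplevels(df_s$artery)), function(a) {
    sub <- df_s[df_s$artery == a, , drop = FALSE]
    sub[1, , drop = FALSE]
  }))
  per_artery <- per_artery[order(as.integer(per_artery$artery)), , drop = FALSE]
  rownames(per_artery) <- NULL
  gmin <- min(df$ssi)
  tied <- sum(df$ssi == gmin) > 1
  global <- df_s[1, , drop = FALSE]
  rownames(global) <- NULL
  structure(list(per_artery = per_artery, global = global, tied = tied),
            class = "ssi_ranking")
}

#' @export
print.ssi_ranking <- function(x, ...) {
  cat("ssi_ranking: per-artery minimum SSI\n")
  print(x$per_artery[, intersect(c("artery", "site_id", "ssi"),
                                 names(x$per_artery))], row.names = FALSE)
  cat(sprintf("global minimum: %s (SSI = %.4g)%s\n",
              as.character(x$global$artery[1]), x$global$ssi[1],
              if (x$tied) " [tied]" else ""))
  invisible(x)
}

#' Concordance between minimum-SSI predictions and PCI observations
#'
#' Scores site predictions against clinical observations at the vessel and
#' patient level. A treated vessel is a (patient, artery) pair where PCI
#' was performed; it is matched when the artery's minimum-SSI site
#' coincides with the PCI site. The per-vessel rate is
#' 100 x matched / treated vessels; the per-patient rate counts a patient
#' as matched only when every one of their treated vessels is matched.
#'
#' @param observations A data.frame with one row per (patient, artery):
#'   columns `patient_id`, `mi` (logical or "Y"/"N"), `artery`, `treated`
#'   (0/1 or logical), `matched` (0/1/logical; `NA` where not treated).
#' @return A `concordance_report` with unrounded rates (display is rounded
#'   to 1 decimal), counts, and `mi_count`.
#' @export
concordance_report <- function(observations) {
  obs <- observations
  need <- c("patient_id", "mi", "artery", "treated", "matched")
  missing_cols <- setdiff(need, names(obs))
  if (length(missing_cols) > 0)
    stop("observations missing column(s): ", paste(missing_cols, collapse = ", "))
  if (!all(obs$artery %in% c("RCA", "LAD", "LCX")))
    stop("artery must be one of RCA, LAD, LCX")
  if (is.character(obs$mi)) obs$mi <- toupper(obs$mi) == "Y"
  obs$treated <- as.logical(obs$treated)
  obs$matched <- as.logical(obs$matched)
  if (any(obs$treated & is.na(obs$matched)))
    stop("treated vessels must carry a matched flag")
  patients <- unique(obs$patient_id)
  treated <- obs[obs$treated, , drop = FALSE]
  n_vessels <- nrow(treated)
  n_vessels_matched <- sum(treated$matched)
  patient_match <- vapply(patients, function(p) {
    tp <- treated[treated$patient_id == p, , drop = FALSE]
    nrow(tp) > 0 && all(tp$matched)
  }, logical(1))
  mi_by_patient <- vapply(patients, function(p)
    any(obs$mi[obs$patient_id == p]), logical(1))
  structure(list(
    n_patients = length(patients),
    n_patients_matched = sum(patient_match),
    n_vessels_treated = n_vessels,
    n_vessels_matched = n_vessels_matched,
    per_patient_rate = if (length(patients) > 0)
      100 * sum(patient_match) / length(patients) else NA_real_,
    per_vessel_rate = if (n_vessels > 0)
      100 * n_vessels_matched / n_vessels else NA_real_,
    mi_count = sum(mi_by_patient)), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("concordance_report\n")
  cat(sprintf("  per-patient: %d/%d matched, rate %s%%\n",
              x$n_patients_matched, x$n_patients,
              if (is.na(x$per_patient_rate)) "NA"
              else format(round(x$per_patient_rate, 1), nsmall = 1)))
  cat(sprintf("  per-vessel:  %d/%d matched, rate %s%%\n",
              x$n_vessels_matched, x$n_vessels_treated,
              if (is.na(x$per_vessel_rate)) "undefined (no treated vessels)"
              else format(round(x$per_vessel_rate, 1), nsmall = 1)))
  cat(sprintf("  MI observed in %d of %d patient(s)\n", x$mi_count,
              x$n_patients))
  invisible(x)
}

#' Fill match flags from site-level predictions
#'
#' Derives the `matched` column consumed by [concordance_report()] by
#' comparing, for every treated vessel, the predicted per-artery
#' minimum-SSI site against the observed PCI site.
#'
#' @param predictions data.frame with one row per (patient, artery):
#'   `patient_id`, `artery`, `site_id` — the artery's minimum-SSI site.
#' @param observations data.frame with `patient_id`, `mi`, `artery`,
#'   `treated` and `pci_site_id` (the site where PCI was performed; may be
#'   `NA` on untreated rows).
#' @return `observations` with a `matched` column, ready for
#'   [concordance_report()].
#' @export
match_predictions <- function(predictions, observations) {
  obs <- observations
  need <- c("patient_id", "artery", "treated", "pci_site_id")
  missing_cols <- setdiff(need, names(obs))
  if (length(missing_cols) > 0)
    stop("observations missing column(s): ", paste(missing_cols, collapse = ", "))
  key <- function(p, a) paste(p, a, sep = "\r")
  pred_site <- stats::setNames(predictions$site_id,
                               key(predictions$patient_id, predictions$artery))
  obs$matched <- NA
  for (i in which(as.logical(obs$treated))) {
    k <- key(obs$patient_id[i], obs$artery[i])
    if (!k %in% names(pred_site))
      stop("alignment error: no prediction for patient '", obs$patient_id[i],
           "', artery ", obs$artery[i])
    obs$matched[i] <- identical(pred_site[[k]], obs$pci_site_id[i])
  }
  obs
}

#' Full SSI pipeline on one coronary tree
#'
#' Calibrates the lumped-parameter outlet boundaries from the lesion-free
#' tree (summed qualifying lengths, `k`, per-artery resistances, outlet
#' distribution), then runs a severity sweep and SSI fit at every candidate
#' site and ranks the sites.
#'
#' @param tree A `coronary_tree`.
#' @param params A `perfusion_params` (default [perfusion_params()]).
#' @param sites List of `candidate_site`s (default [default_sites()]).
#' @param severities Severity grid, percent (default `c(0, 25, 50)`).
#' @param mode `"steady"` (default) or `"pulsatile"`.
#' @param waveform `inlet_waveform` for pulsatile mode.
#' @param lesion_length_mm Lesion length, mm (default 10).
#' @return An `ssi_result`: `records` (SSI table), `ranking`, `sweeps`,
#'   `allocation`, `outlets`, `params`.
#' @export
run_ssi <- function(tree, params = perfusion_params(), sites = NULL,
                    severities = c(0, 25, 50), mode = c("steady", "pulsatile"),
                    waveform = NULL, lesion_length_mm = 10) {
  mode <- match.arg(mode)
  if (is.null(sites)) sites <- default_sites(tree)
  lengths <- summed_lengths(tree, params$diameter_threshold)
  alloc <- allocate_resistances(lengths, params)
  outlets <- distribute_to_outlets(tree, alloc, params)
  inlet <- params$venous_pressure + params$delta_P
  sweeps <- lapply(sites, function(st)
    severity_sweep(tree, st, severities, outlets, inlet_pressure = inlet,
                   params = params, mode = mode, waveform = waveform,
                   lesion_length_mm = lesion_length_mm))
  recs <- lapply(sweeps, ssi_from_sweep)
  tab <- ssi_table(recs, tree)
  structure(list(records = tab, ranking = rank_sites(tab), sweeps = sweeps,
                 allocation = alloc, outlets = outlets, params = params),
            class = "ssi_result")
}

#' @export
print.ssi_result <- function(x, ...) {
  cat(sprintf("ssi_result: %d site(s)\n", nrow(x$records)))
  print(x$records[, c("site_id", "artery", "ssi", "r_squared")],
        row.names = FALSE)
  print(x$ranking)
  invisible(x)
}
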