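#' Candidate stenosis site
#'
#' @param site_id Identifier for the site.
#' @param segment_id Segment carrying the site.
#' @param position Fraction in \[0, 1\] from the segment's proximal end.
#' @return A `candidate_site` object.
#' @export
candidate_site <- function(site_id, segment_id, position) {
  stopifnot(position >= 0, position <= 1)
  structure(list(site_id = site_id, segment_id = segment_id,
                 position = position), class = "candidate_site")
}

# cumulative-length trunk of an artery: root-to-deepest path
.main_trunk <- function(tree, artery) {
  depth <- function(id) {
    path <- path_to_root(tree, id)
    sum(tree$segments$length_mm[match(path, tree$segments$id)])
  }
  terms <- terminal_segments(tree, artery)
  if (length(terms) == 0) return(NULL)
  deepest <- terms[which.max(vapply(terms, depth, numeric(1)))]
  path_to_root(tree, deepest)
}

#' Default candidate sites along each artery's main trunk
#'
#' For each artery present, the main trunk is the root-to-deepest path by
#' cumulative length; candidate sites are placed at fractions 0.25, 0.5 and
#' 0.75 of the trunk's cumulative length, with deterministic ids
#' `"<artery>_p25" / "_p50" / "_p75"`.
#'
#' @param tree A `coronary_tree`.
#' @return List of `candidate_site` objects (3 per artery present).
#' @export
default_sites <- function(tree) {
  sites <- list()
  for (a in c("RCA", "LAD", "LCX")) {
    trunk <- .main_trunk(tree, a)
    if (is.null(trunk)) next
    lens <- tree$segments$length_mm[match(trunk, tree$segments$id)]
    total <- sum(lens)
    ends <- cumsum(lens)
    for (fr in c(0.25, 0.5, 0.75)) {
      target <- fr * total
      i <- which(ends >= target - 1e-12)[1]
      start <- if (i == 1) 0 else ends[i - 1]
      pos <- (target - start) / lens[i]
      sites[[length(sites) + 1]] <-
        candidate_site(sprintf("%s_p%d", a, round(fr * 100)), trunk[i],
                       min(max(pos, 0), 1))
    }
  }
  sites
}

#' Build a lesion at a candidate site
#'
#' The reference diameter is the local healthy diameter at the site
#' (linear proximal-to-distal taper); the minimal lumen diameter is
#' `d_reference x (1 - severity/100)`. The input tree is untouched.
#'
#' @param tree A `coronary_tree`.
#' @param site A `candidate_site`.
#' @param severity_pct Percent diameter reduction in \[0, 100).
#' @param lesion_length_mm Lesion length, mm (default 10, clipped to the
#'   segment length).
#' @return A `lesion_geometry`.
#' @export
apply_stenosis <- function(tree, site, severity_pct, lesion_length_mm = 10) {
  seg <- .segment_row(tree, site$segment_id)
  d_ref <- local_diameter(tree, site$segment_id, site$position)
  lesion_geometry(site$segment_id, site$position, severity_pct,
                  min(lesion_length_mm, seg$length_mm), d_ref)
}

#' Severity sweep at a candidate site
#'
#' The virtual stenosis method at one site: for each severity in the grid a
#' lesion of that severity is inserted at the site, the network is
#' re-solved, and (severity, FFR, WSSmax) is recorded. Boundary conditions
#' (the outlet resistances, calibrated from the lesion-free tree) are held
#' fixed across severities so the sweep isolates the lesion's hemodynamic
#' effect.
#'
#' @param tree A `coronary_tree` (never modified).
#' @param site A `candidate_site`.
#' @param severities Ascending severity grid in percent diameter reduction
#'   (default `c(0, 25, 50)`).
#' @param outlets `outlet_boundaries` from the lesion-free calibration.
#' @param inlet_pressure Inlet pressure, mmHg (steady mode).
#' @param params A `perfusion_params`.
#' @param mode `"steady"` or `"pulsatile"`.
#' @param waveform An `inlet_waveform`, required in pulsatile mode; FFR is
#'   then the ratio of cycle-averaged pressures and WSSmax the maximum over
#'   cycle samples.
#' @param lesion_length_mm Lesion length, mm (default 10).
#' @return A `severity_sweep`: `site`, `solver_mode`, and `points`, a
#'   data.frame with columns `severity_pct`, `ffr`, `wss_max_pa`,
#'   `lesion_flow_ml_s`.
#' @export
severity_sweep <- function(tree, site, severities = c(0, 25, 50), outlets,
                           inlet_pressure = NULL, params,
                           mode = c("steady", "pulsatile"), waveform = NULL,
                           lesion_length_mm = 10) {
  mode <- match.arg(mode)
  if (is.unsorted(severities, strictly = TRUE))
    stop("severities must be strictly ascending")
  if (mode == "pulsatile" && is.null(waveform))
    stop("pulsatile mode requires a waveform")
  if (mode == "steady" && is.null(inlet_pressure))
    stop("steady mode requires inlet_pressure")
  rows <- lapply(severities, function(sv) {
    lesion <- apply_stenosis(tree, site, sv, lesion_length_mm)
    tryCatch({
      if (mode == "steady") {
        st <- solve_steady(tree, outlets, list(lesion), inlet_pressure, params)
        q <- st$segment_flows[[site$segment_id]]
        wss <- compute_wss_max(lesion, q, params$mu)
      } else {
        st <- solve_pulsatile(tree, outlets, list(lesion), waveform, params)
        qs <- vapply(st$states, function(s)
          s$segment_flows[[site$segment_id]], numeric(1))
        wss <- max(vapply(qs, function(qi)
          compute_wss_max(lesion, qi, params$mu), numeric(1)))
        q <- mean(qs)
      }
      data.frame(severity_pct = sv, ffr = compute_ffr(st, site$segment_id),
                 wss_max_pa = wss, lesion_flow_ml_s = q)
    }, error = function(e)
      stop("severity sweep failed at site '", site$site_id, "', severity ",
           sv, "%: ", conditionMessage(e)))
  })
  structure(list(site = site, solver_mode = mode,
                 points = do.call(rbind, rows)),
            class = "severity_sweep")
}

#' @export
print.severity_sweep <- function(x, ...) {
  cat(sprintf("severity_sweep at site '%s' (segment %s, position %.2f), %s mode\n",
              x$site$site_id, x$site$segment_id, x$site$position,
              x$solver_mode))
  print(x$points, row.names = FALSE)
  invisible(x)
}

#' Flatten severity sweeps to a table
#'
#' @param sweeps A `severity_sweep` or list of them.
#' @return data.frame with columns `site_id`, `severity_pct`, `ffr`,
#'   `wss_max_pa`, `wss_max_dyn_cm2`, `lesion_flow_ml_s`.
#' @export
sweeps_to_table <- function(sweeps) {
  if (inherits(sweeps, "severity_sweep")) sweeps <- list(sweeps)
  do.call(rbind, lapply(sweeps, function(sw) {
    p <- sw$points
    data.frame(site_id = sw$site$site_id, severity_pct = p$severity_pct,
               ffr = p$ffr, wss_max_pa = p$wss_max_pa,
               wss_max_dyn_cm2 = pa_to_dyn_cm2(p$wss_max_pa),
               lesion_flow_ml_s = p$lesion_flow_ml_s,
               stringsAsFactors = FALSE)
  }))
}
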