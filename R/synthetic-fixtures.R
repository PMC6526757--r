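#' Parameters for the synthetic coronary tree generator
#'
#' Morphology ranges are literature-plausible conventions for adult
#' epicardial coronaries; they are configuration, not anatomical claims.
#'
#' @param seed Integer RNG seed; a fixed seed reproduces the tree exactly.
#' @param n_branches_per_artery Trunk segments per artery (1-6, default 3);
#'   each interior trunk junction also carries one side branch.
#' @param trunk_length_range Total trunk length range, mm (default 40-120).
#' @param branch_length_range Side-branch length range, mm (default 20-60).
#' @param root_diameter_range Artery root diameter range, mm
#'   (default 2.5-4.5).
#' @param taper_range Root-to-tip diameter taper ratio range
#'   (default 0.6-0.9).
#' @param rca_rv_fraction Fraction of cumulative RCA length tagged as
#'   RV-feeding (default 0.55).
#' @return A `tree_gen_params` object.
#' @export
tree_gen_params <- function(seed, n_branches_per_artery = 3,
                            trunk_length_range = c(40, 120),
                            branch_length_range = c(20, 60),
                            root_diameter_range = c(2.5, 4.5),
                            taper_range = c(0.6, 0.9),
                            rca_rv_fraction = 0.55) {
  stopifnot(n_branches_per_artery >= 1, n_branches_per_artery <= 6,
            all(trunk_length_range > 0), diff(trunk_length_range) >= 0,
            all(branch_length_range > 0), diff(branch_length_range) >= 0,
            all(root_diameter_range > 0), diff(root_diameter_range) >= 0,
            all(taper_range > 0), all(taper_range <= 1),
            rca_rv_fraction > 0, rca_rv_fraction < 1)
  structure(list(seed = as.integer(seed),
                 n_branches_per_artery = n_branches_per_artery,
                 trunk_length_range = trunk_length_range,
                 branch_length_range = branch_length_range,
                 root_diameter_range = root_diameter_range,
                 taper_range = taper_range,
                 rca_rv_fraction = rca_rv_fraction),
            class = "tree_gen_params")
}

#' Generate a synthetic three-artery coronary tree
#'
#' Deterministic, seed-reproducible stand-in for a CT-derived coronary
#' centerline model. Each artery is a tapering trunk of
#' `n_branches_per_artery` chained segments with one side branch at every
#' interior junction; RCA segments are tagged RV-feeding until
#' `rca_rv_fraction` of the cumulative RCA length is reached, LV-feeding
#' after (with at least one segment of each territory whenever the RCA has
#' more than one segment). Lengths and diameters are rounded to 1 um so the
#' JSON round trip is exact. The caller's RNG stream is left untouched.
#'
#' @param params A `tree_gen_params`, or an integer seed (other generator
#'   settings then take their defaults).
#' @return A valid `coronary_tree` with patient id `"synthetic-<seed>"`.
#' @export
generate_tree <- function(params) {
  if (is.numeric(params)) params <- tree_gen_params(params)
  stopifnot(inherits(params, "tree_gen_params"))
  with_preserved_seed(params$seed, {
    rows <- list()
    add <- function(...) rows[[length(rows) + 1]] <<- data.frame(
      ..., stringsAsFactors = FALSE)
    r3 <- function(x) round(x, 3)
    for (a in c("RCA", "LAD", "LCX")) {
      n <- params$n_branches_per_artery
      l_trunk <- stats::runif(1, params$trunk_length_range[1],
                              params$trunk_length_range[2])
      d0 <- stats::runif(1, params$root_diameter_range[1],
                         params$root_diameter_range[2])
      taper <- stats::runif(1, params$taper_range[1], params$taper_range[2])
      # trunk: n chained segments, continuous geometric taper d0 -> d0*taper
      cuts <- if (n > 1) sort(stats::runif(n - 1, 0.3, 0.9)) else numeric(0)
      bounds <- c(0, cuts, 1)
      for (i in seq_len(n)) {
        add(id = sprintf("%s_t%d", a, i), artery = a,
            parent_id = if (i == 1) NA_character_
                        else sprintf("%s_t%d", a, i - 1),
            length_mm = r3(l_trunk * (bounds[i + 1] - bounds[i])),
            d_prox_mm = r3(d0 * taper^bounds[i]),
            d_dist_mm = r3(d0 * taper^bounds[i + 1]),
            territory = "NA")
      }
      # one side branch at each interior junction (distal end of trunk i)
      for (i in seq_len(max(n - 1, 0))) {
        lb <- stats::runif(1, params$branch_length_range[1],
                           params$branch_length_range[2])
        db <- 0.75 * d0 * taper^bounds[i + 1]
        tb <- stats::runif(1, params$taper_range[1], params$taper_range[2])
        add(id = sprintf("%s_b%d", a, i), artery = a,
            parent_id = sprintf("%s_t%d", a, i),
            length_mm = r3(lb), d_prox_mm = r3(db), d_dist_mm = r3(db * tb),
            territory = "NA")
      }
    }
    seg <- do.call(rbind, rows)
    # RV/LV territory split of the RCA along its trunk: a trunk segment is
    # RV-feeding while its cumulative midpoint lies within rca_rv_fraction
    # of the trunk length (proximal acute-marginal region), LV-feeding
    # after (distal PDA/PLV region); side branches inherit the territory
    # of the trunk segment they spring from. With more than one trunk
    # segment both territories are guaranteed nonempty.
    trunk_i <- which(seg$artery == "RCA" & grepl("^RCA_t", seg$id))
    tl <- seg$length_mm[trunk_i]
    mid <- (cumsum(c(0, tl))[seq_along(tl)] + tl / 2) / sum(tl)
    terr <- ifelse(mid < params$rca_rv_fraction, "RV", "LV")
    if (length(terr) > 1) {
      terr[1] <- "RV"
      terr[length(terr)] <- "LV"
    }
    seg$territory[trunk_i] <- terr
    branch_i <- which(seg$artery == "RCA" & grepl("^RCA_b", seg$id))
    for (j in branch_i) {
      k <- match(seg$parent_id[j], seg$id)
      seg$territory[j] <- seg$territory[k]
    }
    coronary_tree(sprintf("synthetic-%d", params$seed), seg)
  })
}

#' Generate a parametric arterial inlet pressure waveform
#'
#' Two-phase periodic cycle: a half-sine (raised-cosine) systolic rise over
#' the first third of the period from diastolic to systolic pressure,
#' followed by an exponential diastolic decay back to the diastolic level.
#' Samples are affinely rescaled so the sampled maximum and minimum equal
#' `sbp` and `dbp` exactly; the cycle mean lands near the textbook
#' dbp + (sbp - dbp)/3 estimate of mean arterial pressure.
#'
#' @param sbp Systolic pressure, mmHg.
#' @param dbp Diastolic pressure, mmHg (`0 < dbp < sbp`).
#' @param heart_rate Heart rate, bpm; the period is `60/heart_rate` s.
#' @param n_samples Samples per cycle (at least 32, default 64).
#' @return An `inlet_waveform`: `time` (s, in `[0, period)`), `pressure`
#'   (mmHg), `sbp`, `dbp`, `heart_rate`, `period`.
#' @export
generate_waveform <- function(sbp = 120, dbp = 80, heart_rate = 70,
                              n_samples = 64) {
  if (!(sbp > dbp && dbp > 0)) stop("need sbp > dbp > 0")
  if (heart_rate <= 0) stop("heart_rate must be positive")
  if (n_samples < 32) stop("need at least 32 samples per cycle")
  period <- 60 / heart_rate
  t <- (seq_len(n_samples) - 1) / n_samples * period
  p <- waveform_shape(t, sbp, dbp, period)
  # rescale samples so sampled extrema hit sbp/dbp exactly
  if (max(p) > min(p))
    p <- dbp + (p - min(p)) * (sbp - dbp) / (max(p) - min(p))
  structure(list(time = t, pressure = p, sbp = sbp, dbp = dbp,
                 heart_rate = heart_rate, period = period),
            class = "inlet_waveform")
}

#' Continuous parametric waveform shape
#'
#' The unscaled pressure at time `t` within a cycle: raised-cosine rise
#' dbp -> sbp over `period/3`, then exponential decay with time constant
#' `(2/3) period / 3.5` toward a floor chosen so the cycle ends exactly at
#' dbp.
#'
#' @param t Time(s) in seconds (wrapped into the cycle).
#' @param sbp,dbp Systolic/diastolic pressure, mmHg.
#' @param period Cycle length, s.
#' @return Pressure(s) in mmHg.
#' @export
waveform_shape <- function(t, sbp, dbp, period) {
  ts <- period / 3
  td <- period - ts
  tau <- td / 3.5
  e <- exp(-td / tau)
  p_floor <- (dbp - sbp * e) / (1 - e)
  tt <- t %% period
  ifelse(tt <= ts,
         dbp + (sbp - dbp) * (1 - cos(pi * tt / ts)) / 2,
         p_floor + (sbp - p_floor) * exp(-(tt - ts) / tau))
}

#' @export
print.inlet_waveform <- function(x, ...) {
  cat(sprintf("inlet_waveform: %d samples, %g/%g mmHg at %g bpm (period %.3g s, mean %.1f mmHg)\n",
              length(x$pressure), x$sbp, x$dbp, x$heart_rate, x$period,
              mean(x$pressure)))
  invisible(x)
}

#' Encoded pilot-study observation table
#'
#' The printed seven-patient pilot table: per-artery minimum SSI values,
#' the MI flag, and the PCI-site match marks per artery ("o" = treated and
#' matched by the minimum-SSI site, "x" = treated but mismatched, "-" = no
#' PCI performed; the blank Case IV LCX cell means that artery was not
#' evaluated and carries no SSI value). SSI values are treated as unitless
#' labels for ranking and reporting; they come from the source study's 3D
#' simulations and are not recomputed here.
#'
#' @return A list with `min_ssi` (data.frame `patient_id`, `artery`,
#'   `min_ssi`; `NA` where not evaluated) and `observations` (data.frame
#'   `patient_id`, `mi`, `artery`, `treated`, `matched` suitable for
#'   [concordance_report()]).
#' @export
table1_fixture <- function() {
  arteries <- c("RCA", "LAD", "LCX")
  ids <- paste0("case_", c("I", "II", "III", "IV", "V", "VI", "VII"))
  ssi_vals <- rbind(c(546, 581, 543),
                    c(412, 329, 239),
                    c(792, 874, 429),
                    c(729, 793, NA),
                    c(468, 755, 877),
                    c(520, 980, 532),
                    c(1171, 1238, 1400))
  mi <- c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE)
  # match marks per artery: "o" treated+matched, "x" treated+mismatched,
  # "-" not treated, "" artery not evaluated
  marks <- rbind(c("o", "-", "o"),
                 c("-", "o", "o"),
                 c("-", "-", "o"),
                 c("o", "-", ""),
                 c("-", "x", "-"),
                 c("-", "x", "-"),
                 c("o", "-", "-"))
  min_ssi <- data.frame(patient_id = rep(ids, each = 3),
                        artery = rep(arteries, times = 7),
                        min_ssi = as.vector(t(ssi_vals)),
                        stringsAsFactors = FALSE)
  obs <- data.frame(patient_id = rep(ids, each = 3),
                    mi = rep(mi, each = 3),
                    artery = rep(arteries, times = 7),
                    mark = as.vector(t(marks)), stringsAsFactors = FALSE)
  obs <- obs[obs$mark != "", , drop = FALSE]
  obs$treated <- obs$mark %in% c("o", "x")
  obs$matched <- ifelse(obs$treated, obs$mark == "o", NA)
  obs$mark <- NULL
  rownames(obs) <- NULL
  list(min_ssi = min_ssi, observations = obs)
}
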