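mk_sweep <- function(ffr, wss_pa, site = candidate_site("s", "seg", 0.5)) {
  structure(list(site = site, solver_mode = "steady",
                 points = data.frame(severity_pct = seq_along(ffr) - 1,
                                     ffr = ffr, wss_max_pa = wss_pa,
                                     lesion_flow_ml_s = NA_real_)),
            class = "severity_sweep")
}

test_that("SSI is minus the OLS slope of WSSmax on FFR", {
  # exact collinear points (values already in dyn/cm^2 terms: use pa units)
  sw <- mk_sweep(c(1.0, 0.9, 0.8), c(0, 50, 100))
  rec <- ssi_from_sweep(sw, units = "pa")
  expect_equal(rec$ssi, 500)
  expect_equal(rec$r_squared, 1)
  # two points: plain difference quotient, r^2 undefined
  sw2 <- mk_sweep(c(1.0, 0.75), c(0, 80))
  rec2 <- ssi_from_sweep(sw2, units = "pa")
  expect_equal(rec2$ssi, (80 - 0) / (1.0 - 0.75))
  expect_true(is.na(rec2$r_squared))
  # default units are dyn/cm^2 = 10x Pa
  expect_equal(ssi_from_sweep(sw)$ssi, 5000)
  # degenerate: constant FFR
  expect_error(ssi_from_sweep(mk_sweep(c(0.9, 0.9), c(0, 10))), "degenerate")
})

test_that("noisy OLS slope equals the brute-force covariance ratio", {
  withr::local_seed(55)
  for (i in 1:20) {
    ffr <- sort(runif(6, 0.5, 1), decreasing = TRUE)
    wss <- 100 * (1 - ffr) + rnorm(6, sd = 3)
    rec <- ssi_from_sweep(mk_sweep(ffr, wss), units = "pa")
    expect_equal(rec$ssi, -oracle_ols_slope(ffr, wss), tolerance = 1e-12)
  }
})

test_that("simplified SSI matches the slope form under the unit baseline", {
  expect_equal(ssi_simplified(400, 0.5), 800)
  expect_equal(ssi_simplified(0, 0.5), 0)
  expect_error(ssi_simplified(10, 1), "FFR < 1")
  # identity with the 2-point slope when the baseline is exactly (1, 0)
  withr::local_seed(77)
  for (i in 1:50) {
    ffr_s <- runif(1, 0.3, 0.99)
    wss_s <- runif(1, 10, 500)
    rec <- ssi_from_sweep(mk_sweep(c(1, ffr_s), c(0, wss_s)), units = "pa")
    expect_lt(abs(rec$ssi - ssi_simplified(wss_s, ffr_s)) /
                ssi_simplified(wss_s, ffr_s), 1e-12)
  }
})

test_that("SSI scales linearly with the WSS values (unit equivariance)", {
  sw <- mk_sweep(c(1.0, 0.92, 0.78), c(2, 40, 130))
  base <- ssi_from_sweep(sw, units = "pa")$ssi
  for (c_scale in c(0.1, 10, 250)) {
    scaled <- mk_sweep(c(1.0, 0.92, 0.78), c_scale * c(2, 40, 130))
    expect_equal(ssi_from_sweep(scaled, units = "pa")$ssi, c_scale * base,
                 tolerance = 1e-12)
  }
})

test_that("site ranking finds per-artery and global minima with stable tie-breaks", {
  df <- data.frame(site_id = c("r1", "r2", "l1", "l2", "x1"),
                   artery = c("RCA", "RCA", "LAD", "LAD", "LCX"),
                   position = c(0.25, 0.5, 0.25, 0.5, 0.5),
                   ssi = c(700, 650, 500, 820, 610))
  rk <- rank_sites(df)
  expect_equal(as.character(rk$per_artery$artery), c("RCA", "LAD", "LCX"))
  expect_equal(rk$per_artery$ssi, c(650, 500, 610))
  expect_equal(rk$global$site_id, "l1")
  expect_false(rk$tied)
  # single record is its own artery and global minimum
  one <- rank_sites(data.frame(site_id = "a", artery = "LCX",
                               position = 0.5, ssi = 42))
  expect_equal(one$global$ssi, 42)
  # permutation invariance and linear-scan oracle on random inputs
  withr::local_seed(13)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    rec <- data.frame(site_id = paste0("s", 1:n),
                      artery = sample(c("RCA", "LAD", "LCX"), n, replace = TRUE),
                      position = runif(n), ssi = round(runif(n, 100, 1500)))
    rk1 <- rank_sites(rec)
    rk2 <- rank_sites(rec[sample(n), ])
    expect_equal(rk1$global$ssi, min(rec$ssi))       # brute-force scan
    expect_equal(rk1$global$site_id, rk2$global$site_id)
    expect_equal(rk1$per_artery$ssi, rk2$per_artery$ssi)
  }
  # ties break by artery order RCA > LAD > LCX, then proximal position
  tie <- data.frame(site_id = c("a", "b"), artery = c("LCX", "RCA"),
                    position = c(0.25, 0.75), ssi = c(300, 300))
  rk_tie <- rank_sites(tie)
  expect_true(rk_tie$tied)
  expect_equal(rk_tie$global$site_id, "b")
  expect_error(rank_sites(df[0, ]), "at least one")
})

test_that("pilot-table fixture reproduces the printed concordance rates", {
  fx <- table1_fixture()
  rep <- concordance_report(fx$observations)
  expect_equal(round(rep$per_patient_rate, 1), 71.4)
  expect_equal(round(rep$per_vessel_rate, 1), 77.8)
  expect_equal(rep$n_patients, 7)
  expect_equal(rep$n_patients_matched, 5)
  expect_equal(rep$n_vessels_treated, 9)
  expect_equal(rep$n_vessels_matched, 7)
  expect_equal(rep$mi_count, 4)
  # invariant to patient ordering
  shuffled <- fx$observations[rev(seq_len(nrow(fx$observations))), ]
  rep2 <- concordance_report(shuffled)
  expect_equal(rep2$per_patient_rate, rep$per_patient_rate)
  expect_equal(rep2$per_vessel_rate, rep$per_vessel_rate)
})

test_that("toy and degenerate concordance inputs behave as specified", {
  toy <- data.frame(patient_id = c("p1", "p2"), mi = c(FALSE, TRUE),
                    artery = c("LAD", "RCA"), treated = c(1, 1),
                    matched = c(1, 1))
  rep <- concordance_report(toy)
  expect_equal(rep$per_patient_rate, 100)
  expect_equal(rep$per_vessel_rate, 100)
  # no treated vessels: explicit undefined (NA), not zero
  none <- data.frame(patient_id = "p1", mi = FALSE, artery = "LAD",
                     treated = 0, matched = NA)
  rep0 <- concordance_report(none)
  expect_true(is.na(rep0$per_vessel_rate))
  expect_equal(rep0$n_vessels_treated, 0)
})

test_that("site-level predictions translate into match flags", {
  pred <- data.frame(patient_id = c("p1", "p1", "p2"),
                     artery = c("LAD", "RCA", "LAD"),
                     site_id = c("LAD_p25", "RCA_p50", "LAD_p75"))
  obs <- data.frame(patient_id = c("p1", "p1", "p2"),
                    mi = FALSE, artery = c("LAD", "RCA", "LAD"),
                    treated = c(1, 1, 1),
                    pci_site_id = c("LAD_p25", "RCA_p75", "LAD_p75"))
  filled <- match_predictions(pred, obs)
  expect_equal(filled$matched, c(TRUE, FALSE, TRUE))
  rep <- concordance_report(filled)
  expect_equal(rep$per_vessel_rate, 100 * 2 / 3)
  expect_equal(rep$n_patients_matched, 1)  # p1 has one mismatched vessel
  obs_bad <- obs; obs_bad$patient_id[1] <- "ghost"
  expect_error(match_predictions(pred, obs_bad), "alignment")
})

test_that("packaged observations CSV matches the in-code fixture", {
  path <- system.file("extdata", "table1_observations.csv",
                      package = "ssindex")
  expect_true(nzchar(path))
  obs_csv <- read.csv(path, stringsAsFactors = FALSE)
  rep_csv <- concordance_report(obs_csv)
  rep_api <- concordance_report(table1_fixture()$observations)
  expect_equal(rep_csv$per_patient_rate, rep_api$per_patient_rate)
  expect_equal(rep_csv$per_vessel_rate, rep_api$per_vessel_rate)
  expect_equal(rep_csv$mi_count, rep_api$mi_count)
})

test_that("the full pipeline returns consistent records and ranking", {
  p <- perfusion_params()
  tree <- generate_tree(6)
  res <- run_ssi(tree, p)
  expect_equal(nrow(res$records), 9)
  expect_true(all(res$records$ssi > 0))
  expect_equal(as.character(res$ranking$per_artery$artery),
               c("RCA", "LAD", "LCX"))
  expect_equal(res$ranking$global$ssi, min(res$records$ssi))
})
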