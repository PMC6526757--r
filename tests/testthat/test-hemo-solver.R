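test_that("Poiseuille segment resistance matches an independent unit conversion", {
  # L = 10 mm, d = 3 mm, mu = 0.0035 Pa.s, converted by hand:
  # R_SI = 128 mu L / (pi d^4) in Pa.s/m^3; 1 mmHg.s/mL = 133.322e6 Pa.s/m^3
  r_si <- 128 * 0.0035 * 0.010 / (pi * 0.003^4)
  expect_equal(poiseuille_resistance(10, 3, 0.0035), r_si / 1.33322e8,
               tolerance = 1e-12)
  # linear in L, d^-4 law
  expect_equal(poiseuille_resistance(20, 3, 0.0035),
               2 * poiseuille_resistance(10, 3, 0.0035))
  expect_equal(poiseuille_resistance(10, 1.5, 0.0035),
               16 * poiseuille_resistance(10, 3, 0.0035), tolerance = 1e-12)
  # segment_resistance uses the mean diameter
  seg <- list(length_mm = 10, d_prox_mm = 3.5, d_dist_mm = 2.5)
  expect_equal(segment_resistance(seg, 0.0035),
               poiseuille_resistance(10, 3, 0.0035))
})

test_that("stenosis pressure drop has the Poiseuille zero-severity limit", {
  p <- perfusion_params()
  les0 <- lesion_geometry("s1", 0.5, 0, 10, 3)
  for (q in c(0.1, 1, 5)) {
    expect_equal(stenosis_pressure_drop(les0, q, p),
                 poiseuille_resistance(10, 3, p$mu) * q, tolerance = 1e-12)
  }
  expect_equal(stenosis_pressure_drop(les0, 0, p), 0)
  les50 <- lesion_geometry("s1", 0.5, 50, 10, 3)
  expect_equal(stenosis_pressure_drop(les50, 0, p), 0)
  expect_error(lesion_geometry("s1", 0.5, 100, 10, 3), "severity")
})

test_that("stenosis loss is a convex quadratic in flow with the stated coefficients", {
  p <- perfusion_params()
  les <- lesion_geometry("s1", 0.5, 50, 10, 3)
  q <- seq(0.1, 5, length.out = 30)
  dp <- vapply(q, function(qi) stenosis_pressure_drop(les, qi, p), numeric(1))
  expect_true(all(diff(dp) > 0))
  expect_true(all(diff(diff(dp)) > 0))  # convex increasing
  # quadratic coefficient from a polynomial fit matches the closed form
  fit <- stats::lm(dp ~ q + I(q^2))
  a_ref <- pi * 0.003^2 / 4
  area_ratio <- 4  # (d_ref/d_min)^2 at 50% diameter reduction
  b_expected <- 1.52 * (p$rho / 2) * (area_ratio - 1)^2 / a_ref^2 *
    1e-12 / 133.322
  expect_equal(unname(stats::coef(fit)[3]), b_expected, tolerance = 1e-8)
  # viscous coefficient: (A_ref/A_min)^2 times the lesion-length Poiseuille
  expect_equal(unname(stats::coef(fit)[2]),
               16 * poiseuille_resistance(10, 3, p$mu), tolerance = 1e-8)
})

test_that("single-segment solve reproduces the series-circuit closed form", {
  p <- perfusion_params()
  tree <- single_segment_tree()
  r_seg <- segment_resistance(tree$segments[1, ], p$mu)
  outlets <- uniform_outlets(tree, 20)
  st <- solve_steady(tree, outlets, list(), 90, p)
  q_expected <- 90 / (r_seg + 20)
  expect_equal(unname(st$segment_flows["s1"]), q_expected, tolerance = 1e-12)
  expect_equal(unname(st$node_pressures["s1"]), 90 - r_seg * q_expected,
               tolerance = 1e-12)
  expect_equal(compute_ffr(st, "s1"), (90 - r_seg * q_expected) / 90,
               tolerance = 1e-12)
})

test_that("a zero-severity lesion leaves the solved state unchanged", {
  p <- perfusion_params()
  tree <- generate_tree(5)
  alloc <- allocate_resistances(summed_lengths(tree, 1.5), p)
  outlets <- distribute_to_outlets(tree, alloc, p)
  base <- solve_steady(tree, outlets, list(), 90, p)
  site <- default_sites(tree)[[2]]
  les0 <- apply_stenosis(tree, site, 0)
  with0 <- solve_steady(tree, outlets, list(les0), 90, p)
  expect_equal(with0$node_pressures, base$node_pressures, tolerance = 1e-12)
  expect_equal(with0$segment_flows, base$segment_flows, tolerance = 1e-12)
})

test_that("mass is conserved at every junction after convergence", {
  p <- perfusion_params()
  for (seed in c(2, 9, 23)) {
    tree <- generate_tree(seed)
    alloc <- allocate_resistances(summed_lengths(tree, 1.5), p)
    outlets <- distribute_to_outlets(tree, alloc, p)
    site <- default_sites(tree)[[5]]
    les <- apply_stenosis(tree, site, 50)
    st <- solve_steady(tree, outlets, list(les), 90, p)
    imb <- junction_imbalance(tree, st, outlets, p$venous_pressure)
    expect_lt(max(abs(imb)), 1e-9)
    # pressures nonincreasing from root to leaf along every path
    for (leaf in terminal_segments(tree)) {
      path <- path_to_root(tree, leaf)
      pr <- c(st$inlet_pressure, st$node_pressures[path])
      expect_true(all(diff(pr) <= 1e-12))
    }
  }
})

test_that("solver agrees with an independent brute-force root-finder", {
  p <- perfusion_params()
  withr::local_seed(31)
  seeds <- sample.int(10000, 5)
  for (seed in seeds) {
    tree <- generate_tree(seed)
    alloc <- allocate_resistances(summed_lengths(tree, 1.5), p)
    outlets <- distribute_to_outlets(tree, alloc, p)
    site <- default_sites(tree)[[sample.int(9, 1)]]
    les <- apply_stenosis(tree, site, 50)
    st <- solve_steady(tree, outlets, list(les), 90, p)
    ref <- oracle_solve(tree, outlets, list(les), 90, p)
    expect_equal(st$node_pressures[names(ref)], ref, tolerance = 1e-8)
  }
})

test_that("collateral switching engages below the threshold and raises distal flow", {
  p_on <- perfusion_params(collateral = list(enabled = TRUE,
                                             threshold_mmHg = 60,
                                             resistance_factor = 1))
  p_off <- perfusion_params()
  tree <- single_segment_tree()
  alloc <- allocate_resistances(summed_lengths(tree, 1.5), p_on)
  out_on <- distribute_to_outlets(tree, alloc, p_on)
  out_off <- distribute_to_outlets(tree, alloc, p_off)
  site <- candidate_site("mid", "s1", 0.5)
  les <- apply_stenosis(tree, site, 85)   # deep pressure loss
  st_off <- solve_steady(tree, out_off, list(les), 90, p_off)
  st_on <- solve_steady(tree, out_on, list(les), 90, p_on)
  expect_lt(unname(st_off$node_pressures["s1"]), 60)  # below threshold
  # with an equal parallel collateral open, total outflow rises
  expect_gt(unname(st_on$segment_flows["s1"]),
            unname(st_off$segment_flows["s1"]))
})

test_that("quasi-static pulsatile solve matches steady behavior where it must", {
  p <- perfusion_params()
  tree <- forked_tree()
  alloc <- allocate_resistances(summed_lengths(tree, 1.5), p)
  outlets <- distribute_to_outlets(tree, alloc, p)
  # constant waveform: every sample equals the steady solve (build a
  # degenerate two-level waveform by hand)
  wf <- generate_waveform(90 + 1e-9, 90 - 1e-9, 60, 64)
  pr <- solve_pulsatile(tree, outlets, list(), wf, p)
  st <- solve_steady(tree, outlets, list(), 90, p)
  expect_equal(pr$mean_pressures, st$node_pressures, tolerance = 1e-8)
  # linear (lesion-free) network: cycle-mean flow equals flow at mean pressure
  wf2 <- generate_waveform(120, 80, 75, 64)
  pr2 <- solve_pulsatile(tree, outlets, list(), wf2, p)
  st2 <- solve_steady(tree, outlets, list(), mean(wf2$pressure), p)
  expect_equal(pr2$mean_flows, st2$segment_flows, tolerance = 1e-12)
  # with a lesion the loss is superlinear, so cycle-mean FFR cannot exceed
  # the FFR at the cycle-mean pressure (Jensen gap)
  les <- apply_stenosis(tree, candidate_site("m", "trunk", 0.5), 60)
  pr3 <- solve_pulsatile(tree, outlets, list(les), wf2, p)
  st3 <- solve_steady(tree, outlets, list(les), mean(wf2$pressure), p)
  expect_lte(compute_ffr(pr3, "trunk"), compute_ffr(st3, "trunk") + 1e-12)
})

test_that("throat wall shear follows the d^-3 law and the severity response is monotone", {
  mu <- 0.0035
  expect_equal(compute_wss_max(lesion_geometry("s", 0.5, 50, 10, 3), 0, mu), 0)
  les0 <- lesion_geometry("s", 0.5, 0, 10, 3)
  les50 <- lesion_geometry("s", 0.5, 50, 10, 3)
  q <- 2
  expect_equal(compute_wss_max(les50, q, mu) / compute_wss_max(les0, q, mu),
               8, tolerance = 1e-12)
  # numeric diameter input equals the lesion-free site value
  expect_equal(compute_wss_max(3, q, mu), compute_wss_max(les0, q, mu))
  # full pipeline: WSSmax strictly increases and FFR strictly decreases
  # with severity even though the flow falls (spot seeds; the acceptance
  # suite runs 100)
  p <- perfusion_params()
  for (seed in c(1, 17)) {
    tree <- generate_tree(seed)
    alloc <- allocate_resistances(summed_lengths(tree, 1.5), p)
    outlets <- distribute_to_outlets(tree, alloc, p)
    for (site in default_sites(tree)) {
      sw <- severity_sweep(tree, site, c(0, 25, 50), outlets, 90, p)
      expect_true(all(diff(sw$points$ffr) < 0))
      expect_true(all(diff(sw$points$wss_max_pa) > 0))
    }
  }
})

test_that("degenerate networks are rejected", {
  p <- perfusion_params()
  tree <- single_segment_tree()
  bad <- uniform_outlets(tree, Inf)
  expect_error(solve_steady(tree, bad, list(), 90, p), "degenerate")
})
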