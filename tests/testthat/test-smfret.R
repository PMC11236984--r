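test_that("co-localization matches mutual nearest neighbors within the radius", {
  a <- data.frame(frame = 1, x = c(0, 1000), y = 0)
  # identical sets all match
  m <- colocalize(a, a, radius = 50)
  expect_equal(nrow(m), 2)
  expect_true(all(m$dist_nm == 0))
  # 200 nm apart stays unmatched at the 150 nm radius
  b <- data.frame(frame = 1, x = 200, y = 0)
  expect_equal(nrow(colocalize(a[1, ], b, radius = 150)), 0)
  # nearest of two candidates wins
  one <- data.frame(frame = 1, x = 0, y = 0)
  two <- data.frame(frame = 1, x = c(100, 120), y = 0)
  got <- colocalize(one, two, radius = 150)
  expect_equal(got$idx_b, 1)
  expect_equal(got$dist_nm, 100)
  # each point matched at most once
  many_a <- data.frame(frame = 1, x = c(0, 10), y = 0)
  one_b <- data.frame(frame = 1, x = 5, y = 0)
  expect_equal(nrow(colocalize(many_a, one_b, radius = 150)), 1)
})

test_that("leakage is the mean acceptor/donor ratio of donor-only records", {
  r0 <- data.frame(I_Dex_Dem = c(100, 200), I_Dex_Aem = c(0, 0))
  expect_equal(estimate_leakage(r0), 0)
  r1 <- data.frame(I_Dex_Dem = c(100, 300), I_Dex_Aem = 0.11 * c(100, 300))
  expect_equal(estimate_leakage(r1), 0.11)
  r2 <- data.frame(I_Dex_Dem = c(100, 100), I_Dex_Aem = c(10, 12))
  expect_equal(estimate_leakage(r2), 0.11)
  expect_error(estimate_leakage(r2[0, ]), "no donor-only")
})

test_that("gamma is the quantum-yield x detection-efficiency ratio", {
  expect_equal(gamma_theoretical(0.5, 0.5, 2, 2), 1)
  expect_equal(gamma_theoretical(0.8, 0.7, 0.5, 0.5), 0.875)
  expect_error(gamma_theoretical(0, 0.5, 1, 1))
})

test_that("efficiency corrections follow the ALEX correction chain", {
  # identity limit: l = 0, Dir = 0, gamma = 1
  rec <- data.frame(I_Dex_Dem = 300, I_Dex_Aem = 100, I_Aex_Aem = 200)
  ident <- fret_efficiencies(rec, fret_corrections(0, 0, 1))
  expect_equal(ident$E_raw, 0.25)
  expect_equal(ident$E_PR, 0.25)
  expect_equal(ident$E, 0.25)

  # leakage and gamma corrections, hand-evaluated
  rec0 <- data.frame(I_Dex_Dem = 300, I_Dex_Aem = 100, I_Aex_Aem = 0)
  out <- fret_efficiencies(rec0, fret_corrections(0.11, 0, 0.8755))
  expect_equal(out$I_star, 67)
  expect_equal(out$E_PR, 67 / 367, tolerance = 1e-12)
  expect_equal(out$E, 0.2033, tolerance = 1e-3)

  # equal channels give stoichiometry 2/3
  eq <- data.frame(I_Dex_Dem = 150, I_Dex_Aem = 150, I_Aex_Aem = 150)
  expect_equal(fret_efficiencies(eq, fret_corrections(0, 0, 1))$S_raw, 2 / 3)

  # gamma = 1 leaves the proximity ratio untouched for any leakage
  set.seed(5)
  recs <- data.frame(I_Dex_Dem = stats::runif(20, 100, 500),
                     I_Dex_Aem = stats::runif(20, 10, 200),
                     I_Aex_Aem = stats::runif(20, 100, 500))
  g1 <- fret_efficiencies(recs, fret_corrections(0.11, 0.01, 1))
  expect_equal(g1$E, g1$E_PR)

  # zero donor-excitation signal is skipped
  z <- fret_efficiencies(data.frame(I_Dex_Dem = 0, I_Dex_Aem = 0,
                                    I_Aex_Aem = 100),
                         fret_corrections())
  expect_true(z$skipped)
  expect_true(is.na(z$E))
})

test_that("efficiency-distance conversion is exact and involutive", {
  expect_equal(distance_from_efficiency(0.5, r0 = 6.441), 6.441)
  expect_equal(round(distance_from_efficiency(0.178, 6.441), 1), 8.3)
  expect_equal(efficiency_from_distance(0), 1)
  expect_error(distance_from_efficiency(0), "E must")
  expect_error(distance_from_efficiency(1), "E must")
  e <- seq(0.01, 0.99, length.out = 50)
  expect_equal(efficiency_from_distance(distance_from_efficiency(e)), e,
               tolerance = 1e-12)
  r <- seq(1, 15, length.out = 50)
  expect_true(all(diff(efficiency_from_distance(r)) < 0))
})

test_that("dimer fraction follows the labeling-ratio-corrected count algebra", {
  res <- dimer_fraction(80, 80, 8)
  expect_equal(res$r_l, 0.5)
  expect_equal(res$c_l, 0.25)
  expect_equal(res$N_d, 32)
  expect_equal(res$N_m, 128)
  expect_equal(res$f_rel_D, 0.2)
  # equimolar labeling gives the factor-2 correction for mixed dimers
  expect_equal(1 / (2 * res$r_l * (1 - res$r_l)), 2)

  expect_equal(dimer_fraction(50, 70, 0)$f_rel_D, 0)
  expect_error(dimer_fraction(0, 0, 0), "no localizations")
  expect_error(dimer_fraction(100, 0, 0), "single-channel")
  expect_warning(dimer_fraction(10, 100, 20), "exceeds")
})

test_that("the closed-form fraction equals the explicit count composition", {
  # brute-force route: estimate dimers from the mixed-label count, replace
  # the label-homozygous false monomers, recompute f = N_d / (N_m + N_d)
  set.seed(6)
  for (i in 1:200) {
    n1 <- stats::runif(1, 10, 500)
    n2 <- stats::runif(1, 10, 500)
    nd12 <- stats::runif(1, 0, 0.2 * min(n1, n2))
    r_l <- n1 / (n1 + n2)
    c_l <- r_l * (1 - r_l)
    N_d <- 2 * nd12 / (2 * r_l * (1 - r_l))
    nd11 <- N_d / 2 * 2 * r_l^2
    nd22 <- N_d / 2 * 2 * (1 - r_l)^2
    N_m <- (n1 - nd11 - nd12) + (n2 - nd22 - nd12)
    f_explicit <- N_d / (N_m + N_d)
    f_closed <- suppressWarnings(dimer_fraction(n1, n2, nd12))$f_rel_D
    expect_equal(f_closed, f_explicit, tolerance = 1e-12)
  }
})

test_that("spurious dim acceptor populations are removed only below 5% share", {
  set.seed(7)
  main <- stats::rnorm(2000, 400, 60)
  spur <- stats::rnorm(60, 80, 25)      # 2.9% dim spur
  out <- filter_acceptor_population(c(spur, main))
  expect_lt(mean(out$keep[seq_along(spur)]), 0.2)   # spur dropped
  expect_gt(mean(out$keep[-seq_along(spur)]), 0.98) # main retained

  # a 40% low component is a real population and is retained
  big_low <- c(stats::rnorm(800, 150, 30), stats::rnorm(1200, 400, 60))
  out2 <- filter_acceptor_population(big_low)
  expect_true(all(out2$keep))

  # unimodal input: either branch must retain everything
  uni <- stats::rnorm(1000, 400, 60)
  out3 <- suppressWarnings(filter_acceptor_population(uni))
  expect_gt(mean(out3$keep), 0.95)
})

test_that("simulated ALEX data recover the dimer fraction and efficiency", {
  sim <- simulate_alex_experiment(n_receptors = 1000, f_true = 0.2,
                                  r_l = 0.5, E_true = 0.18, seed = 42)
  res <- analyze_alex_experiment(sim)
  expect_lt(abs(res$dimer$f_rel_D - 0.2), 0.03)
  expect_lt(abs(res$E_peak - 0.18), 0.03)
  expect_equal(res$leakage, 0.11, tolerance = 0.05)
})

test_that("FRET gating rejects density-driven false dimers that co-localization accepts", {
  sim0 <- simulate_alex_experiment(n_receptors = 3000, f_true = 0,
                                   r_l = 0.5, E_true = 0.18, field_um = 15,
                                   n_frames = 15, seed = 43)
  res0 <- analyze_alex_experiment(sim0)
  expect_lt(res0$dimer$f_rel_D, 0.02)
  expect_gt(res0$coloc_fraction, 10 * max(res0$dimer$f_rel_D, 0.005))
})
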