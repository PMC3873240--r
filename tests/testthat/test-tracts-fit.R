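test_that("noise-free self-consistency: the fit reproduces its own expectation", {
  g <- default_genome()
  bins <- length_bins(g)
  mh <- family_history("three_pulses_simultaneous",
                       c(t0 = 13, fNAT = 0.24, fEUR = 0.68))
  e <- expected_tract_counts(mh, bins, g, 132)
  obs <- structure(round(unclass(e)), class = "tract_histogram", bins = bins,
                   n_haplotypes = 132, genome = g)
  f <- fit_tracts_model(obs, "three_pulses_simultaneous", n_starts = 4, seed = 3)
  expect_equal(f$par[["t0"]], 13, tolerance = 0.02)
  expect_equal(f$par[["fNAT"]], 0.24, tolerance = 0.02)
  expect_equal(f$par[["fEUR"]], 0.68, tolerance = 0.02)
  # the running-best likelihood trace never decreases
  expect_false(is.unsorted(f$trace))
})

test_that("single-pulse parameters are recovered from simulated tracts", {
  g <- default_genome()
  bins <- length_bins(g)
  mh <- family_history("three_pulses_simultaneous",
                       c(t0 = 10, fNAT = 0.5, fEUR = 0.4))
  ts <- simulate_admixed_tracts(mh, g, 40, seed = 11)
  f <- fit_tracts_model(tract_histogram(ts, bins),
                        "three_pulses_simultaneous", n_starts = 6, seed = 12)
  expect_equal(f$par[["t0"]], 10, tolerance = 0.12)
  expect_equal(f$par[["fNAT"]], 0.5, tolerance = 0.05)
})

test_that("model selection prefers the simpler family absent a second pulse", {
  g <- default_genome()
  bins <- length_bins(g)
  mh <- family_history("three_pulses_simultaneous",
                       c(t0 = 12, fNAT = 0.3, fEUR = 0.6))
  ts <- simulate_admixed_tracts(mh, g, 50, seed = 21)
  obs <- tract_histogram(ts, bins)
  f1 <- fit_tracts_model(obs, "three_pulses_simultaneous", n_starts = 5, seed = 1)
  f2 <- fit_tracts_model(obs, "founding_plus_second_NAT_pulse",
                         n_starts = 5, seed = 2)
  sel <- select_model(list(f1, f2))
  expect_equal(sel$family, "three_pulses_simultaneous")
  expect_s3_class(attr(sel, "selection"), "data.frame")

  # fits on different data refuse to be compared
  ts2 <- simulate_admixed_tracts(mh, g, 50, seed = 22)
  f3 <- fit_tracts_model(tract_histogram(ts2, bins),
                         "three_pulses_simultaneous", n_starts = 2, seed = 3)
  expect_error(select_model(list(f1, f3)), "same observed")
})

test_that("bootstrap CIs cover the truth on a small recovery run", {
  g <- default_genome()
  mh <- family_history("three_pulses_simultaneous",
                       c(t0 = 10, fNAT = 0.5, fEUR = 0.4))
  ts <- simulate_admixed_tracts(mh, g, 40, seed = 31)
  f <- bootstrap_tracts_ci(ts, "three_pulses_simultaneous", n_boot = 12,
                           seed = 5, n_starts = 2)
  expect_true(all(c("lower", "upper") %in% colnames(f$ci)))
  # point estimate inside its own CI; interval is informative (neither
  # degenerate nor absurdly wide); single-replicate truth coverage is not
  # asserted (that is a calibration property, not a per-run guarantee)
  expect_lte(f$ci["t0", "lower"], f$par[["t0"]])
  expect_gte(f$ci["t0", "upper"], f$par[["t0"]])
  wid <- f$ci["t0", "upper"] - f$ci["t0", "lower"]
  expect_gt(wid, 0.01)
  expect_lt(wid, 5)
  expect_lt(abs(f$par[["t0"]] - 10), 1.5)
  expect_error(bootstrap_tracts_ci(ts, "three_pulses_simultaneous",
                                   n_boot = 1, seed = 1), "n_boot")
})
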