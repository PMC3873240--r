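test_that("single-pulse expected counts match the closed-form phase-type limit", {
  # independent oracle: for one founding pulse, tract lengths of an ancestry
  # with fraction f are exponential with rate (t-1)(1-f) per Morgan; expected
  # observed counts per chromosome follow from entry flux f(1-f)(t-1) plus
  # start/end censoring, all computable by quadrature
  g <- small_genome()
  t0 <- 9; f <- 0.3
  mh <- family_history("three_pulses_simultaneous",
                       c(t0 = t0, fNAT = f, fEUR = 1 - f))
  bins <- length_bins(g, n_bins = 12)
  got <- expected_tract_counts(mh, bins, g, 1)
  lam <- (t0 - 1) * (1 - f)
  rho <- f * (1 - f) * (t0 - 1)
  expect_cnt <- numeric(length(bins) - 1)
  for (ci in seq_len(nrow(g))) {
    C <- g$length_M[ci]
    for (b in seq_len(length(bins) - 1)) {
      a1 <- min(bins[b] / 100, C); b1 <- min(bins[b + 1] / 100, C)
      if (b1 > a1) {
        n_int <- stats::integrate(function(l) rho * (C - l) * lam * exp(-lam * l),
                                  a1, b1)$value
        n_rgt <- stats::integrate(function(l) rho * exp(-lam * l), a1, b1)$value
        n_lft <- stats::integrate(function(l) f * lam * exp(-lam * l), a1, b1)$value
        expect_cnt[b] <- expect_cnt[b] + n_int + n_rgt + n_lft
      }
      if (C >= bins[b] / 100 && C < bins[b + 1] / 100)
        expect_cnt[b] <- expect_cnt[b] + f * exp(-lam * C)
    }
  }
  expect_equal(unname(got[, "NAT"]), expect_cnt, tolerance = 1e-6)
})

test_that("a single-ancestry history yields one full-chromosome tract each", {
  g <- small_genome()
  mh <- family_history("three_pulses_simultaneous",
                       c(t0 = 8, fNAT = 1, fEUR = 0))
  bins <- length_bins(g)
  e <- expected_tract_counts(mh, bins, g, 4)
  expect_equal(sum(e[, "NAT"]), 4 * nrow(g), tolerance = 1e-9)
  expect_equal(sum(e[, c("EUR", "AFR")]), 0)
  # each count sits in the bin holding its chromosome length
  for (C in g$length_M) {
    b <- findInterval(100 * C, bins)
    expect_gte(e[b, "NAT"], 4 - 1e-9)
  }
})

test_that("length-weighted totals recover ancestry proportions (conservation)", {
  g <- default_genome()
  bins <- length_bins(g, n_bins = 200, min_cM = 1e-3)
  mids <- exp((log(bins[-1]) + log(bins[-length(bins)])) / 2) / 100
  for (mh in list(mxl_history(), clm_history(),
                  family_history("two_EUR_two_AFR_pulses",
                                 c(t0 = 16.9, fNAT = 0.15, fEUR = 0.65,
                                   t2 = 6.8, mEUR2 = 0.1, mAFR2 = 0.05)))) {
    e <- expected_tract_counts(mh, bins, g, 2)
    p <- ancestry_proportions(mh)
    for (a in c("NAT", "EUR", "AFR")) {
      got <- sum(e[, a] * mids)
      expect_equal(got, p[[a]] * total_morgans(g) * 2, tolerance = 0.01)
    }
  }
})

test_that("analytic model matches forward simulation at study scale", {
  # per-bin agreement within 3 Poisson standard deviations on >= 95% of
  # informative bins, for three distinct histories
  g <- default_genome()
  bins <- length_bins(g)
  cases <- list(
    list(mh = mxl_history(), n = 68),
    list(mh = clm_history(), n = 66),
    list(mh = family_history("two_EUR_two_AFR_pulses",
                             c(t0 = 16.9, fNAT = 0.15, fEUR = 0.65,
                               t2 = 6.8, mEUR2 = 0.1, mAFR2 = 0.05)),
         n = 55))
  for (k in seq_along(cases)) {
    ts <- simulate_admixed_tracts(cases[[k]]$mh, g, cases[[k]]$n, seed = 40 + k)
    obs <- tract_histogram(ts, bins)
    e <- expected_tract_counts(cases[[k]]$mh, bins, g, 2 * cases[[k]]$n)
    sel <- e >= 5
    z <- (unclass(obs)[sel] - e[sel]) / sqrt(e[sel])
    expect_gte(mean(abs(z) <= 3), 0.95)
  }
})

test_that("Poisson bin likelihood follows the Poisson pmf", {
  g <- genome_map(1.0)
  bins <- c(1, 10, 100)
  mk <- function(v) structure(matrix(c(v, 0, 0, 0, 0), 2, 3,
                                     dimnames = list(NULL, c("NAT", "EUR", "AFR"))),
                              class = "tract_histogram", bins = bins,
                              n_haplotypes = 2, genome = g)
  obs <- mk(c(3, 7)); expd <- mk(c(2.5, 8.1))
  expect_equal(poisson_loglik(obs, expd),
               dpois(3, 2.5, log = TRUE) + dpois(7, 8.1, log = TRUE))
  # all-zero observed against all-zero expected contributes zero
  expect_equal(poisson_loglik(mk(c(0, 0)), mk(c(0, 0))), 0)
  # expected zero with observed support is impossible
  expect_equal(poisson_loglik(mk(c(1, 0)), mk(c(0, 0))), -Inf)
  # integer-valued expectation maximizes the likelihood at itself
  o <- mk(c(4, 9))
  expect_gt(poisson_loglik(o, mk(c(4, 9))), poisson_loglik(o, mk(c(5, 9))))
  expect_gt(poisson_loglik(o, mk(c(4, 9))), poisson_loglik(o, mk(c(4, 7))))
})
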