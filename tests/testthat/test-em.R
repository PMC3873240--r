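test_that("genotype probabilities follow two independent Bernoulli haplotypes", {
  f <- list(NAT = 0, EUR = 1)
  expect_equal(genotype_prob(1, c("NAT", "EUR"), f), 1)
  expect_equal(genotype_prob(2, c("NAT", "NAT"), list(NAT = 0.3, EUR = 0)), 0.09)
  # normalization over G at random frequencies
  set.seed(1)
  for (k in 1:5) {
    f2 <- list(NAT = runif(1), EUR = runif(1))
    tot <- sum(vapply(0:2, genotype_prob, 0, A = c("NAT", "EUR"), f = f2))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
  expect_error(genotype_prob(3, c("NAT", "EUR"), f), "genotype")
})

test_that("site posteriors match brute-force grid summation", {
  # two individuals: one NAT/NAT with G=2, one NAT/EUR with G=1
  grid <- frequency_grid(41)
  sp <- site_posterior(c(2, 1), c("NAT/NAT", "EUR/NAT"), grid)
  f <- grid$f
  joint <- outer(f, f, function(fN, fE)
    fN^2 * (fN * (1 - fE) + fE * (1 - fN)))   # rows NAT, cols EUR
  pN <- rowSums(joint); pN <- pN / sum(pN)
  pE <- colSums(joint); pE <- pE / sum(pE)
  expect_equal(sp$posterior$NAT, pN, tolerance = 1e-12)
  expect_equal(sp$posterior$EUR, pE, tolerance = 1e-12)
  expect_equal(sp$mean[["NAT"]], sum(f * pN), tolerance = 1e-12)
  # all NAT/NAT homozygous derived: posterior concentrates at 1
  sp2 <- site_posterior(rep(2, 8), rep("NAT/NAT", 8), frequency_grid(101))
  expect_gt(sp2$mean[["NAT"]], 0.9)
  expect_error(site_posterior(NA, NA), "no individual")
})

test_that("HPD intervals behave on point-mass and flat posteriors", {
  f <- seq(0, 1, length.out = 101)
  p <- numeric(101); p[51] <- 1
  expect_equal(hpd_interval(p, f), c(0.5, 0.5))
  flat <- rep(1, 101)
  ci <- hpd_interval(flat, f, 0.95)
  expect_equal(ci[2] - ci[1], 0.95, tolerance = 0.02)
  expect_equal(frequency_ci(flat, f)$width, ci[2] - ci[1])
})

test_that("EM increases the likelihood and matches sample frequencies", {
  tb <- pseudo_admixed_panel(n_ind = 40, n_sites = 1200, seed = 3)
  fit <- em_estimate(tb, grid = 101, iters = 12)
  expect_false(is.unsorted(fit$loglik_trace))
  truth <- attr(tb, "truth")
  e <- fit$estimates
  for (a in c("EUR", "AFR")) {
    d <- e[e$ancestry == a, ]
    sf <- if (a == "EUR") truth$sampE[d$site] else truth$sampA[d$site]
    outside <- sf < d$lower - 1e-9 | sf > d$upper + 1e-9
    expect_lte(mean(outside), 0.005)
    # point estimates track the truth
    expect_gt(stats::cor(d$mean, sf), 0.9)
  }
})

test_that("estimates are invariant to phase-switch errors", {
  tb <- pseudo_admixed_panel(n_ind = 20, n_sites = 400, seed = 4)
  fit0 <- em_estimate(tb, grid = 51, iters = 5)
  tb_sw <- inject_phase_switch_errors(tb, 0.05, seed = 9)
  expect_identical(tb_sw$G, tb$G)
  fit1 <- em_estimate(tb_sw, grid = 51, iters = 5)
  expect_identical(fit0$estimates, fit1$estimates)
})

test_that("the monomorphic correction recovers undetected rare mass", {
  f <- seq(0, 1, length.out = 101)
  prior <- rep(1 / 101, 101)
  expect_equal(monomorphic_correction(prior, 40, 0, f)$prior, prior)
  # simulation oracle: true prior is 1/x-shaped; detection removes rare
  # sites; the corrected prior is closer to the truth in KL divergence
  set.seed(6)
  lo <- 0.01
  truef <- lo * ((1 - lo) / lo)^runif(40000)
  k <- 20
  detected <- rbinom(length(truef), k, truef) > 0
  brks <- c(f - 1 / 200, 1 + 1 / 200)
  p_true <- as.numeric(table(cut(truef, brks))) / length(truef)
  p_obs <- as.numeric(table(cut(truef[detected], brks))) / sum(detected)
  n0 <- sum(!detected)
  corr <- monomorphic_correction(p_obs, k, n0, f, n_poly = sum(detected))$prior
  kl <- function(p, q) {
    s <- p > 0
    sum(p[s] * log(p[s] / pmax(q[s], 1e-12)))
  }
  expect_lt(kl(p_true, corr), kl(p_true, p_obs))
  expect_error(monomorphic_correction(p_obs, k, -1, f), "n0")
})

test_that("frequency-difference bootstrap is calibrated and powered", {
  set.seed(7)
  n <- 60
  A <- rep("EUR/NAT", n)
  mk <- function(fN, fE) rbinom(n, 1, fN) + rbinom(n, 1, fE)
  # identical panels: difference crosses zero about half the time
  G1 <- mk(0.4, 0.2); G2 <- mk(0.4, 0.2)
  r0 <- ancestry_freq_difference_test(G1, A, G2, A, "NAT", n_boot = 100, seed = 1)
  expect_gt(r0$p_raw, 0.05)
  # planted large difference: significant after Bonferroni
  G3 <- mk(0.9, 0.2); G4 <- mk(0.1, 0.2)
  r1 <- ancestry_freq_difference_test(G3, A, G4, A, "NAT", n_boot = 400,
                                      seed = 2, n_tests = 10)
  expect_lt(r1$p_bonferroni, 0.05)
  expect_error(ancestry_freq_difference_test(G1, A, G2, A, "NAT",
                                             n_boot = 10, n_tests = 5),
               "n_boot too small")
})
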