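test_that("composite likelihood profiles theta and matches the Poisson pmf", {
  m <- split_model(N_anc = 10000, T_found = 600, N_bot = 1000,
                   sizes = c(A = 5000, B = 20000), T1 = 400)
  expd <- expected_joint_sfs(m, c(A = 8, B = 8))
  th <- 700
  obs <- lapply(expd, function(s) joint_sfs(th * unclass(s), pops = attr(s, "pops")))
  ll <- composite_loglik(obs, m)
  expect_equal(attr(ll, "theta"), th, tolerance = 1e-6)
  # hand-computed Poisson log-likelihood over unmasked cells
  e1 <- expd[[1]]; o1 <- obs[[1]]
  ok <- !attr(o1, "mask")
  mu <- th * e1[ok]; x <- o1[ok]
  expect_equal(as.numeric(ll), sum(x * log(mu) - mu - lgamma(x + 1)),
               tolerance = 1e-6)
  # doubling the data doubles theta-hat but the fit location is unchanged
  obs2 <- lapply(obs, function(s) joint_sfs(2 * unclass(s), pops = attr(s, "pops")))
  expect_equal(attr(composite_loglik(obs2, m), "theta"), 2 * th,
               tolerance = 1e-6)
})

test_that("self-generated spectra are maximized at the truth", {
  m <- split_model(N_anc = 10000, T_found = 600, N_bot = 1000,
                   sizes = c(A = 5000, B = 20000), T1 = 400)
  obs <- lapply(expected_joint_sfs(m, c(A = 8, B = 8)),
                function(s) joint_sfs(500 * unclass(s), pops = attr(s, "pops")))
  ll0 <- as.numeric(composite_loglik(obs, m))
  worse <- split_model(N_anc = 10000, T_found = 600, N_bot = 1000,
                       sizes = c(A = 8000, B = 20000), T1 = 300)
  expect_gt(ll0, as.numeric(composite_loglik(obs, worse)))
})

test_that("noise-free three-population recovery is exact to tolerance", {
  m <- split_model(N_anc = 12500, T_found = 533, N_bot = 125,
                   sizes = c(MXL = 64000, CLM = 4000, PUR = 2000),
                   T1 = 420, T2 = 403, order = "MXL")
  obs <- lapply(expected_joint_sfs(m, c(MXL = 20, CLM = 12, PUR = 8),
                                   list(extrap = FALSE, grids = 40L)),
                function(s) joint_sfs(5e4 * unclass(s), pops = attr(s, "pops")))
  f <- fit_split_model(obs, m, orderings = "MXL", n_starts = 1, seed = 2,
                       opt_grid = 40L, engine_opts = list(grids = 40L))
  expect_equal(unname(f$par[c("tau_found", "tau1", "tau2")]),
               unname(fitted_diffusion_par(m)[c("tau_found", "tau1", "tau2")]),
               tolerance = 0.03)
  expect_equal(f$par[["nu_MXL"]], 5.12, tolerance = 0.08)
})

test_that("physical calibration scales linearly with the anchor", {
  f <- structure(list(par = c(tau_found = 0.02, nu_bot = 0.01, tau1 = 0.016,
                              tau2 = 0.015, nu_MXL = 5, nu_CLM = 0.3,
                              nu_PUR = 0.15),
                      theta = 4000), class = "demography_fit")
  cal <- calibrate_physical(f, 16000, 30, L_callable = 1e7)
  expect_equal(unname(cal$times_years["T_found"]), 16000)
  cal2 <- cal$rescale(32000)
  expect_equal(cal2$times_years, 2 * cal$times_years)
  expect_equal(cal2$sizes, 2 * cal$sizes)
  expect_equal(cal2$mu, cal$mu / 2)
  # round-trip re-anchor is the identity
  expect_equal(cal$rescale(16000)$sizes, cal$sizes)
  expect_error(calibrate_physical(f, 16000, 30, 0), "L_callable")
})

test_that("block bootstrap returns CIs, orderings and the T2/T1 ratio", {
  m <- split_model(N_anc = 10000, T_found = 500, N_bot = 500,
                   sizes = c(A = 8000, B = 3000, C = 2000),
                   T1 = 400, T2 = 380, order = "A")
  sim <- simulate_split_sfs(m, c(A = 12, B = 8, C = 8), n_loci = 3e4,
                            seed = 5, scale = 4)
  prs <- sfs_pairs(sim$counts, c(A = 12, B = 8, C = 8))
  f <- fit_split_model(prs, m, orderings = "A", n_starts = 1, seed = 6,
                       opt_grid = 30L, engine_opts = list(grids = 30L),
                       polish = FALSE)
  bs <- bootstrap_demography(sim$counts, c(A = 12, B = 8, C = 8), f,
                             n_boot = 2, n_blocks = 10, seed = 7,
                             orderings = f$order, opt_grid = 30L,
                             engine_opts = list(grids = 30L), polish = FALSE)
  expect_true(all(c("lower", "upper") %in% colnames(bs$ci)))
  expect_length(bs$t2_t1, 2)
  expect_true(all(bs$t2_t1 <= 1 + 1e-9, na.rm = TRUE))
  expect_error(bootstrap_demography(sim$counts, c(A = 12, B = 8, C = 8), f,
                                    n_boot = 2, n_blocks = 1), "blocks")
})

test_that("a fixed recent bottleneck of severity one changes nothing", {
  m <- split_model(N_anc = 10000, T_found = 500, N_bot = 500,
                   sizes = c(A = 8000, B = 3000), T1 = 400, order = "A")
  obs <- lapply(expected_joint_sfs(m, c(A = 10, B = 10),
                                   list(extrap = FALSE, grids = 30L)),
                function(s) joint_sfs(2e4 * unclass(s), pops = attr(s, "pops")))
  f <- fit_split_model(obs, m, orderings = "A", n_starts = 1, seed = 3,
                       opt_grid = 30L, engine_opts = list(grids = 30L),
                       polish = FALSE)
  sens <- bottleneck_sensitivity(
    f, list(pop = "A", T_start = 15, T_end = 5, severity = 1),
    n_starts = 1, seed = 4, opt_grid = 30L, engine_opts = list(grids = 30L),
    polish = FALSE)
  expect_equal(sens$size_ratio, 1, tolerance = 0.05)
  expect_error(bottleneck_sensitivity(f, list(pop = "A", T_start = 15)),
               "fix")
})
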