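test_that("the equilibrium spectrum reproduces theta/i within one percent", {
  e <- expected_equilibrium_sfs(30)
  i <- 1:29
  expect_lt(max(abs(e[i + 1] * i - 1)), 0.03)
  # interior classes are tighter still
  expect_lt(max(abs(e[3:28] * (2:27) - 1)), 0.01)
})

test_that("expected spectra are linear in theta and stationary at equilibrium", {
  opts <- utils::modifyList(default_engine_opts(), list())
  G <- 40L
  P0 <- stationary_mass(G, theta = 1)
  # stationarity: evolving the stationary state leaves the sample SFS fixed
  P1 <- evolve_1d(P0, 0.05, 1, G, opts, theta = 1)
  s0 <- sample_1d(P0, 15, G); s1 <- sample_1d(P1, 15, G)
  expect_equal(s1[2:15], s0[2:15], tolerance = 1e-3)
  # linearity: doubling theta doubles everything
  P2 <- stationary_mass(G, theta = 2)
  expect_equal(2 * P0, P2, tolerance = 1e-12)
})

test_that("zero divergence gives exchangeable, ancestral-margin spectra", {
  m <- split_model(N_anc = 10000, T_found = 500, N_bot = 10000, r = 1,
                   sizes = c(A = 10000, B = 10000), T1 = 1e-9)
  sp <- expected_joint_sfs(m, c(A = 12, B = 12))[[1]]
  M <- unclass(sp)
  expect_lt(max(abs(M - t(M))) / max(M), 1e-10)
  # margins equal the single-population equilibrium
  marg <- rowSums(M)
  eq <- expected_equilibrium_sfs(12)
  expect_equal(as.numeric(marg[2:12]), as.numeric(unclass(eq)[2:12]),
               tolerance = 0.02)
})

test_that("projection commutes with expectation", {
  m <- split_model(N_anc = 10000, T_found = 600, N_bot = 1000,
                   sizes = c(A = 5000, B = 20000), T1 = 400)
  big <- expected_joint_sfs(m, c(A = 16, B = 16))[[1]]
  small <- expected_joint_sfs(m, c(A = 8, B = 8))[[1]]
  proj <- project_sfs(big, c(8, 8))
  ok <- !attr(small, "mask")
  expect_equal(proj[ok], small[ok], tolerance = 0.02)
})

test_that("engine agrees with forward Wright-Fisher simulation", {
  # chi-square per-entry agreement on pooled classes at 1e5 standing loci
  m <- split_model(N_anc = 10000, T_found = 500, N_bot = 2000,
                   sizes = c(A = 8000, B = 3000), T1 = 350)
  sim <- simulate_split_sfs(m, c(A = 12, B = 12), n_loci = 1e5, seed = 9,
                            scale = 4)
  obs <- sim$sfs
  expd <- expected_joint_sfs(m, c(A = 12, B = 12))[[1]]
  ok <- !attr(obs, "mask")
  theta <- sum(obs[ok]) / sum(expd[ok])
  mu <- theta * expd[ok]; x <- obs[ok]
  keep <- mu >= 5
  chi <- sum((x[keep] - mu[keep])^2 / mu[keep])
  df <- sum(keep) - 1
  expect_gt(pchisq(chi, df, lower.tail = FALSE), 0.01)
})
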