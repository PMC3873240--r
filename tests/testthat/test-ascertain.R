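# small panel with controlled ancestry states per site
asc_panel <- function() {
  # 6 sites x 4 individuals; ancestry states fixed per individual
  A1 <- matrix(rep(c("NAT", "NAT", "EUR", "EUR"), each = 6), 6)
  A2 <- matrix(rep(c("NAT", "EUR", "EUR", "AFR"), each = 6), 6)
  G <- matrix(0L, 6, 4)
  G[1, 1] <- 1L           # site 1: derived only in the NAT/NAT diploid
  G[2, 2] <- 1L           # site 2: derived in a NAT/EUR diploid
  G[3, 3] <- 2L           # site 3: derived only in EUR/EUR -> non-NAT
  G[4, 1] <- 1L; G[4, 4] <- 1L  # site 4: NAT/NAT but also EUR/AFR -> non-NAT
  G[5, 1] <- 2L           # site 5: outgroup will carry it
  # site 6: monomorphic
  sites <- data.frame(chrom = "chr1", pos_cM = 1:6)
  ancestry_genotype_table(sites, G, A1, A2)
}

test_that("negative ascertainment removes outgroup and non-NAT observations", {
  tb <- asc_panel()
  og <- c(0, 0, 0, 0, 3, 0)    # outgroup carries site 5
  res <- negative_ascertainment_filter(tb, list(og))
  expect_equal(res$sites, c(1L, 2L))
  expect_true(res$removed_by_outgroup[5])
  expect_true(res$removed_by_nonNAT[3] && res$removed_by_nonNAT[4])
  # NAT haplotype bookkeeping: 4 individuals carry 2+1+0+0 NAT haplotypes
  expect_equal(unname(res$nat_n[1, 1]), 3L)
  expect_equal(unname(res$nat_d[, 1]), c(1L, 1L))
})

test_that("the filter is idempotent", {
  tb <- asc_panel()
  og <- list(c(0, 0, 0, 0, 3, 0))
  r1 <- negative_ascertainment_filter(tb, og)
  # re-filter a table restricted to the retained sites
  keep <- r1$sites
  tb2 <- ancestry_genotype_table(tb$sites[keep, ],
                                 tb$G[keep, , drop = FALSE],
                                 tb$A1[keep, , drop = FALSE],
                                 tb$A2[keep, , drop = FALSE])
  r2 <- negative_ascertainment_filter(tb2, list(og[[1]][keep]))
  expect_equal(length(r2$sites), length(r1$sites))
  expect_equal(r2$nat_d, r1$nat_d)
})

test_that("larger outgroup panels retain fewer sites (nested monotonicity)", {
  m <- split_model(N_anc = 10000, T_found = 403, N_bot = 10000, r = 1,
                   sizes = c(p1 = 10000, p2 = 10000), T1 = 403,
                   outgroup = list(T_split = 550, N = 10000))
  sim <- simulate_split_sfs(m, c(p1 = 10, p2 = 10), n_loci = 2e4, seed = 3,
                            n_outgroup_diploid = 100, scale = 8)
  # nested panels: outgroup observation indicators for 10 vs 100 diploids
  # are coupled through the same frequencies; emulate by thinning
  set.seed(1)
  segregating <- rowSums(sim$counts) > 0
  kept_small <- segregating & !(sim$outgroup_derived & runif(length(segregating)) < 0.6)
  kept_big <- segregating & !sim$outgroup_derived
  expect_lte(sum(kept_big), sum(kept_small))
  # ascertained spectrum is depleted of old variation: retained variants are
  # rarer than removed ones
  frq <- rowSums(sim$counts) / 20
  expect_lt(mean(frq[segregating & !sim$outgroup_derived]),
            mean(frq[segregating & sim$outgroup_derived]))
})

test_that("mock European panels quantify singleton leakage", {
  set.seed(5)
  n_sites <- 400; n_ind <- 20
  # half the individuals are EUR/EUR, half NAT/NAT
  A1 <- cbind(matrix("EUR", n_sites, 10), matrix("NAT", n_sites, 10))
  A2 <- A1
  fE <- rep(0.03, n_sites)                 # private European rare variation
  G <- cbind(matrix(rbinom(n_sites * 10, 2, fE), n_sites),
             matrix(0L, n_sites, 10))
  tb <- ancestry_genotype_table(data.frame(chrom = "chr1", pos_cM = 1:n_sites),
                                G, A1, A2)
  bias <- singleton_bias_estimate(tb, list(), n_mock = 6, n_rep = 4, seed = 2)
  # leakage dominated by singletons
  expect_gt(bias$correction[1], max(bias$correction[-1]))
  # an outgroup identical to the European source drives leakage to zero
  og <- rowSums(G)
  bias0 <- singleton_bias_estimate(tb, list(og), n_mock = 6, n_rep = 4, seed = 2)
  expect_equal(sum(bias0$correction), 0)
  expect_error(singleton_bias_estimate(tb, list(), n_mock = 11),
               "insufficient EUR/EUR")
})

test_that("the ascertained NAT spectrum projects, conserves and corrects", {
  tb <- asc_panel()
  res <- negative_ascertainment_filter(tb, list(c(0, 0, 0, 0, 3, 0)))
  s <- ascertained_nat_sfs(res, c(panel = 2L))
  # conservation: total mass equals the retained variant count
  expect_equal(sum(s), length(res$sites), tolerance = 1e-9)
  expect_error(ascertained_nat_sfs(res, c(panel = 50L)), "exceeds")
  # subtracting a singleton correction reduces the singleton class only
  corr <- structure(list(correction = c(0.5, rep(0, 3)), n_mock = 2L),
                    class = "ascertainment_bias")
  s2 <- ascertained_nat_sfs(res, c(panel = 2L), corr)
  expect_lt(s2[2], s[2])
  # empty result gives the zero spectrum
  res0 <- res; res0$sites <- integer(0)
  res0$nat_n <- res0$nat_n[0, , drop = FALSE]
  res0$nat_d <- res0$nat_d[0, , drop = FALSE]
  expect_equal(sum(ascertained_nat_sfs(res0, c(panel = 2L))), 0)
})
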