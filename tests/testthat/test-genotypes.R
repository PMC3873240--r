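test_that("genotypes follow the local ancestry's allele frequencies", {
  tr <- toy_tracts()   # hap1: NAT to 30 then EUR; hap2: EUR to 70 then AFR
  sites <- data.frame(chrom = "chr1", pos_cM = c(10, 50, 80))
  f <- ancestral_frequencies(cbind(NAT = c(1, 1, 1), EUR = c(0, 0, 0),
                                   AFR = c(1, 1, 1)))
  tb <- assign_genotypes(tr, f, sites, seed = 1)
  # site at 10 cM: NAT/EUR -> exactly one derived copy
  expect_equal(tb$G[1, 1], 1L)
  # site at 50 cM: EUR/EUR -> zero copies
  expect_equal(tb$G[2, 1], 0L)
  # site at 80: EUR/AFR -> one
  expect_equal(tb$G[3, 1], 1L)
  # all-zero frequencies give a monomorphic table
  f0 <- ancestral_frequencies(matrix(0, 3, 3,
                                     dimnames = list(NULL, c("NAT", "EUR", "AFR"))))
  tb0 <- assign_genotypes(tr, f0, sites, seed = 2)
  expect_true(all(tb0$G == 0))
  expect_error(assign_genotypes(tr, f, data.frame(chrom = "chr1", pos_cM = 150),
                                seed = 1), "inside the genome")
})

test_that("realized sample frequencies match the mixture expectation", {
  g <- genome_map(2.0)
  mh <- family_history("three_pulses_simultaneous",
                       c(t0 = 12, fNAT = 0, fEUR = 0.5))
  tr <- simulate_admixed_tracts(mh, g, 40, seed = 3, n_pop = 400)
  n_sites <- 400
  sites <- data.frame(chrom = "chr1", pos_cM = seq(1, 199, length.out = n_sites))
  fr <- simulate_ancestral_frequencies(n_sites, seed = 4)
  tb <- assign_genotypes(tr, fr, sites, seed = 5)
  mix <- 0.5 * (fr[, "EUR"] + fr[, "AFR"])
  realized <- rowMeans(tb$G) / 2
  expect_equal(mean(realized - mix), 0, tolerance = 0.02)
  expect_gt(stats::cor(realized, mix), 0.9)
})

test_that("phase-switch errors swap haplotype assignment but not summaries", {
  tb <- pseudo_admixed_panel(n_ind = 10, n_sites = 200, seed = 6)
  # rate zero: identity
  expect_identical(inject_phase_switch_errors(tb, 0, seed = 1), tb)
  # rate one: switch state alternates every site
  sw <- inject_phase_switch_errors(tb, 1, seed = 1)
  expect_identical(sw$G, tb$G)
  n_s <- nrow(tb$G)
  odd <- seq(1, n_s, by = 2)   # state is "switched" at odd rows
  expect_identical(sw$H1[odd, ], tb$H2[odd, ])
  expect_identical(sw$H2[odd, ], tb$H1[odd, ])
  even <- seq(2, n_s, by = 2)
  expect_identical(sw$H1[even, ], tb$H1[even, ])
  expect_error(inject_phase_switch_errors(tb, 1.5, seed = 1), "switch_rate")
})
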