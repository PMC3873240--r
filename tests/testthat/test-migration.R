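test_that("migration histories validate their invariants", {
  m <- matrix(c(0.5, 0.4, 0.1), 1, 3,
              dimnames = list("12", c("NAT", "EUR", "AFR")))
  mh <- migration_history(m)
  expect_s3_class(mh, "migration_history")
  expect_equal(attr(mh, "founding"), 12L)

  bad <- m; bad[1, 1] <- 0.2
  expect_error(migration_history(bad), "founding")
  expect_error(migration_history(matrix(0.5, 1, 3,
    dimnames = list("1", c("NAT", "EUR", "AFR")))), "invalid-history")
})

test_that("ancestry proportions follow the dilution recursion", {
  # single pulse: proportions are the founding fractions
  mh <- family_history("three_pulses_simultaneous",
                       c(t0 = 10, fNAT = 0.3, fEUR = 0.6))
  expect_equal(unname(ancestry_proportions(mh)[c("NAT", "EUR", "AFR")]),
               c(0.3, 0.6, 0.1), tolerance = 1e-12)
  # later pulse replaces: founding fractions diluted by (1 - m), plus m
  mh2 <- family_history("founding_plus_second_NAT_pulse",
                        c(t0 = 10, fNAT = 0.3, fEUR = 0.6, t2 = 4, mNAT2 = 0.1))
  p <- ancestry_proportions(mh2)
  expect_equal(unname(p["NAT"]), 0.3 * 0.9 + 0.1, tolerance = 1e-12)
  expect_equal(sum(p), 1, tolerance = 1e-12)
})

test_that("pulse discretization interpolates between neighbouring generations", {
  # onset at 13.02 generations: founding 14 generations ago with a
  # near-complete replacement (0.98) at 13
  d <- discretize_pulse(13.02, 1)
  expect_equal(d$gen, c(14L, 13L))
  expect_equal(d$weight, c(1, 0.98), tolerance = 1e-12)

  # integer onset: a single row, no second pulse
  d13 <- discretize_pulse(13, 1)
  expect_equal(nrow(d13), 1L)
  expect_equal(d13$gen, 13L)

  # midpoint: replacement weight one half
  expect_equal(discretize_pulse(13.5, 1)$weight[2], 0.5, tolerance = 1e-12)

  expect_error(discretize_pulse(1, 1), "exceed 1 generation")
  expect_error(discretize_pulse(0.5, 1), "exceed 1 generation")
})

test_that("discretization preserves the total ancestry contribution exactly", {
  for (tt in c(7.3, 4.8, 9.99)) {
    for (mag in c(1, 0.25, 0.03)) {
      d <- discretize_pulse(tt, mag)
      # net contribution after applying the older pulse then the newer one
      net <- d$weight[1] * (1 - d$weight[2]) + d$weight[2]
      expect_equal(net, mag, tolerance = 1e-12)
    }
  }
  # the discretized single-pulse history reproduces the pulse proportions
  mh <- family_history("three_pulses_simultaneous",
                       c(t0 = 13.02, fNAT = 0.24, fEUR = 0.68))
  expect_equal(unname(ancestry_proportions(mh)[c("NAT", "EUR", "AFR")]),
               c(0.24, 0.68, 0.08), tolerance = 1e-9)
})

test_that("family builders enforce parameter bounds", {
  expect_error(family_history("founding_plus_continuing",
    c(t0 = 10, fNAT = 0.7, fEUR = 0.6, mEUR = 0.01, mNAT = 0.01)),
    "fractions")
  expect_error(family_history("founding_plus_second_NAT_pulse",
    c(t0 = 10, fNAT = 0.3, fEUR = 0.5, t2 = 11, mNAT2 = 0.05)),
    "predate")
})
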