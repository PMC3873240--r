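# build an ancestry background and plant IBD segments on it
planted_world <- function(n_ind = 8, seed = 1) {
  g <- genome_map(1.0)
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_ind)) {
    for (h in 1:2) {
      # two tracts: EUR then NAT, boundary at a random midpoint
      b <- runif(1, 30, 70)
      rows[[length(rows) + 1L]] <- data.frame(
        ind = i, hap = h, chrom = "chr1",
        start_cM = c(0, b), end_cM = c(b, 100),
        ancestry = c("EUR", "NAT"), stringsAsFactors = FALSE)
    }
  }
  tract_set(do.call(rbind, rows), g, n_diploid = n_ind)
}

test_that("IBD segments are annotated with origin, mismatch and switches", {
  tr <- planted_world()
  # segment inside the EUR side of both haplotypes: clean EUR, no switches
  seg <- ibd_set(data.frame(id1 = 1, hap1 = 1, id2 = 2, hap2 = 1,
                            chrom = "chr1", start_cM = 0, end_cM = 25,
                            length_cM = 25, group = "within"))
  rec <- annotate_ibd_ancestry(seg, tr)
  expect_equal(rec$origin, "EUR")
  expect_equal(rec$mismatch, 0)
  expect_equal(rec$switches, 0L)

  # segment spanning both haplotypes' EUR->NAT boundaries: has switches and
  # some mismatch stretch between the two boundaries
  seg2 <- ibd_set(data.frame(id1 = 1, hap1 = 1, id2 = 2, hap2 = 1,
                             chrom = "chr1", start_cM = 10, end_cM = 90,
                             length_cM = 80, group = "within"))
  rec2 <- annotate_ibd_ancestry(seg2, tr)
  expect_gte(rec2$switches, 1L)
  expect_gt(rec2$mismatch, 0)
  expect_lt(rec2$mismatch, 1)
})

test_that("switch density trend detects a planted signal and not a null", {
  set.seed(4)
  n <- 80
  len <- runif(n, 5, 50)
  mk_rec <- function(switches) {
    data.frame(id1 = sample(20, n, TRUE), id2 = sample(21:40, n, TRUE),
               hap1 = 1, hap2 = 1, chrom = "chr1", start_cM = 0,
               end_cM = len, length_cM = len, origin = "EUR",
               mismatch = 0, switches = switches, covered = TRUE)
  }
  # planted: density grows with length
  planted <- mk_rec(rpois(n, 0.02 * len^2 / 10 + 0.01 * len))
  res <- switch_density_trend(planted, n_boot = 200, seed = 1)
  expect_gt(res$slope, 0)
  expect_lt(res$p, 0.05)
  # null: switch counts proportional to length (flat density)
  null <- mk_rec(rpois(n, 0.2 * len))
  res0 <- switch_density_trend(null, n_boot = 200, seed = 2)
  expect_gt(res0$p, 0.05)
  expect_error(switch_density_trend(planted[1:5, ]), "at least 10")
  same_len <- mk_rec(rpois(n, 1)); same_len$length_cM <- 10
  expect_error(switch_density_trend(same_len), "single segment length")
})

test_that("longest-segment origin summary is deterministic and conserves counts", {
  tr <- planted_world()
  set.seed(9)
  n <- 30
  st <- runif(n, 0, 20)
  en <- st + runif(n, 2, 8)
  seg <- ibd_set(data.frame(id1 = sample(1:4, n, TRUE), hap1 = 1,
                            id2 = sample(5:8, n, TRUE), hap2 = 1,
                            chrom = "chr1", start_cM = st,
                            end_cM = en, length_cM = en - st,
                            group = rep(c("within", "across"), 15)))
  rec <- annotate_ibd_ancestry(seg, tr)
  s <- cross_within_summary(rec, top_k = 10)
  expect_equal(sum(s["within", ]), 10)
  expect_equal(sum(s["across", ]), 10)
  # all segments start inside the EUR portion of every haplotype
  expect_equal(unname(s[, "EUR"]), c(10, 10))
  expect_error(cross_within_summary(rec, top_k = 1000), "exceeds")
  z <- cross_within_summary(rec, top_k = 0)
  expect_true(all(z == 0))
})

test_that("the non-IBD control reflects the background composition", {
  tr <- planted_world()
  seg <- ibd_set(data.frame(id1 = 1, hap1 = 1, id2 = 2, hap2 = 1,
                            chrom = "chr1", start_cM = 0, end_cM = 20,
                            length_cM = 20, group = "within"))
  rec <- annotate_ibd_ancestry(seg, tr)
  ctrl <- non_ibd_control(rec, tr)
  # homogeneous background at these loci: control matches the IBD origin
  expect_equal(unname(ctrl["within", "EUR"]), 2L)
  empty <- non_ibd_control(rec[0, ], tr)
  expect_true(all(empty == 0))
})
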