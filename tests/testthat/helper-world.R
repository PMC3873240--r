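# shared builders for a small synthetic world

small_genome <- function() genome_map(c(1.5, 1.2, 0.8))

# a compact tract set built by hand: one diploid, one chromosome
toy_tracts <- function() {
  g <- genome_map(1.0)
  df <- data.frame(
    ind = c(1L, 1L, 1L, 1L),
    hap = c(1L, 1L, 2L, 2L),
    chrom = "chr1",
    start_cM = c(0, 30, 0, 70),
    end_cM = c(30, 100, 70, 100),
    ancestry = c("NAT", "EUR", "EUR", "AFR"),
    stringsAsFactors = FALSE)
  tract_set(df, g, n_diploid = 1L)
}

# two-ancestry admixed panel: each diploid carries one EUR and one AFR
# haplotype, emulating pseudo-admixed individuals built from two reference
# panels; sites emulate discovered variants (ancestral MAF above ~1%)
pseudo_admixed_panel <- function(n_ind = 30, n_sites = 2000, seed = 1,
                                 Fst = 0.15) {
  set.seed(seed)
  lo <- 0.01; hi <- 1 - lo
  x <- lo * (hi / lo)^runif(n_sites)
  cbn <- (1 - Fst) / Fst
  fE <- rbeta(n_sites, x * cbn, (1 - x) * cbn)
  fA <- rbeta(n_sites, x * cbn, (1 - x) * cbn)
  H1 <- matrix(rbinom(n_sites * n_ind, 1, fE), n_sites)
  H2 <- matrix(rbinom(n_sites * n_ind, 1, fA), n_sites)
  G <- H1 + H2
  keep <- rowSums(G) > 0 & rowSums(G) < 2 * n_ind
  sites <- data.frame(chrom = "chr1",
                      pos_cM = seq(0.1, 100, length.out = n_sites))[keep, ]
  tb <- ancestry_genotype_table(
    sites, G[keep, , drop = FALSE],
    matrix("EUR", sum(keep), n_ind), matrix("AFR", sum(keep), n_ind),
    H1[keep, , drop = FALSE], H2[keep, , drop = FALSE])
  attr(tb, "truth") <- list(fE = fE[keep], fA = fA[keep],
                            sampE = rowMeans(H1[keep, , drop = FALSE]),
                            sampA = rowMeans(H2[keep, , drop = FALSE]),
                            n_monomorphic = sum(!keep))
  tb
}

mxl_history <- function() {
  family_history("founding_plus_continuing",
                 c(t0 = 15.1, fNAT = 0.5, fEUR = 0.45,
                   mEUR = 0.01, mNAT = 0.01))
}

clm_history <- function() {
  family_history("founding_plus_second_NAT_pulse",
                 c(t0 = 13.02, fNAT = 0.24, fEUR = 0.68,
                   t2 = 4.8, mNAT2 = 0.03))
}
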