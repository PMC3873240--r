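# Genotypes on ancestry backgrounds: the diploid genotype + diploid local
# ancestry table that ascertainment and the EM frequency estimator consume.

#' Ancestral allele frequencies per source population
#'
#' @param f matrix of derived-allele frequencies, sites x ancestries
#'   (columns named among NAT/EUR/AFR), all in `[0, 1]`.
#' @return object of class `ancestral_frequencies`.
#' @export
ancestral_frequencies <- function(f) {
  f <- as.matrix(f)
  if (is.null(colnames(f)) || !all(colnames(f) %in% ANCESTRIES))
    stop("columns must be named among NAT, EUR, AFR")
  if (any(f < 0 | f > 1)) stop("frequencies must lie in [0, 1]")
  structure(f, class = "ancestral_frequencies")
}

#' Simulate correlated ancestral frequencies
#'
#' Draws per-site derived frequencies for the source populations under a
#' Balding-Nichols model: an ancestral frequency from a neutral 1/x-shaped
#' spectrum, then per-population frequencies from
#' `Beta(x (1-Fst)/Fst, (1-x)(1-Fst)/Fst)`. `Fst = 0.15` matches
#' continental-scale differentiation (e.g. European vs West African).
#'
#' @param n_sites number of sites.
#' @param ancestries which source populations to draw.
#' @param Fst differentiation from the shared ancestral frequency.
#' @param seed integer seed.
#' @param n_anc haploid size controlling the ancestral spectrum's truncation.
#' @return an [ancestral_frequencies()] matrix.
#' @export
simulate_ancestral_frequencies <- function(n_sites, ancestries = ANCESTRIES,
                                           Fst = 0.15, seed, n_anc = 2e4) {
  set.seed(as.integer(seed))
  lo <- 1 / n_anc; hi <- 1 - lo
  x <- lo * (hi / lo)^runif(n_sites)
  c_bn <- (1 - Fst) / Fst
  f <- vapply(ancestries, function(a) rbeta(n_sites, x * c_bn, (1 - x) * c_bn),
              numeric(n_sites))
  colnames(f) <- ancestries
  ancestral_frequencies(f)
}

#' Construct an ancestry-genotype table
#'
#' @param sites data.frame with columns `chrom`, `pos_cM` (genetic position)
#'   and optionally `id`.
#' @param G integer matrix sites x individuals of derived-allele dosages
#'   (0/1/2, `NA` = missing).
#' @param A1,A2 character matrices of the same shape: local-ancestry labels
#'   of the two haplotypes (`NA` = missing). The diploid ancestry state is
#'   the unordered pair.
#' @param H1,H2 optional 0/1 allele matrices for the two (phase-assigned)
#'   haplotypes; only used when emitting phased output.
#' @return object of class `ancestry_genotype_table`.
#' @export
ancestry_genotype_table <- function(sites, G, A1, A2, H1 = NULL, H2 = NULL) {
  stopifnot(nrow(sites) == nrow(G), identical(dim(G), dim(A1)),
            identical(dim(G), dim(A2)))
  if (is.null(sites$id)) sites$id <- seq_len(nrow(sites))
  bad <- !is.na(G) & !(G %in% 0:2)
  if (any(bad)) stop("genotypes must be 0, 1, 2 or NA")
  structure(list(sites = sites, G = G, A1 = A1, A2 = A2, H1 = H1, H2 = H2),
            class = "ancestry_genotype_table")
}

#' @export
print.ancestry_genotype_table <- function(x, ...) {
  cat(sprintf("<ancestry_genotype_table> %d sites x %d individuals (%s phased haplotypes)\n",
              nrow(x$G), ncol(x$G), if (is.null(x$H1)) "no" else "with"))
  invisible(x)
}

# ancestry labels of every haplotype at given sites (sites x 2*n_ind)
tract_labels_at <- function(tracts, sites, genome) {
  n_ind <- attr(tracts, "n_diploid")
  out <- matrix(NA_character_, nrow(sites), 2L * n_ind)
  for (ind in seq_len(n_ind)) {
    for (hp in 1:2) {
      col <- 2L * (ind - 1L) + hp
      for (ch in unique(sites$chrom)) {
        sel <- sites$chrom == ch
        d <- tracts[tracts$ind == ind & tracts$hap == hp & tracts$chrom == ch, ]
        if (!nrow(d)) next
        ix <- findInterval(sites$pos_cM[sel], d$start_cM)
        ok <- ix >= 1L & sites$pos_cM[sel] < d$end_cM[pmax(ix, 1L)]
        lab <- rep(NA_character_, sum(sel))
        lab[ok] <- d$ancestry[ix[ok]]
        out[sel, col] <- lab
      }
    }
  }
  out
}

#' Assign genotypes on simulated ancestry tracts
#'
#' Each haploid allele is an independent Bernoulli draw from the derived
#' frequency of the source population whose tract overlaps the site; the
#' diploid genotype is the sum and the diploid ancestry state the unordered
#' label pair. Sites falling outside every tract are missing.
#'
#' @param tracts a `tract_set`.
#' @param freqs an [ancestral_frequencies()] matrix (rows = sites).
#' @param sites data.frame with `chrom` and `pos_cM`, one row per frequency
#'   row, inside the genome map.
#' @param seed integer seed.
#' @return an [ancestry_genotype_table()] with phased haplotypes attached.
#' @export
assign_genotypes <- function(tracts, freqs, sites, seed) {
  genome <- attr(tracts, "genome")
  len <- 100 * genome$length_M[match(sites$chrom, genome$chrom)]
  if (anyNA(len) || any(sites$pos_cM < 0 | sites$pos_cM > len))
    stop("site positions must fall inside the genome map")
  set.seed(as.integer(seed))
  n_ind <- attr(tracts, "n_diploid")
  lab <- tract_labels_at(tracts, sites, genome)
  n_s <- nrow(sites)
  pick <- match(lab, colnames(freqs))          # ancestry column per cell
  fmat <- matrix(unclass(freqs)[cbind(rep(seq_len(n_s), 2L * n_ind),
                                      as.vector(pick))],
                 nrow = n_s)
  H <- matrix(NA_integer_, n_s, 2L * n_ind)
  ok <- !is.na(fmat)
  H[ok] <- rbinom(sum(ok), 1L, fmat[ok])
  odd <- seq(1L, 2L * n_ind, by = 2L)
  H1 <- H[, odd, drop = FALSE]; H2 <- H[, odd + 1L, drop = FALSE]
  A1 <- lab[, odd, drop = FALSE]; A2 <- lab[, odd + 1L, drop = FALSE]
  G <- H1 + H2
  ancestry_genotype_table(sites, G, A1, A2, H1, H2)
}

#' Inject phase-switch errors
#'
#' Emulates statistical phasing error: within each individual, switch
#' points arise independently at each site with probability `switch_rate`;
#' downstream of an odd number of switches the two haplotype allele
#' assignments are swapped. The per-haplotype ancestry labels stay as
#' called, so allele-specific ancestry becomes incorrect after a switch,
#' while the unphased genotype and the unordered diploid ancestry state are
#' unchanged (the EM estimator operates only on those).
#'
#' @param table an [ancestry_genotype_table()] with phased haplotypes.
#' @param switch_rate per-site switch probability in `[0, 1]`.
#' @param seed integer seed.
#' @return the table with `H1`/`H2` swapped downstream of switch points.
#' @export
inject_phase_switch_errors <- function(table, switch_rate, seed) {
  if (switch_rate < 0 || switch_rate > 1) stop("switch_rate must be in [0, 1]")
  if (is.null(table$H1)) stop("table carries no phased haplotypes")
  if (switch_rate == 0) return(table)
  set.seed(as.integer(seed))
  n_s <- nrow(table$G); n_i <- ncol(table$G)
  flips <- matrix(rbinom(n_s * n_i, 1L, switch_rate), n_s, n_i)
  state <- (apply(flips, 2L, cumsum) %% 2L) == 1L
  H1 <- table$H1; H2 <- table$H2
  tmp <- H1[state]
  H1[state] <- H2[state]
  H2[state] <- tmp
  table$H1 <- H1; table$H2 <- H2
  table
}

# unordered diploid ancestry state per cell, e.g. "EUR/NAT" (sorted), NA if
# either haplotype is uncalled
diploid_ancestry <- function(table) {
  a1 <- table$A1; a2 <- table$A2
  lo <- pmin(a1, a2); hi <- pmax(a1, a2)
  matrix(ifelse(is.na(lo) | is.na(hi), NA_character_, paste(lo, hi, sep = "/")),
         nrow(a1))
}
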