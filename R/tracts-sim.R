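#' Simulate local-ancestry tracts under a migration history
#'
#' Forward-in-time chromosome painting: a Wright-Fisher population of haploid
#' chromosomes is founded from migrants at the oldest generation of the
#' history; at every later generation each chromosome is a recombinant
#' (Poisson crossovers per Morgan, no interference) of two random parents,
#' and a fraction of chromosomes is replaced by fresh single-ancestry migrant
#' chromosomes according to the history. The sampled generation-0 haplotypes
#' are paired into diploid individuals.
#'
#' @param mig a [migration_history()].
#' @param genome a [genome_map()].
#' @param n_diploid number of diploid individuals to sample (>= 1).
#' @param seed integer seed (required: generators carry no hidden entropy).
#' @param n_pop haploid population size of the forward simulation. The
#'   default 2000 approximates the large-population assumption of the
#'   analytic tract model while keeping per-replicate cost at desk scale.
#' @return a `tract_set`: data.frame with columns `ind`, `hap` (1 or 2),
#'   `chrom`, `start_cM`, `end_cM`, `ancestry`; attributes `genome` and
#'   `n_diploid`. Segments tile each chromosome without gaps or overlaps.
#' @export
simulate_admixed_tracts <- function(mig, genome, n_diploid, seed,
                                    n_pop = 2000) {
  if (!inherits(mig, "migration_history")) stop("invalid-history: not a migration_history")
  if (n_diploid < 1) stop("n_diploid must be >= 1")
  n_out <- 2L * as.integer(n_diploid)
  n_pop <- max(n_pop, n_out)
  set.seed(as.integer(seed))
  raw <- .paint_genome(genome$length_M, as.integer(rownames(mig)),
                       unclass(mig), as.integer(n_pop), n_out)
  tract_set(data.frame(
    ind = (raw$hap + 1L) %/% 2L,
    hap = 2L - (raw$hap %% 2L),
    chrom = genome$chrom[raw$chrom],
    start_cM = 100 * raw$start,
    end_cM = 100 * raw$end,
    ancestry = colnames(mig)[raw$ancestry],
    stringsAsFactors = FALSE
  ), genome = genome, n_diploid = n_diploid)
}

#' Construct and validate a set of ancestry tracts
#'
#' @param df data.frame with columns `ind`, `hap`, `chrom`, `start_cM`,
#'   `end_cM`, `ancestry`.
#' @param genome the [genome_map()] the tracts live on.
#' @param n_diploid number of diploid individuals (defaults to `max(ind)`).
#' @param validate check that segments tile each chromosome exactly.
#' @return object of class `tract_set`.
#' @export
tract_set <- function(df, genome, n_diploid = max(df$ind), validate = TRUE) {
  need <- c("ind", "hap", "chrom", "start_cM", "end_cM", "ancestry")
  if (!all(need %in% names(df))) stop("missing tract columns")
  df <- df[order(df$ind, df$hap, match(df$chrom, genome$chrom), df$start_cM), ]
  rownames(df) <- NULL
  if (any(df$end_cM <= df$start_cM)) stop("tract lengths must be positive")
  if (validate) {
    len <- 100 * genome$length_M[match(df$chrom, genome$chrom)]
    if (anyNA(len)) stop("tract on chromosome absent from genome map")
    if (any(df$end_cM > len + 1e-6)) stop("data error: tract longer than its chromosome")
    key <- paste(df$ind, df$hap, df$chrom)
    new_block <- !duplicated(key)
    prev_end <- c(0, df$end_cM[-nrow(df)])
    prev_end[new_block] <- 0
    if (any(abs(df$start_cM - prev_end) > 1e-6))
      stop("segments must tile each chromosome without gaps or overlaps")
    last <- !duplicated(key, fromLast = TRUE)
    if (any(abs(df$end_cM[last] - len[last]) > 1e-6))
      stop("segments must reach the chromosome end")
  }
  structure(df, class = c("tract_set", "data.frame"),
            genome = genome, n_diploid = as.integer(n_diploid))
}

#' @export
print.tract_set <- function(x, ...) {
  cat(sprintf("<tract_set> %d tracts, %d diploid individuals, ancestries: %s\n",
              nrow(x), attr(x, "n_diploid"),
              paste(sort(unique(x$ancestry)), collapse = ", ")))
  invisible(x)
}

n_haplotypes <- function(tracts) 2L * attr(tracts, "n_diploid")

#' Logarithmic tract-length bins
#'
#' Thirty logarithmically spaced bins spanning the detectable range, from a
#' configurable short-tract detection limit up to the longest chromosome.
#' The lower cutoff reflects the difficulty of calling short ancestry tracts
#' with local-ancestry methods; tracts below it are not counted.
#'
#' @param genome a [genome_map()].
#' @param n_bins number of bins (default 30).
#' @param min_cM shortest countable tract length in cM (default 0.2, a
#'   typical local-ancestry detection limit).
#' @return numeric vector of bin edges in cM (length `n_bins + 1`).
#' @export
length_bins <- function(genome, n_bins = 30, min_cM = 0.2) {
  top <- 100 * max(genome$length_M)
  exp(seq(log(min_cM), log(top + 1e-9), length.out = n_bins + 1))
}

#' Histogram of tract lengths by ancestry
#'
#' Counts tracts per ancestry and length bin. Tracts are never merged across
#' chromosome ends; tracts shorter than the first bin edge are dropped
#' (detection limit), and full-chromosome tracts fall in the bin containing
#' the chromosome length.
#'
#' @param tracts a `tract_set`.
#' @param bins bin edges in cM, as from [length_bins()].
#' @param ancestries ancestry labels to tabulate (default: all three).
#' @return a `tract_histogram`: matrix of counts (bins x ancestries) with
#'   attributes `bins`, `n_haplotypes`, `genome`.
#' @export
tract_histogram <- function(tracts, bins, ancestries = ANCESTRIES) {
  len <- tracts$end_cM - tracts$start_cM
  k <- length(bins) - 1L
  counts <- matrix(0L, nrow = k, ncol = length(ancestries),
                   dimnames = list(NULL, ancestries))
  for (a in ancestries) {
    l <- len[tracts$ancestry == a]
    l <- l[l >= bins[1L]]
    if (length(l)) {
      ix <- findInterval(l, bins, rightmost.closed = TRUE)
      ix[ix > k] <- k
      tb <- tabulate(ix, nbins = k)
      counts[, a] <- tb
    }
  }
  structure(counts, class = "tract_histogram", bins = bins,
            n_haplotypes = n_haplotypes(tracts), genome = attr(tracts, "genome"))
}

#' @export
print.tract_histogram <- function(x, ...) {
  cat(sprintf("<tract_histogram> %d bins x %d ancestries, %d tracts total\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}
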