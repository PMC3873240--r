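# IBD segment sharing: closed-form expectations, simulation, Ne estimation.
#
# For a pair of haplotypes in a panmictic constant-size population of diploid
# effective size Ne, the time to the most recent common ancestor at a locus
# is approximately exponential with mean 2*Ne generations. Conditional on a
# TMRCA of t generations, the two lineages have passed through 2t meioses,
# so maximal constant-TMRCA segments end at rate 2t per Morgan and a segment
# has length ~ Exp(2t). In the stationary process the density (per Morgan,
# per haplotype pair) of maximal segments with TMRCA in (t, t+dt) and length
# >= u is f(t) * 2t * exp(-2tu) dt, and each chromosome start contributes
# f(t) * exp(-2tu) dt (a segment truncated by the chromosome edge).
# Integrating over f(t) = exp(-t/(2Ne))/(2Ne):
#   E[N(>=u)] = L / (Ne * (1/(2Ne) + 2u)^2) + C / (1 + 4*Ne*u)
# with L the genome length in Morgans and C the number of chromosomes.

#' Expected number of IBD segments of at least a given length
#'
#' @param Ne diploid effective population size.
#' @param min_len_cM minimum segment length in cM.
#' @param genome a [genome_map()].
#' @return expected number of segments `>= min_len_cM` per haplotype pair.
#' @export
expected_ibd_segments <- function(Ne, min_len_cM, genome) {
  u <- min_len_cM / 100
  # a body segment is observed at length >= u only if it starts at least u
  # before the chromosome end, hence the (L_c - u)+ per chromosome
  Leff <- sum(pmax(genome$length_M - u, 0))
  C <- nrow(genome)
  Leff / (Ne * (1 / (2 * Ne) + 2 * u)^2) + C / (1 + 4 * Ne * u)
}

#' Estimate effective population size from IBD segment counts
#'
#' Inverts the monotone map from constant diploid `Ne` to the expected
#' number of IBD segments longer than `min_len_cM` per haplotype pair
#' (see [expected_ibd_segments()]) at the observed mean count.
#'
#' @param segments an `ibd_set` (see [ibd_set()]), or anything with a
#'   `length_cM` column.
#' @param min_len_cM length threshold in cM (default 4, the threshold used
#'   for recent-Ne estimation from array data).
#' @param n_pairs number of haplotype pairs the segments were discovered in.
#' @param genome a [genome_map()].
#' @return an object of class `ibd_ne`: list with `Ne` (point estimate;
#'   `Inf` if no segment passes the threshold), `mean_per_pair`,
#'   `n_segments`, `min_len_cM`.
#' @export
ibd_ne_from_counts <- function(segments, min_len_cM = 4, n_pairs, genome) {
  if (min_len_cM <= 0) stop("min_len_cM must be positive")
  if (n_pairs < 1) stop("n_pairs must be >= 1")
  n_seg <- sum(segments$length_cM >= min_len_cM)
  obs <- n_seg / n_pairs
  if (n_seg == 0)
    return(structure(list(Ne = Inf, mean_per_pair = 0, n_segments = 0L,
                          min_len_cM = min_len_cM), class = "ibd_ne"))
  f <- function(logNe) expected_ibd_segments(exp(logNe), min_len_cM, genome) - obs
  sol <- stats::uniroot(f, lower = log(2), upper = log(1e9), tol = 1e-10)
  structure(list(Ne = exp(sol$root), mean_per_pair = obs,
                 n_segments = as.integer(n_seg), min_len_cM = min_len_cM),
            class = "ibd_ne")
}

#' @export
print.ibd_ne <- function(x, ...) {
  cat(sprintf("<ibd_ne> Ne = %s (from %d segments >= %.1f cM, %.3f per pair)\n",
              if (is.finite(x$Ne)) format(round(x$Ne)) else "Inf",
              x$n_segments, x$min_len_cM, x$mean_per_pair))
  invisible(x)
}

#' Construct a set of IBD segments
#'
#' @param df data.frame with columns `id1`, `hap1`, `id2`, `hap2`, `chrom`,
#'   `start_cM`, `end_cM`, `length_cM`, and optionally `group` (`"within"` or
#'   `"across"` population).
#' @return object of class `ibd_set`.
#' @export
ibd_set <- function(df) {
  need <- c("id1", "hap1", "id2", "hap2", "chrom", "start_cM", "end_cM",
            "length_cM")
  if (!all(need %in% names(df))) stop("missing IBD columns")
  if (any(df$length_cM <= 0)) stop("IBD segment lengths must be positive")
  if (any(df$id1 == df$id2 & df$hap1 == df$hap2))
    stop("IBD pair members must be distinct haplotypes")
  if (is.null(df$group)) df$group <- rep("within", nrow(df))
  structure(df, class = c("ibd_set", "data.frame"))
}

#' @export
print.ibd_set <- function(x, ...) {
  cat(sprintf("<ibd_set> %d segments, %.1f-%.1f cM\n", nrow(x),
              if (nrow(x)) min(x$length_cM) else NA,
              if (nrow(x)) max(x$length_cM) else NA))
  invisible(x)
}

# draw TMRCA values from density ~ t * exp(-t/(2Ne)) truncated to (0, tmax):
# rejection from the linear density t (sample tmax*sqrt(U)) against the
# exponential factor, efficient because tmax << 2Ne in all uses here
rtrunc_gamma2 <- function(n, Ne, tmax) {
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, 2L * (n - length(out)))
    t <- tmax * sqrt(runif(m))
    keep <- runif(m) < exp(-t / (2 * Ne))
    out <- c(out, t[keep])
  }
  out[seq_len(n)]
}

#' Simulate pairwise IBD sharing in a constant-size population
#'
#' Sequential Markovian approximation restricted to recent coalescence: for
#' each haplotype pair and chromosome, candidate IBD segments (runs of
#' constant, recent TMRCA) arise as a renewal process whose start intensity
#' and length law follow the stationary segment process of the coalescent
#' with recombination (see [expected_ibd_segments()]); TMRCAs older than
#' `tmax = 5 / min_len` contribute segments `>= min_len` with probability
#' `< exp(-10)` and are treated as non-IBD background. Segments reaching a
#' chromosome end are truncated; only segments `>= min_len_cM` are reported.
#'
#' @param Ne diploid effective size (>= 2).
#' @param n_diploid number of diploid individuals in the panel.
#' @param genome a [genome_map()].
#' @param min_len_cM minimum reported segment length (cM), > 0.
#' @param seed integer seed.
#' @return an `ibd_set` of segments across all haplotype pairs.
#' @export
simulate_ibd_sharing <- function(Ne, n_diploid, genome, min_len_cM = 4, seed) {
  if (Ne < 2) stop("Ne must be >= 2")
  if (min_len_cM <= 0) stop("min_len_cM must be positive")
  set.seed(as.integer(seed))
  u <- min_len_cM / 100
  tmax <- 5 / u
  n_hap <- 2L * n_diploid
  # per-Morgan intensity of candidate-segment starts with TMRCA <= tmax
  lam <- stats::integrate(function(t) exp(-t / (2 * Ne)) / (2 * Ne) * 2 * t,
                          0, tmax)$value
  p_edge <- stats::integrate(function(t) exp(-t / (2 * Ne)) / (2 * Ne),
                             0, tmax)$value
  hap_pairs <- utils::combn(n_hap, 2L)
  # drop within-individual pairs (haplotypes 2i-1, 2i belong to individual i)
  ind <- function(h) (h + 1L) %/% 2L
  keep <- ind(hap_pairs[1L, ]) != ind(hap_pairs[2L, ])
  hap_pairs <- hap_pairs[, keep, drop = FALSE]
  np <- ncol(hap_pairs)
  res <- vector("list", nrow(genome))
  for (ci in seq_len(nrow(genome))) {
    L <- genome$length_M[ci]
    # number of candidate runs per pair: edge run (Bernoulli) + Poisson body
    n_body <- rpois(np, lam * L)
    edge <- runif(np) < p_edge
    tot <- n_body + edge
    if (sum(tot) == 0) { res[[ci]] <- NULL; next }
    pair_id <- rep.int(seq_len(np), tot)
    is_edge <- unlist(lapply(seq_len(np), function(i)
      c(rep(FALSE, n_body[i]), rep(TRUE, edge[i]))), use.names = FALSE)
    n_all <- length(pair_id)
    t_all <- rtrunc_gamma2(n_all, Ne, tmax)
    start <- runif(n_all) * L
    start[is_edge] <- 0
    len <- stats::rexp(n_all, rate = 2 * t_all)
    end <- pmin(start + len, L)
    obs_len <- end - start
    selseg <- obs_len >= u
    if (!any(selseg)) { res[[ci]] <- NULL; next }
    h1 <- hap_pairs[1L, pair_id[selseg]]
    h2 <- hap_pairs[2L, pair_id[selseg]]
    res[[ci]] <- data.frame(
      id1 = ind(h1), hap1 = 2L - (h1 %% 2L),
      id2 = ind(h2), hap2 = 2L - (h2 %% 2L),
      chrom = genome$chrom[ci],
      start_cM = 100 * start[selseg], end_cM = 100 * end[selseg],
      length_cM = 100 * obs_len[selseg], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(id1 = integer(), hap1 = integer(), id2 = integer(),
                      hap2 = integer(), chrom = character(),
                      start_cM = numeric(), end_cM = numeric(),
                      length_cM = numeric(), stringsAsFactors = FALSE)
  out <- ibd_set(out)
  attr(out, "n_pairs") <- np
  attr(out, "Ne") <- Ne
  out
}
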