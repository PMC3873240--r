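# Analytic tract-length model.
#
# Ancestry along a present-day chromosome is approximated by a Markov jump
# process whose states are migrant cohorts (ancestry p, entry generation t).
# A lineage that entered the admixed population t generations ago has passed
# through t - 1 meioses, so it switches state at rate (t - 1) per Morgan; at
# a switch the meiosis generation s is uniform on 1..t-1 and the new state is
# drawn from the population composition at generation s. Tract lengths for an
# ancestry are then phase-type distributed (sub-generator restricted to that
# ancestry's states), and expected per-bin tract counts on a finite
# chromosome follow from the entry flux plus start/end edge corrections.

# state decomposition of a migration history: marginals and jump kernel
mig_states <- function(mig) {
  gens <- as.integer(rownames(mig))
  T0 <- max(gens)
  M <- numeric(T0)                       # total inflow by generation index
  for (i in seq_along(gens)) M[gens[i]] <- sum(mig[i, ])
  # surv[s, t'] = prod_{v=s}^{t'-1} (1 - M[v]);  composition at generation s:
  # c_s(t', p') = m[t', p'] * surv[s, t']
  surv <- matrix(1, nrow = T0, ncol = T0)  # rows s, cols t'
  for (tp in 2:T0) {
    # fill decreasing s < t'
    for (s in (tp - 1):1) surv[s, tp] <- surv[s + 1, tp] * (1 - M[s])
  }
  idx <- which(unclass(mig) > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty history")
  st_t <- gens[idx[, 1]]
  st_p <- colnames(mig)[idx[, 2]]
  ns <- length(st_t)
  mval <- unclass(mig)[idx]
  # present-day marginal pi: lineages entering at t survive replacement at
  # generations t-1 .. 2 (composition c_2)
  pi0 <- mval * surv[2, st_t]
  # jump kernel K[i, j]: a lineage of age t_i recombines at one of its
  # t_i - 1 meioses (uniformly); the meiosis producing generation s - 1 joins
  # a partner lineage from the post-replacement population at generation s,
  # i.e. composition c_s with s ranging over 2 .. t_i
  csum <- apply(surv, 2, cumsum) - surv[rep(1L, T0), , drop = FALSE]
  # csum[s, t'] = sum_{sigma=2}^{s} surv[sigma, t']
  ti_m <- matrix(st_t, ns, ns)
  tj_m <- t(ti_m)
  K <- matrix(csum[cbind(as.vector(pmin(ti_m, tj_m)), as.vector(tj_m))], ns, ns) *
    rep(mval, each = ns) / (st_t - 1)
  lam <- st_t - 1
  Q <- lam * (K - diag(ns))              # generator (rows scaled by rate)
  list(t = st_t, p = st_p, pi = pi0, Q = Q, lam = lam)
}

# scalar integrals of exp(d*l) over [a,b] (complex-safe)
.g1 <- function(d, a, b) {
  out <- ifelse(Mod(d) < 1e-12, b - a, (exp(d * b) - exp(d * a)) / d)
  out
}
.gl <- function(d, a, b) {              # integral of l * exp(d l)
  small <- Mod(d) < 1e-12
  out <- (b / d - 1 / d^2) * exp(d * b) - (a / d - 1 / d^2) * exp(d * a)
  out[small] <- (b^2 - a^2) / 2
  out
}

#' Expected tract counts under a migration history
#'
#' Computes real-valued expected counts of ancestry tracts per length bin
#' from the inhomogeneous Markov model of local ancestry implied by a
#' migration history, with exact finite-chromosome edge corrections
#' (tracts censored at chromosome starts/ends and full-chromosome tracts are
#' counted at their observed length, matching what a tract histogram of
#' simulated or real data contains).
#'
#' @param mig a [migration_history()].
#' @param bins bin edges in cM (see [length_bins()]).
#' @param genome a [genome_map()].
#' @param n_haplotypes number of haplotypes observed.
#' @return a `tract_histogram` (real-valued, attribute `expected = TRUE`).
#' @export
expected_tract_counts <- function(mig, bins, genome, n_haplotypes) {
  st <- mig_states(mig)
  k <- length(bins) - 1L
  anc <- ANCESTRIES
  counts <- matrix(0, nrow = k, ncol = length(anc), dimnames = list(NULL, anc))
  bins_M <- bins / 100
  chroms <- genome$length_M
  for (a in anc) {
    I <- which(st$p == a)
    if (!length(I)) next
    piI <- st$pi[I]
    B <- st$Q[I, I, drop = FALSE]
    ones <- rep(1, length(I))
    r_exit <- -as.vector(B %*% ones)               # rate of leaving ancestry a
    out <- setdiff(seq_along(st$p), I)
    a_raw <- if (length(out)) as.vector(st$pi[out] %*% st$Q[out, I, drop = FALSE]) else numeric(length(I))
    rho <- sum(a_raw)
    eg <- eigen(B)
    V <- eg$vectors; d <- eg$values
    Vi <- solve(V)
    alpha <- if (rho > 1e-14) a_raw / rho else a_raw * 0
    wa <- as.vector(alpha %*% V)       # entry distribution in eigenbasis
    wp <- as.vector(piI %*% V)         # chromosome-start distribution
    vr <- as.vector(Vi %*% r_exit)
    v1 <- as.vector(Vi %*% ones)
    dz <- Mod(d) < 1e-12               # zero eigenvalues (no-exit limit)
    dsafe <- ifelse(dz, 1, d)
    # all chromosomes at once: rows are (edge, chromosome) pairs
    nc <- length(chroms)
    ecap <- pmin(matrix(bins_M, k + 1L, nc), rep(chroms, each = k + 1L))
    ev <- as.vector(ecap)
    E <- exp(outer(ev, d))                       # ((k+1)*nc) x ns
    Dm <- matrix(dsafe, length(ev), length(d), byrow = TRUE)
    A1 <- (ev * E) / Dm - E / Dm^2               # antiderivative of l e^(dl)
    lo <- rep(seq_len(k), nc) + rep((k + 1L) * (seq_len(nc) - 1L), each = k)
    hi <- lo + 1L
    G1 <- (E[hi, , drop = FALSE] - E[lo, , drop = FALSE]) / Dm[hi, , drop = FALSE]
    GL <- A1[hi, , drop = FALSE] - A1[lo, , drop = FALSE]
    if (any(dz)) {
      G1[, dz] <- ev[hi] - ev[lo]
      GL[, dz] <- (ev[hi]^2 - ev[lo]^2) / 2
    }
    G2 <- rep(chroms, each = k) * G1 - GL
    add <- Re(G2 %*% (rho * wa * vr) + G1 %*% (rho * wa * v1 + wp * vr))
    tot <- rowSums(matrix(as.vector(add), k, nc))
    # full-chromosome tracts land in the bin containing the chromosome length
    full <- Re(exp(outer(chroms, d)) %*% (wp * v1))
    bc <- findInterval(chroms, bins_M, rightmost.closed = TRUE)
    okc <- bc >= 1 & bc <= k
    if (any(okc)) {
      agg <- rowsum(full[okc], bc[okc])
      tot[as.integer(rownames(agg))] <- tot[as.integer(rownames(agg))] + agg[, 1L]
    }
    counts[, a] <- counts[, a] + tot
  }
  counts <- pmax(counts, 0) * n_haplotypes
  structure(counts, class = "tract_histogram", bins = bins,
            n_haplotypes = n_haplotypes, genome = genome, expected = TRUE)
}

#' Poisson log-likelihood of an observed tract histogram
#'
#' Counts per bin are modelled as independent Poisson with the expected
#' counts as means. Bins with zero expectation contribute 0 when the
#' observation is also 0 and `-Inf` otherwise.
#'
#' @param obs observed `tract_histogram` (integer counts).
#' @param exp expected `tract_histogram` (same bins and ancestries).
#' @return log-likelihood (scalar; may be `-Inf`).
#' @export
poisson_loglik <- function(obs, exp) {
  if (!identical(dim(obs), dim(exp)))
    stop("histograms must share bins and ancestries")
  bo <- attr(obs, "bins"); be <- attr(exp, "bins")
  if (!isTRUE(all.equal(bo, be))) stop("histograms must share bin edges")
  mu <- pmax(as.numeric(exp), 0)
  x <- as.numeric(obs)
  ll <- stats::dpois(x, mu, log = TRUE)
  ll[x == 0 & mu == 0] <- 0
  sum(ll)
}
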