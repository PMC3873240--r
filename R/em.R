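# EM estimation of ancestry-specific allele frequencies from unphased
# genotypes with diploid local-ancestry calls.
#
# Per site, the two haplotypes of an individual are independent Bernoulli
# draws from the derived frequency of their own ancestry, so for diploid
# ancestry state (a, b):
#   P(G=0) = (1-f_a)(1-f_b),  P(G=1) = f_a(1-f_b) + f_b(1-f_a),
#   P(G=2) = f_a f_b
# -- phasing-free by construction. Site posteriors over a frequency grid
# are combined with a per-ancestry prior P(f) (Bayes rule); the prior is
# re-estimated as the average of the site posteriors, and the two steps are
# iterated to self-consistency (an EM whose marginal likelihood is
# non-decreasing). Only the genotype-heterozygous, ancestry-heterozygous
# class couples the two frequencies; everything else factorizes, which is
# what makes 100k-site panels tractable.

#' Genotype probability given diploid ancestry and ancestral frequencies
#'
#' @param G genotype 0, 1 or 2 (derived dosage).
#' @param A unordered ancestry pair, e.g. `c("NAT", "EUR")`.
#' @param f named vector of derived frequencies per ancestry.
#' @return probability (vectorized over `f` grids if `f` entries are
#'   vectors of equal length).
#' @export
genotype_prob <- function(G, A, f) {
  if (!all(G %in% 0:2)) stop("genotype must be 0, 1 or 2")
  fa <- f[[A[[1L]]]]; fb <- f[[A[[2L]]]]
  switch(as.character(G),
         "0" = (1 - fa) * (1 - fb),
         "1" = fa * (1 - fb) + fb * (1 - fa),
         "2" = fa * fb)
}

#' Frequency grid and priors
#'
#' @param n_grid number of equispaced grid points in `[0, 1]` including the
#'   endpoints (default 201, giving 0.5% resolution).
#' @param ancestries ancestry labels carrying priors.
#' @return object of class `frequency_grid`: `f` (grid values), `prior`
#'   (matrix grid x ancestry, uniform by default).
#' @export
frequency_grid <- function(n_grid = 201, ancestries = ANCESTRIES) {
  f <- seq(0, 1, length.out = n_grid)
  prior <- matrix(1 / n_grid, n_grid, length(ancestries),
                  dimnames = list(NULL, ancestries))
  structure(list(f = f, prior = prior), class = "frequency_grid")
}

# sufficient statistics per site: for each ordered ancestry-class label
# ("X/Y" sorted) x genotype, the count of individuals
site_suffstats <- function(table) {
  A <- diploid_ancestry(table)
  G <- table$G
  complete <- rowSums(is.na(G) | is.na(A)) == 0
  classes <- sort(unique(as.vector(A[complete, , drop = FALSE])))
  ns <- nrow(G)
  cnt <- list()
  for (cl in classes) {
    for (g in 0:2) {
      cnt[[paste(cl, g, sep = ":")]] <-
        rowSums(A == cl & G == g, na.rm = TRUE)
    }
  }
  list(counts = cnt, classes = classes, complete = complete)
}

# per-ancestry separable exponents (derived d, ancestral r) and the het
# coupling counts per ancestry pair
site_exponents <- function(ss, ancestries) {
  ns <- length(ss$complete)
  d <- r <- matrix(0L, ns, length(ancestries), dimnames = list(NULL, ancestries))
  het <- list()
  for (cl in ss$classes) {
    ab <- strsplit(cl, "/")[[1L]]
    n0 <- ss$counts[[paste(cl, 0, sep = ":")]]
    n1 <- ss$counts[[paste(cl, 1, sep = ":")]]
    n2 <- ss$counts[[paste(cl, 2, sep = ":")]]
    if (ab[1L] == ab[2L]) {
      a <- ab[1L]
      d[, a] <- d[, a] + n1 + 2L * n2
      r[, a] <- r[, a] + n1 + 2L * n0
    } else {
      for (a in ab) {
        d[, a] <- d[, a] + n2
        r[, a] <- r[, a] + n0
      }
      het[[cl]] <- n1
    }
  }
  list(d = d, r = r, het = het)
}

#' Ancestry-specific allele frequencies by expectation-maximization
#'
#' Iterates site posteriors (Bayes rule on the frequency grid) and prior
#' re-estimation (average of site posteriors, with the monomorphic-site
#' correction when `n_monomorphic > 0`) to self-consistency. Sites with any
#' missing genotype or ancestry call are excluded.
#'
#' @param table an [ancestry_genotype_table()].
#' @param grid a [frequency_grid()] (or `n_grid` integer).
#' @param iters EM iterations (default 20).
#' @param n_monomorphic number of monomorphic (undetected) sites behind the
#'   polymorphic set, for the prior correction; 0 disables it.
#' @param ci_level credible level for per-site intervals.
#' @param block_size sites processed per block (bounds peak memory).
#' @return object of class `em_fit`: `prior` (final per-ancestry priors),
#'   `loglik_trace` (non-decreasing), `estimates` (data.frame per site x
#'   involved ancestry: posterior mean, HPD interval, NAT/EUR/AFR haplotype
#'   counts), `grid`, `n_sites_used`.
#' @export
em_estimate <- function(table, grid = 201, iters = 20, n_monomorphic = 0,
                        ci_level = 0.95, block_size = 20000L) {
  if (is.numeric(grid)) grid <- frequency_grid(grid)
  f <- grid$f; nf <- length(f)
  ss <- site_suffstats(table)
  use <- which(ss$complete)
  if (!length(use)) stop("no site has complete genotype and ancestry calls")
  ancs <- sort(unique(unlist(strsplit(ss$classes, "/"))))
  ex <- site_exponents(ss, ancs)
  d <- ex$d[use, , drop = FALSE]; r <- ex$r[use, , drop = FALSE]
  het <- lapply(ex$het, function(v) v[use])
  ns <- length(use)
  kmax <- max(d, r, 1L)
  lf <- log(pmax(f, 1e-300)); l1f <- log(pmax(1 - f, 1e-300))
  pow_f <- exp(outer(lf, 0:kmax)); pow_1f <- exp(outer(l1f, 0:kmax))
  pow_f[1L, ] <- c(1, rep(0, kmax)); pow_1f[nf, ] <- c(1, rep(0, kmax))
  het_pairs <- names(het)
  M1 <- outer(f, f, function(x, y) x * (1 - y) + y * (1 - x))
  lM1 <- log(pmax(M1, 1e-300))
  prior <- grid$prior[, ancs, drop = FALSE]
  prior <- sweep(prior, 2, colSums(prior), "/")
  trace <- numeric(iters)
  blocks <- split(seq_len(ns), ceiling(seq_len(ns) / block_size))
  est <- NULL
  for (it in seq_len(iters)) {
    logZ_tot <- 0
    prior_acc <- matrix(0, nf, length(ancs), dimnames = list(NULL, ancs))
    if (it == iters) est <- vector("list", length(blocks))
    for (bi in seq_along(blocks)) {
      ib <- blocks[[bi]]
      nb <- length(ib)
      av <- list()
      for (a in ancs)
        av[[a]] <- prior[, a] * pow_f[, d[ib, a] + 1L, drop = FALSE] *
          pow_1f[, r[ib, a] + 1L, drop = FALSE]
      marg <- av
      if (length(het_pairs) == 1L && length(ancs) == 2L) {
        n1 <- het[[1L]][ib]
        aA <- av[[1L]]; aB <- av[[2L]]
        mA <- aA; mB <- aB
        for (k in sort(unique(n1[n1 > 0L]))) {
          cols <- which(n1 == k)
          Mk <- exp(k * lM1)          # symmetric coupling kernel
          mA[, cols] <- aA[, cols, drop = FALSE] *
            (Mk %*% aB[, cols, drop = FALSE])
          mB[, cols] <- aB[, cols, drop = FALSE] *
            (Mk %*% aA[, cols, drop = FALSE])
        }
        marg[[ancs[1L]]] <- mA; marg[[ancs[2L]]] <- mB
        zero <- n1 == 0L
        logZ <- numeric(nb)
        logZ[!zero] <- log(pmax(colSums(mA[, !zero, drop = FALSE]), 1e-300))
        if (any(zero))
          logZ[zero] <- log(pmax(colSums(aA[, zero, drop = FALSE]), 1e-300)) +
            log(pmax(colSums(aB[, zero, drop = FALSE]), 1e-300))
      } else if (length(het_pairs) == 0L) {
        logZ <- rep(0, nb)
        for (a in ancs) logZ <- logZ + log(pmax(colSums(av[[a]]), 1e-300))
      } else {
        logZ <- numeric(nb)
        for (a in ancs) marg[[a]] <- matrix(0, nf, nb)
        for (j in seq_len(nb)) {
          res <- contract_site(lapply(av, function(m) m[, j]),
                               lapply(het, function(v) v[ib]), j, lM1, ancs)
          logZ[j] <- res$logZ
          for (a in ancs) marg[[a]][, j] <- res$marg[[a]]
        }
      }
      logZ_tot <- logZ_tot + sum(logZ)
      for (a in ancs) {
        m <- marg[[a]]
        m <- sweep(m, 2, pmax(colSums(m), 1e-300), "/")
        marg[[a]] <- m
        prior_acc[, a] <- prior_acc[, a] + rowSums(m)
      }
      if (it == iters) {
        bl <- list()
        for (a in ancs) {
          m <- marg[[a]]
          mu <- as.vector(f %*% m)
          ci <- apply(m, 2, hpd_interval, f = f, level = ci_level)
          nh <- rowSums((table$A1[use[ib], , drop = FALSE] == a) +
                          (table$A2[use[ib], , drop = FALSE] == a))
          bl[[a]] <- data.frame(site = use[ib], ancestry = a, mean = mu,
                                lower = ci[1L, ], upper = ci[2L, ],
                                n_hap = as.integer(nh),
                                stringsAsFactors = FALSE)
        }
        est[[bi]] <- do.call(rbind, bl)
      }
    }
    trace[it] <- logZ_tot
    for (a in ancs) {
      pr <- prior_acc[, a] / ns
      if (n_monomorphic > 0) {
        k_bar <- mean(d[, a] + r[, a]) +
          2 * mean(if (length(het)) Reduce(`+`, lapply(het, identity)) else 0)
        pr <- monomorphic_correction(pr, k_bar, n_monomorphic, f,
                                     n_poly = ns)$prior
      }
      prior[, a] <- pr / sum(pr)
    }
  }
  structure(list(prior = prior, loglik_trace = trace,
                 estimates = do.call(rbind, est), grid = grid,
                 n_sites_used = ns, ancestries = ancs),
            class = "em_fit")
}

# exact three-ancestry contraction for one site (het = list of n1 vectors)
contract_site <- function(a_list, het, i, lM1, ancs) {
  nf <- nrow(lM1)
  Mp <- function(pair) {
    k <- het[[pair]][i]
    if (is.null(k) || k == 0L) matrix(1, nf, nf) else exp(k * lM1)
  }
  pn <- function(x, y) paste(sort(c(x, y)), collapse = "/")
  A <- ancs[1L]; B <- ancs[2L]; C <- ancs[3L]
  MAB <- Mp(pn(A, B)); MAC <- Mp(pn(A, C)); MBC <- Mp(pn(B, C))
  # S(fA, fB) = sum_fC MAC(fA,fC) c(fC) MBC(fB,fC)
  S <- MAC %*% (a_list[[C]] * t(MBC))
  JAB <- MAB * S * outer(a_list[[A]], a_list[[B]])
  margA <- rowSums(JAB)
  margB <- colSums(JAB)
  # marg over C: sum_{fA,fB} ...
  W <- t(MAB * outer(a_list[[A]], a_list[[B]]))      # fB x fA
  margC <- a_list[[C]] * colSums((MBC %*% W) * t(MAC))
  Z <- sum(margA)
  out <- list(); out[[A]] <- margA; out[[B]] <- margB; out[[C]] <- margC
  list(marg = out, logZ = log(max(Z, 1e-300)))
}

#' Highest-posterior-density interval on a grid
#'
#' @param p posterior mass vector (need not be normalized).
#' @param f grid values.
#' @param level credible level.
#' @return `c(lower, upper)` endpoints of the smallest set of grid points
#'   holding at least `level` of the mass (reported as its range).
#' @export
hpd_interval <- function(p, f, level = 0.95) {
  p <- p / sum(p)
  o <- order(p, decreasing = TRUE)
  k <- which(cumsum(p[o]) >= level)[1L]
  sel <- o[seq_len(k)]
  c(min(f[sel]), max(f[sel]))
}

#' Per-site credible interval from a posterior
#'
#' @param posterior posterior mass over the grid.
#' @param f grid values (default 201-point grid).
#' @param level credible level (default 0.95).
#' @return list with `interval` and `width`.
#' @export
frequency_ci <- function(posterior, f = seq(0, 1, length.out = length(posterior)),
                         level = 0.95) {
  ci <- hpd_interval(posterior, f, level)
  list(interval = ci, width = ci[2L] - ci[1L])
}

#' Monomorphic-site correction of a frequency prior
#'
#' Sites at frequency `f` enter the polymorphic set only with detection
#' probability `d(f) = 1 - (1 - f)^k` (no derived allele in `k` sampled
#' haplotypes escapes detection). The prior estimated from polymorphic
#' sites is therefore reweighted by `1/d(f)`; mass implied by the `n0`
#' undetected sites beyond the reweighting is assigned to the `f = 0`
#' class, and the result renormalized. `n0 = 0` returns the prior
#' unchanged.
#'
#' @param prior prior mass over the grid (from polymorphic sites).
#' @param k_bar (mean) number of sampled haplotypes of this ancestry.
#' @param n0 number of monomorphic sites.
#' @param f grid values.
#' @param n_poly number of polymorphic sites behind `prior`; enables the
#'   reconciliation of the implied and observed undetected fractions.
#' @return list with `prior` (corrected, normalized) and `detection`.
#' @export
monomorphic_correction <- function(prior, k_bar, n0, f, n_poly = NULL) {
  if (n0 < 0) stop("n0 must be >= 0")
  det <- 1 - (1 - f)^k_bar
  prior <- prior / sum(prior)
  if (n0 == 0) return(list(prior = prior, detection = det))
  if (all(det <= 0)) stop("detection probability vanishes with n0 > 0")
  w <- prior / pmax(det, det[2L] / 2)      # guard the f = 0 point
  w[1L] <- prior[1L]
  if (!is.null(n_poly) && n_poly > 0) {
    # reconcile with the observed monomorphic fraction: whatever undetected
    # mass the reweighting has not already implied sits at (or below) the
    # f = 0 grid point, in per-polymorphic-site units
    implied <- sum(w) - 1
    w[1L] <- w[1L] + max(0, n0 / n_poly - implied)
  }
  list(prior = w / sum(w), detection = det)
}

#' @export
print.em_fit <- function(x, ...) {
  cat(sprintf("<em_fit> %d sites, ancestries %s, %d iterations (logLik %.2f -> %.2f)\n",
              x$n_sites_used, paste(x$ancestries, collapse = "/"),
              length(x$loglik_trace), x$loglik_trace[1L],
              x$loglik_trace[length(x$loglik_trace)]))
  invisible(x)
}

#' @export
summary.em_fit <- function(object, ...) {
  print(object)
  e <- object$estimates
  for (a in object$ancestries) {
    d <- e[e$ancestry == a, ]
    cat(sprintf("  %s: mean CI width %.3f, mean n_hap %.1f\n",
                a, mean(d$upper - d$lower), mean(d$n_hap)))
  }
  invisible(object)
}

#' Posterior for a single site
#'
#' @param G genotype vector over individuals (0/1/2).
#' @param A list or character vector of diploid ancestry states
#'   (`"EUR/NAT"` style, sorted labels).
#' @param grid a [frequency_grid()] whose priors to use.
#' @param ci_level credible level.
#' @return object of class `site_posterior`: per-ancestry posterior mass,
#'   posterior means, HPD intervals, haplotype counts.
#' @export
site_posterior <- function(G, A, grid = frequency_grid(), ci_level = 0.95) {
  ok <- !is.na(G) & !is.na(A)
  if (!any(ok)) stop("site has no individual with both calls")
  G <- G[ok]; A <- A[ok]
  tb <- ancestry_genotype_table(data.frame(chrom = "chr1", pos_cM = 1),
                                matrix(G, 1), matrix(sub("/.*", "", A), 1),
                                matrix(sub(".*/", "", A), 1))
  fit <- em_estimate_site(tb, grid, ci_level)
  fit
}

# one-site posterior with fixed priors (no EM iteration)
em_estimate_site <- function(table, grid, ci_level = 0.95) {
  f <- grid$f; nf <- length(f)
  ss <- site_suffstats(table)
  ancs <- sort(unique(unlist(strsplit(ss$classes, "/"))))
  ex <- site_exponents(ss, ancs)
  het <- lapply(ex$het, function(v) v[1L])
  av <- list()
  for (a in ancs)
    av[[a]] <- grid$prior[, a] * f^ex$d[1L, a] * (1 - f)^ex$r[1L, a]
  lM1 <- log(pmax(outer(f, f, function(x, y) x * (1 - y) + y * (1 - x)), 1e-300))
  if (length(ancs) == 1L) {
    marg <- stats::setNames(list(av[[1L]]), ancs)
  } else if (length(ancs) == 2L) {
    k <- if (length(het)) het[[1L]] else 0L
    Mk <- if (k == 0L) matrix(1, nf, nf) else exp(k * lM1)
    mA <- av[[1L]] * as.vector(Mk %*% av[[2L]])
    mB <- av[[2L]] * as.vector(crossprod(Mk, av[[1L]]))
    marg <- stats::setNames(list(mA, mB), ancs)
  } else {
    res <- contract_site(av, het, 1L, lM1, ancs)
    marg <- res$marg
  }
  post <- lapply(marg, function(m) m / sum(m))
  means <- vapply(post, function(m) sum(f * m), 0)
  cis <- vapply(post, hpd_interval, numeric(2L), f = f, level = ci_level)
  nh <- vapply(ancs, function(a)
    sum((table$A1[1L, ] == a) + (table$A2[1L, ] == a), na.rm = TRUE), 0)
  structure(list(posterior = post, mean = means, ci = cis, n_hap = nh,
                 ancestries = ancs),
            class = "site_posterior")
}

#' @export
print.site_posterior <- function(x, ...) {
  for (a in x$ancestries)
    cat(sprintf("  %s: mean %.3f, CI [%.3f, %.3f], n_hap %d\n", a,
                x$mean[[a]], x$ci[1L, a], x$ci[2L, a], as.integer(x$n_hap[[a]])))
  invisible(x)
}

#' Bootstrap test for an allele-frequency difference between two panels
#'
#' Resamples individuals with replacement within each panel, recomputes the
#' single-site posterior-mean frequency for the chosen ancestry in each,
#' and reports the fraction of replicates in which the difference crosses
#' zero (raw p), with a Bonferroni adjustment for the number of sites
#' tested.
#'
#' @param G1,G2 genotype vectors of the site in the two panels.
#' @param A1,A2 diploid ancestry states (`"EUR/NAT"` style) in the panels.
#' @param ancestry which ancestry's frequency to compare.
#' @param grid1,grid2 [frequency_grid()]s with each panel's priors.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @param n_tests number of sites tested (Bonferroni denominator).
#' @return list with `diff` (point estimate), `p_raw`, `p_bonferroni`.
#' @export
ancestry_freq_difference_test <- function(G1, A1, G2, A2, ancestry,
                                          grid1 = frequency_grid(),
                                          grid2 = frequency_grid(),
                                          n_boot = 200, seed = 1,
                                          n_tests = 1) {
  if (n_boot * 0.05 < n_tests)
    stop("n_boot too small to resolve the Bonferroni threshold for ",
         n_tests, " tests")
  set.seed(as.integer(seed))
  mean_of <- function(G, A, grid) {
    sp <- site_posterior(G, A, grid)
    if (!ancestry %in% sp$ancestries) return(NA_real_)
    sp$mean[[ancestry]]
  }
  m1 <- mean_of(G1, A1, grid1); m2 <- mean_of(G2, A2, grid2)
  diff0 <- m1 - m2
  n1 <- length(G1); n2 <- length(G2)
  diffs <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    i1 <- sample.int(n1, n1, replace = TRUE)
    i2 <- sample.int(n2, n2, replace = TRUE)
    diffs[b] <- tryCatch(
      mean_of(G1[i1], A1[i1], grid1) - mean_of(G2[i2], A2[i2], grid2),
      error = function(e) NA_real_)
  }
  diffs <- diffs[!is.na(diffs)]
  p_raw <- mean(diffs * sign(diff0) <= 0)
  list(diff = diff0, p_raw = p_raw,
       p_bonferroni = min(1, p_raw * n_tests), n_boot_used = length(diffs))
}
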