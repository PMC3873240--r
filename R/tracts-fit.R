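# Maximum-likelihood fitting of migration-model families to tract histograms.
#
# Parameters are optimized on an unconstrained scale (log times, softmax
# founding fractions, logit-capped rates) by Nelder-Mead from multiple random
# starts followed by a quasi-Newton polish of the best start.

# ---- parameter transforms ---------------------------------------------------

par_to_unc <- function(family, par) {
  u <- c(lt0 = log(par[["t0"]] - 1))
  fA <- max(1 - par[["fNAT"]] - par[["fEUR"]], 1e-8)
  u <- c(u, xN = log(par[["fNAT"]] / fA + 1e-12), xE = log(par[["fEUR"]] / fA + 1e-12))
  if (family == "founding_plus_continuing")
    u <- c(u, qE = stats::qlogis(pmin(pmax(par[["mEUR"]] / 0.2, 1e-8), 1 - 1e-8)),
           qN = stats::qlogis(pmin(pmax(par[["mNAT"]] / 0.2, 1e-8), 1 - 1e-8)))
  if (family == "founding_plus_second_NAT_pulse")
    u <- c(u, q2 = stats::qlogis(pmin(pmax((par[["t2"]] - 1) / (par[["t0"]] - 2), 1e-8), 1 - 1e-8)),
           qm = stats::qlogis(pmin(pmax(par[["mNAT2"]] / 0.5, 1e-8), 1 - 1e-8)))
  if (family == "two_EUR_two_AFR_pulses")
    u <- c(u, q2 = stats::qlogis(pmin(pmax((par[["t2"]] - 1) / (par[["t0"]] - 2), 1e-8), 1 - 1e-8)),
           qE2 = stats::qlogis(pmin(pmax(par[["mEUR2"]] / 0.5, 1e-8), 1 - 1e-8)),
           qA2 = stats::qlogis(pmin(pmax(par[["mAFR2"]] / 0.5, 1e-8), 1 - 1e-8)))
  u
}

unc_to_par <- function(family, u) {
  # cap the onset at 200 generations: far beyond any post-contact history,
  # and keeps the generation-indexed state space at desk size
  t0 <- 1 + exp(min(u[[1L]], log(199)))
  eN <- exp(u[[2L]]); eE <- exp(u[[3L]])
  den <- 1 + eN + eE
  par <- c(t0 = t0, fNAT = eN / den, fEUR = eE / den)
  if (family == "founding_plus_continuing")
    par <- c(par, mEUR = 0.2 * stats::plogis(u[[4L]]), mNAT = 0.2 * stats::plogis(u[[5L]]))
  if (family == "founding_plus_second_NAT_pulse")
    par <- c(par, t2 = 1 + stats::plogis(u[[4L]]) * (t0 - 2),
             mNAT2 = 0.5 * stats::plogis(u[[5L]]))
  if (family == "two_EUR_two_AFR_pulses")
    par <- c(par, t2 = 1 + stats::plogis(u[[4L]]) * (t0 - 2),
             mEUR2 = 0.5 * stats::plogis(u[[5L]]), mAFR2 = 0.5 * stats::plogis(u[[6L]]))
  par
}

random_start <- function(family) {
  par <- c(t0 = runif(1, 6, 22))
  f <- c(runif(1, 0.05, 0.9), runif(1, 0.05, 0.9), runif(1, 0.02, 0.3))
  f <- f / sum(f)
  par <- c(par, fNAT = f[1], fEUR = f[2])
  if (family == "founding_plus_continuing")
    par <- c(par, mEUR = runif(1, 0.001, 0.05), mNAT = runif(1, 0.001, 0.05))
  if (family == "founding_plus_second_NAT_pulse")
    par <- c(par, t2 = runif(1, 2.2, par[["t0"]] - 2), mNAT2 = runif(1, 0.005, 0.1))
  if (family == "two_EUR_two_AFR_pulses")
    par <- c(par, t2 = runif(1, 2.2, par[["t0"]] - 2),
             mEUR2 = runif(1, 0.01, 0.2), mAFR2 = runif(1, 0.01, 0.2))
  par
}

#' Fit a migration-model family to an observed tract histogram
#'
#' Maximizes the Poisson bin-count likelihood of [expected_tract_counts()]
#' over the family's parameters, from `n_starts` random starts (Nelder-Mead
#' on the unconstrained scale, best start polished by BFGS). The running
#' best log-likelihood across evaluations is recorded as a non-decreasing
#' trace.
#'
#' @param obs observed `tract_histogram` (non-empty).
#' @param family model family id (see [family_history()]).
#' @param n_starts number of random starts (default 10).
#' @param seed integer seed making the start sequence reproducible.
#' @param start optional named parameter vector used as the first start.
#' @return object of class `tracts_fit` with elements `family`, `par`
#'   (ML parameters, natural scale), `loglik`, `bic`, `n_tracts`, `trace`,
#'   `history` (the fitted [migration_history()]), plus the inputs needed to
#'   re-evaluate the fit.
#' @export
fit_tracts_model <- function(obs, family, n_starts = 10, seed = 1, start = NULL) {
  family <- match.arg(family, TRACTS_FAMILIES)
  if (sum(obs) == 0) stop("observed histogram is empty")
  bins <- attr(obs, "bins"); genome <- attr(obs, "genome")
  nh <- attr(obs, "n_haplotypes")
  set.seed(as.integer(seed))
  trace_env <- new.env()
  trace_env$best <- -Inf; trace_env$trace <- numeric(0)
  negll <- function(u) {
    par <- unc_to_par(family, u)
    ll <- tryCatch({
      mh <- family_history(family, par)
      poisson_loglik(obs, expected_tract_counts(mh, bins, genome, nh))
    }, error = function(e) -Inf)
    if (!is.finite(ll)) return(1e9)
    if (ll > trace_env$best) trace_env$best <- ll
    trace_env$trace <- c(trace_env$trace, trace_env$best)
    -ll
  }
  starts <- lapply(seq_len(n_starts), function(i) {
    if (i == 1L && !is.null(start)) start else random_start(family)
  })
  best <- NULL
  for (s in starts) {
    u0 <- par_to_unc(family, s)
    if (negll(u0) >= 1e9) next
    o <- stats::optim(u0, negll, method = "Nelder-Mead",
                      control = list(maxit = 250, reltol = 1e-7))
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) stop("no finite-likelihood start found for family ", family)
  o <- stats::optim(best$par, negll, method = "BFGS",
                    control = list(maxit = 50, reltol = 1e-9))
  if (o$value < best$value) best <- o
  par <- unc_to_par(family, best$par)
  ll <- -best$value
  k <- length(par)
  n_tr <- sum(obs)
  structure(list(family = family, par = par, loglik = ll,
                 bic = -2 * ll + k * log(max(n_tr, 1)),
                 n_tracts = n_tr, trace = trace_env$trace,
                 history = family_history(family, par),
                 obs = obs, n_starts = n_starts, seed = seed),
            class = "tracts_fit")
}

#' @export
print.tracts_fit <- function(x, ...) {
  cat(sprintf("<tracts_fit> family %s | logLik %.2f | BIC %.2f\n",
              x$family, x$loglik, x$bic))
  print(round(x$par, 4))
  if (!is.null(x$ci)) {
    cat("bootstrap 95% CIs:\n")
    print(round(x$ci, 3))
  }
  invisible(x)
}

#' @export
coef.tracts_fit <- function(object, ...) object$par

#' @export
logLik.tracts_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$par), class = "logLik")
}

#' @export
summary.tracts_fit <- function(object, ...) {
  cat("Migration-model fit to ancestry tract lengths\n")
  print(object)
  cat(sprintf("onset of admixture: %.2f generations ago (%.0f years at 30 y/gen)\n",
              object$par[["t0"]], 30 * object$par[["t0"]]))
  p <- ancestry_proportions(object$history)
  cat("implied ancestry proportions:",
      paste(sprintf("%s %.3f", names(p), p), collapse = ", "), "\n")
  invisible(object)
}

#' Select among fitted migration models by information criterion
#'
#' Returns the fit minimizing BIC; the likelihood-ratio statistic between the
#' best and the best-nested-simpler fit is reported alongside.
#'
#' @param fits list of `tracts_fit` objects on the same observed histogram.
#' @return the selected `tracts_fit`, with attribute `selection` (data.frame
#'   of family, loglik, n_par, BIC) and attribute `lr` (likelihood-ratio
#'   statistic of best vs simplest).
#' @export
select_model <- function(fits) {
  if (length(fits) < 2L) stop("need at least two fits to select among")
  obs0 <- fits[[1L]]$obs
  for (f in fits)
    if (!isTRUE(all.equal(as.numeric(f$obs), as.numeric(obs0))))
      stop("fits must be computed on the same observed histogram")
  tab <- data.frame(
    family = vapply(fits, function(f) f$family, ""),
    loglik = vapply(fits, function(f) f$loglik, 0),
    n_par = vapply(fits, function(f) length(f$par), 0L),
    bic = vapply(fits, function(f) f$bic, 0))
  best <- fits[[which.min(tab$bic)]]
  simplest <- fits[[which.min(tab$n_par)]]
  attr(best, "selection") <- tab
  attr(best, "lr") <- 2 * (best$loglik - simplest$loglik)
  best
}

#' Bootstrap confidence intervals for tract-model parameters
#'
#' Resamples diploid individuals with replacement, rebuilds the tract
#' histogram, refits the family (warm-started at the point estimate), and
#' returns percentile intervals.
#'
#' @param tracts a `tract_set`.
#' @param family model family id.
#' @param n_boot number of bootstrap replicates (>= 2).
#' @param seed integer seed.
#' @param bins histogram bin edges (default [length_bins()] of the genome).
#' @param level confidence level (default 0.95).
#' @param n_starts random starts per refit (warm start is always included).
#' @return the point-estimate `tracts_fit` with element `ci` (matrix with
#'   columns `lower`, `upper` per parameter) and `boot` (replicate matrix).
#' @export
bootstrap_tracts_ci <- function(tracts, family, n_boot = 100, seed = 1,
                                bins = NULL, level = 0.95, n_starts = 4) {
  n_ind <- attr(tracts, "n_diploid")
  if (n_ind < 2L) stop("need at least two individuals to bootstrap")
  if (n_boot < 2L) stop("n_boot must be >= 2")
  genome <- attr(tracts, "genome")
  if (is.null(bins)) bins <- length_bins(genome)
  obs <- tract_histogram(tracts, bins)
  fit0 <- fit_tracts_model(obs, family, n_starts = max(n_starts, 4), seed = seed)
  set.seed(as.integer(seed) + 1L)
  reps <- matrix(NA_real_, nrow = n_boot, ncol = length(fit0$par),
                 dimnames = list(NULL, names(fit0$par)))
  for (b in seq_len(n_boot)) {
    ids <- sample.int(n_ind, n_ind, replace = TRUE)
    pieces <- lapply(seq_along(ids), function(k) {
      d <- tracts[tracts$ind == ids[k], , drop = FALSE]
      d$ind <- k
      d
    })
    tb <- tract_set(do.call(rbind, pieces), genome, n_diploid = n_ind,
                    validate = FALSE)
    ob <- tract_histogram(tb, bins)
    fb <- tryCatch(
      fit_tracts_model(ob, family, n_starts = n_starts, seed = seed + b,
                       start = fit0$par),
      error = function(e) NULL)
    if (!is.null(fb)) reps[b, ] <- fb$par
  }
  a <- (1 - level) / 2
  ci <- t(apply(reps, 2, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE))
  colnames(ci) <- c("lower", "upper")
  fit0$ci <- ci
  fit0$boot <- reps
  fit0
}
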