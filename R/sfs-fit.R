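# Pairwise composite-likelihood fitting of split demographic models.
#
# The model has no migration between the daughter populations, so the
# three-population spectrum carries little information beyond its three
# two-population margins; the composite likelihood multiplies independent
# Poisson likelihoods over the unmasked entries of the three pairwise
# spectra. theta enters every expected entry linearly and is profiled
# analytically (theta_hat = sum(obs)/sum(expected)).

#' Composite Poisson log-likelihood of pairwise spectra
#'
#' @param obs_pairs named list of observed two-population [joint_sfs()]
#'   objects (names like `"MXL_CLM"`), as produced by [sfs_pairs()].
#' @param model a [split_model()].
#' @param engine_opts engine options passed to [expected_joint_sfs()].
#' @param theta fixed mutational scale; `NULL` (default) profiles it
#'   analytically as `sum(obs)/sum(expected)`.
#' @return scalar log-likelihood with attributes `theta` (profiled or as
#'   given) and `by_pair`.
#' @export
composite_loglik <- function(obs_pairs, model, engine_opts = list(),
                             theta = NULL) {
  sizes <- pair_sample_sizes(obs_pairs)
  expd <- expected_joint_sfs(model, sizes, engine_opts)
  tot_obs <- 0; tot_exp <- 0
  for (nm in names(obs_pairs)) {
    em <- expd[[match_pair(nm, names(expd))]]
    ok <- !attr(obs_pairs[[nm]], "mask")
    if (!any(ok)) stop("all-masked spectrum")
    tot_obs <- tot_obs + sum(obs_pairs[[nm]][ok])
    tot_exp <- tot_exp + sum(em[ok])
  }
  if (is.null(theta)) theta <- tot_obs / tot_exp
  ll <- 0; by_pair <- numeric(length(obs_pairs))
  names(by_pair) <- names(obs_pairs)
  for (nm in names(obs_pairs)) {
    em <- expd[[match_pair(nm, names(expd))]]
    ok <- !attr(obs_pairs[[nm]], "mask")
    mu <- pmax(theta * em[ok], 1e-300)
    x <- obs_pairs[[nm]][ok]
    by_pair[nm] <- sum(x * log(mu) - mu - lgamma(x + 1))
    ll <- ll + by_pair[nm]
  }
  structure(ll, theta = theta, by_pair = by_pair)
}

# pair names may list the two populations in either order
match_pair <- function(nm, candidates) {
  if (nm %in% candidates) return(nm)
  rev_nm <- paste(rev(strsplit(nm, "_")[[1L]]), collapse = "_")
  if (rev_nm %in% candidates) return(rev_nm)
  stop("no expected spectrum for pair ", nm)
}

pair_sample_sizes <- function(obs_pairs) {
  sizes <- integer(0)
  for (nm in names(obs_pairs)) {
    pops <- attr(obs_pairs[[nm]], "pops")
    n <- sample_sizes(obs_pairs[[nm]])
    sizes[pops] <- n
  }
  sizes
}

#' Pairwise margins of a three-population SFS (or per-locus counts)
#'
#' @param counts integer matrix of per-locus derived counts (loci x pops)
#'   as in [simulate_split_sfs()]'s `counts`.
#' @param sample_sizes named haploid sizes.
#' @param project_to optional named sizes to project each pair down to.
#' @return named list of two-population [joint_sfs()] objects.
#' @export
sfs_pairs <- function(counts, sample_sizes, project_to = NULL) {
  pops <- colnames(counts)
  prs <- utils::combn(pops, 2L, simplify = FALSE)
  out <- list()
  for (pr in prs) {
    s <- counts_to_sfs(counts[, pr, drop = FALSE], sample_sizes[pr])
    if (!is.null(project_to))
      s <- project_sfs(s, project_to[pr])
    out[[paste(pr, collapse = "_")]] <- s
  }
  out
}

# ---- parameter transforms (diffusion units, N_ref = N_anc) ------------------

# free parameters: tauF, tau1/tauF, tau2/tau1 (logit), nu_bot, nu_1..3 (log)
sm_to_unc <- function(model) {
  Nref2 <- 2 * model$N_anc
  tauF <- model$T_found / Nref2
  tau1 <- model$T1 / Nref2
  u <- c(ltF = log(tauF),
         q1 = stats::qlogis(min(max(tau1 / tauF, 1e-6), 1 - 1e-6)),
         lnb = log(model$N_bot / model$N_anc))
  if (!is.null(model$T2)) {
    tau2 <- model$T2 / Nref2
    u <- c(u, q2 = stats::qlogis(min(max(tau2 / max(tau1, 1e-12), 1e-6), 1 - 1e-6)))
  }
  c(u, log(model$sizes / model$N_anc))
}

unc_to_sm <- function(u, template) {
  Nref2 <- 2 * template$N_anc
  np <- length(template$sizes)
  tauF <- exp(min(u[[1L]], log(2)))       # founding no older than 4 N_ref gens
  tau1 <- tauF * stats::plogis(u[[2L]])
  nu_bot <- min(max(exp(u[[3L]]), 1e-6), 1)   # floor keeps step counts finite
  k <- 4L
  if (np == 3L) { tau2 <- tau1 * stats::plogis(u[[4L]]); k <- 5L } else tau2 <- NULL
  nus <- exp(pmin(u[k:(k + np - 1L)], log(500)))
  split_model(N_anc = template$N_anc, T_found = tauF * Nref2,
              N_bot = nu_bot * template$N_anc,
              sizes = stats::setNames(nus * template$N_anc, names(template$sizes)),
              T1 = tau1 * Nref2, T2 = if (!is.null(tau2)) tau2 * Nref2 else NULL,
              order = template$order, r = template$r,
              recent_bottleneck = template$recent_bottleneck,
              bottleneck_duration = template$bottleneck_duration)
}

#' Fit a split model to pairwise spectra by composite likelihood
#'
#' Optimizes the composite Poisson likelihood over the model's free
#' parameters (founding time, bottleneck size, split times, branch sizes;
#' `r` fixed, theta profiled) for each requested split ordering, by
#' Nelder-Mead from `n_starts` starts on a single optimization grid,
#' followed by a final evaluation with grid extrapolation.
#'
#' @param obs_pairs named list of observed two-population [joint_sfs()].
#' @param template a [split_model()] providing the anchor `N_anc`, `r`,
#'   population names and the starting parameter magnitudes.
#' @param orderings character vector of populations to try as the
#'   first-splitting branch (default: all).
#' @param n_starts random starts per ordering.
#' @param seed integer seed.
#' @param engine_opts engine options for the final (reporting) evaluation.
#' @param opt_grid single grid size used during optimization; `NULL` uses
#'   the reporting engine options.
#' @param fix names of parameters held at their template values (among
#'   `tau_found`, `nu_bot`, `tau1`, `tau2`).
#' @param theta fixed mutational scale (`NULL` profiles it).
#' @param polish run the restarted-simplex + quasi-Newton polish (disable
#'   for cheap warm-started refits such as bootstrap replicates).
#' @return object of class `demography_fit`: `model` (best
#'   [split_model()]), `loglik`, `theta`, `by_ordering` (log-likelihood per
#'   ordering), `order`, `par` (named diffusion-scale parameters).
#' @export
fit_split_model <- function(obs_pairs, template,
                            orderings = names(template$sizes),
                            n_starts = 4, seed = 1,
                            engine_opts = list(), opt_grid = NULL,
                            fix = character(), theta = NULL, polish = TRUE) {
  set.seed(as.integer(seed))
  # optimization can run on a single coarse grid (fast, but biased in the
  # singleton classes) or, with opt_grid = NULL, on the same extrapolated
  # grids as the reported fit
  opt_opts <- if (is.null(opt_grid)) {
    utils::modifyList(default_engine_opts(), engine_opts)
  } else {
    utils::modifyList(default_engine_opts(),
                      c(engine_opts, list(extrap = FALSE, grids = opt_grid)))
  }
  fits <- list()
  for (ord in orderings) {
    tmpl <- template; tmpl$order <- ord
    u_full0 <- sm_to_unc(tmpl)
    fix_idx <- match_fixed(fix, names(u_full0))
    free_idx <- setdiff(seq_along(u_full0), fix_idx)
    negll <- function(u) {
      v <- tryCatch({
        uf <- u_full0; uf[free_idx] <- u
        m <- unc_to_sm(uf, tmpl)
        -as.numeric(composite_loglik(obs_pairs, m, opt_opts, theta = theta))
      }, error = function(e) NA_real_)
      if (!is.finite(v)) 1e12 else v
    }
    u0 <- u_full0[free_idx]
    best <- NULL
    for (k in seq_len(n_starts)) {
      uk <- if (k == 1L) u0 else u0 + stats::rnorm(length(u0), 0, 0.6)
      if (negll(uk) >= 1e12) next
      o <- stats::optim(uk, negll, method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-8))
      if (is.null(best) || o$value < best$value) best <- o
    }
    if (is.null(best)) stop("optimizer failed for ordering ", ord)
    if (polish) {
      # polish: restarted simplex (rebuilt geometry) then quasi-Newton
      o <- stats::optim(best$par, negll, method = "Nelder-Mead",
                        control = list(maxit = 800, reltol = 1e-10))
      if (o$value < best$value) best <- o
      o <- stats::optim(best$par, negll, method = "BFGS",
                        control = list(maxit = 40, reltol = 1e-10))
      if (o$value < best$value) best <- o
    }
    up <- u_full0; up[free_idx] <- best$par
    best$par_full <- up
    fits[[ord]] <- best
  }
  lls <- -vapply(fits, function(f) f$value, 0)
  ord_best <- names(which.max(lls))
  tmpl <- template; tmpl$order <- ord_best
  model <- unc_to_sm(fits[[ord_best]]$par_full, tmpl)
  final_opts <- utils::modifyList(default_engine_opts(), engine_opts)
  ll <- composite_loglik(obs_pairs, model, final_opts, theta = theta)
  structure(list(model = model, loglik = as.numeric(ll),
                 theta = attr(ll, "theta"), by_ordering = lls,
                 order = ord_best,
                 par = fitted_diffusion_par(model),
                 obs_pairs = obs_pairs, template = template, seed = seed),
            class = "demography_fit")
}

# map user-facing fixed-parameter names to transform coordinates
match_fixed <- function(fix, unames) {
  if (!length(fix)) return(integer(0))
  key <- c(tau_found = "ltF", nu_bot = "lnb", tau1 = "q1", tau2 = "q2")
  unknown <- setdiff(fix, names(key))
  if (length(unknown)) stop("cannot fix: ", paste(unknown, collapse = ", "))
  idx <- match(unname(key[fix]), unames)
  if (anyNA(idx)) stop("fixed parameter absent from this model family")
  idx
}

fitted_diffusion_par <- function(model) {
  Nref2 <- 2 * model$N_anc
  p <- c(tau_found = model$T_found / Nref2,
         nu_bot = model$N_bot / model$N_anc,
         tau1 = model$T1 / Nref2)
  if (!is.null(model$T2)) p <- c(p, tau2 = model$T2 / Nref2)
  c(p, stats::setNames(model$sizes / model$N_anc,
                       paste0("nu_", names(model$sizes))))
}

#' @export
print.demography_fit <- function(x, ...) {
  cat(sprintf("<demography_fit> best ordering: %s first | composite logLik %.2f | theta %.3g\n",
              x$order, x$loglik, x$theta))
  cat("per-ordering logLik:\n"); print(round(x$by_ordering, 2))
  print(x$model)
  invisible(x)
}

#' @export
coef.demography_fit <- function(object, ...) object$par

#' @export
logLik.demography_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$par) + 1, class = "logLik")
}

#' Anchor a demographic fit to physical units
#'
#' The composite likelihood identifies times in units of `2 N_ref`
#' generations and sizes relative to `N_ref`; one physical anchor fixes the
#' scale. Anchoring the founding bottleneck at `T_found_years` implies
#' `N_ref = T_found_years / (gen_years * 2 * tau_found)`; all times and
#' sizes scale linearly with the anchor and the per-site mutation rate is
#' `mu = theta / (4 N_ref L_callable)` (inversely proportional to it).
#'
#' @param fit a `demography_fit`.
#' @param T_found_years calendar age of the founding bottleneck (default
#'   16000 years).
#' @param gen_years years per generation (default 30).
#' @param L_callable number of callable sites behind the spectra.
#' @return list with `N_ref`, physical `times_years`, `sizes`, `mu`, and
#'   `rescale`, a function returning the same table under a different
#'   anchor without refitting.
#' @export
calibrate_physical <- function(fit, T_found_years = 16000, gen_years = 30,
                               L_callable) {
  if (L_callable <= 0) stop("L_callable must be positive")
  par <- fit$par
  make <- function(anchor_years) {
    N_ref <- anchor_years / (gen_years * 2 * par[["tau_found"]])
    times <- c(T_found = par[["tau_found"]],
               T1 = par[["tau1"]],
               T2 = if ("tau2" %in% names(par)) par[["tau2"]] else NA)
    times_years <- times * 2 * N_ref * gen_years
    nus <- par[grep("^nu_", names(par))]
    sizes <- nus * N_ref
    names(sizes) <- sub("^nu_", "", names(sizes))
    mu <- fit$theta / (4 * N_ref * L_callable)
    list(N_ref = N_ref, times_years = times_years, sizes = sizes, mu = mu,
         anchor_years = anchor_years)
  }
  out <- make(T_found_years)
  out$rescale <- make
  out
}

#' Block bootstrap for demographic parameters
#'
#' Resamples blocks of loci with replacement, rebuilds the pairwise
#' spectra, and refits (warm-started at the point estimate, best ordering
#' re-chosen each replicate). Reports percentile confidence intervals, the
#' distribution of `T2/T1`, and how often each split ordering wins.
#'
#' @param counts per-locus derived count matrix (loci x populations).
#' @param sample_sizes named haploid sizes for `counts`.
#' @param fit the point-estimate `demography_fit`.
#' @param n_boot number of replicates.
#' @param n_blocks number of contiguous locus blocks (>= 2).
#' @param seed integer seed.
#' @param project_to optional projection sizes (as used for the fit).
#' @param level confidence level.
#' @param orderings split orderings tried per replicate (all, by default;
#'   restrict to the point estimate's ordering for cheap interval-only runs).
#' @param ... further arguments passed to [fit_split_model()].
#' @return list with `ci` (matrix lower/upper per diffusion parameter),
#'   `order_freq`, `t2_t1` (vector across replicates), `reps`.
#' @export
bootstrap_demography <- function(counts, sample_sizes, fit, n_boot = 20,
                                 n_blocks = 50, seed = 1, project_to = NULL,
                                 level = 0.95,
                                 orderings = names(fit$model$sizes), ...) {
  if (n_blocks < 2) stop("need at least 2 blocks")
  set.seed(as.integer(seed))
  n <- nrow(counts)
  blk <- cut(seq_len(n), n_blocks, labels = FALSE)
  par0 <- fit$par
  reps <- matrix(NA_real_, n_boot, length(par0),
                 dimnames = list(NULL, names(par0)))
  orders <- character(n_boot)
  for (b in seq_len(n_boot)) {
    take <- sample.int(n_blocks, n_blocks, replace = TRUE)
    rows <- unlist(lapply(take, function(k) which(blk == k)), use.names = FALSE)
    prs <- sfs_pairs(counts[rows, , drop = FALSE], sample_sizes, project_to)
    fb <- tryCatch(
      fit_split_model(prs, fit$model, orderings = orderings,
                      n_starts = 1, seed = seed + b, ...),
      error = function(e) NULL)
    if (is.null(fb)) next
    reps[b, ] <- fb$par
    orders[b] <- fb$order
  }
  a <- (1 - level) / 2
  ci <- t(apply(reps, 2, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE))
  colnames(ci) <- c("lower", "upper")
  t2_t1 <- if ("tau2" %in% colnames(reps)) reps[, "tau2"] / reps[, "tau1"] else NULL
  list(ci = ci, order_freq = table(orders[orders != ""]), t2_t1 = t2_t1,
       reps = reps)
}

#' Sensitivity of a fit to a fixed post-contact bottleneck
#'
#' Re-fits the model with a fully fixed recent bottleneck (timing, duration
#' and severity from non-genetic sources) imposed on one branch, and
#' reports the ratio of the affected branch's inferred (pre-bottleneck)
#' size with and without the bottleneck assumption.
#'
#' @param fit the no-bottleneck `demography_fit`.
#' @param bottleneck_spec `list(pop =, T_start =, T_end =, severity =)`
#'   with times in generations back; all elements must be fixed values.
#' @param ... passed to [fit_split_model()].
#' @return list with `fit_bottleneck` (the refit), `size_ratio`
#'   (with/without, for the affected branch), `spec`.
#' @export
bottleneck_sensitivity <- function(fit, bottleneck_spec, ...) {
  need <- c("pop", "T_start", "T_end", "severity")
  if (!all(need %in% names(bottleneck_spec)) ||
      !all(vapply(bottleneck_spec[need], function(v) length(v) == 1L, TRUE)))
    stop("bottleneck spec must fix pop, T_start, T_end and severity")
  tmpl <- fit$model
  tmpl$recent_bottleneck <- bottleneck_spec
  fb <- fit_split_model(fit$obs_pairs, tmpl,
                        orderings = fit$order, ...)
  pop <- bottleneck_spec$pop
  ratio <- fb$model$sizes[[pop]] / fit$model$sizes[[pop]]
  list(fit_bottleneck = fb, size_ratio = ratio, spec = bottleneck_spec)
}
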