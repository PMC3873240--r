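# Negative ascertainment of Native-background variants.
#
# Variants observed in any outgroup panel (African, European, Asian
# reference samples), or observed in the admixed panel inside segments with
# no Native American ancestry, are discarded. Under the perfect-
# ascertainment assumption every surviving derived allele sits on a Native
# American haplotype; the residual leakage from European haplotypes in
# NAT/EUR segments is estimated empirically from mock all-European
# pseudo-samples and subtracted (it is concentrated in singletons).

#' Negative-ascertainment filter
#'
#' @param tables named list of [ancestry_genotype_table()] objects (one per
#'   admixed panel) sharing the same sites, or a single table.
#' @param outgroup_genotypes list of derived-allele count vectors or
#'   genotype matrices (sites x individuals), one per outgroup panel,
#'   aligned to the same sites. "Observed" means at least one derived call,
#'   with no frequency threshold.
#' @return object of class `ascertainment`: `sites` (retained site indices),
#'   `removed_by_outgroup`, `removed_by_nonNAT` (logical per input site),
#'   `nat_n` and `nat_d` (per retained site and panel: number of NAT
#'   haplotypes and NAT-attributed derived alleles), `panels`.
#' @export
negative_ascertainment_filter <- function(tables, outgroup_genotypes = list()) {
  if (inherits(tables, "ancestry_genotype_table")) tables <- list(panel = tables)
  ns <- nrow(tables[[1L]]$G)
  for (tb in tables)
    if (nrow(tb$G) != ns) stop("panels must share the same sites")
  out_obs <- rep(FALSE, ns)
  for (og in outgroup_genotypes) {
    cnt <- if (is.matrix(og)) rowSums(og, na.rm = TRUE) else as.numeric(og)
    if (length(cnt) != ns) stop("outgroup panel does not match the site set")
    out_obs <- out_obs | (cnt > 0)
  }
  non_nat <- rep(FALSE, ns)
  any_var <- rep(FALSE, ns)
  for (tb in tables) {
    nNAT <- (tb$A1 == "NAT") + (tb$A2 == "NAT")
    obs_noNAT <- tb$G > 0 & !is.na(tb$G) & !is.na(nNAT) & nNAT == 0L
    non_nat <- non_nat | rowSums(obs_noNAT) > 0
    any_var <- any_var | rowSums(tb$G > 0, na.rm = TRUE) > 0
  }
  keep <- which(!out_obs & !non_nat & any_var)
  nat_n <- nat_d <- matrix(0L, length(keep), length(tables),
                           dimnames = list(NULL, names(tables)))
  for (j in seq_along(tables)) {
    tb <- tables[[j]]
    nNAT <- (tb$A1[keep, , drop = FALSE] == "NAT") +
      (tb$A2[keep, , drop = FALSE] == "NAT")
    G <- tb$G[keep, , drop = FALSE]
    ok <- !is.na(G) & !is.na(nNAT)
    nN <- ifelse(ok, nNAT, 0L)
    # perfect ascertainment: derived copies attributed to the NAT background,
    # capped by the number of NAT haplotypes in the diploid state
    dN <- ifelse(ok, pmin(G, nNAT), 0L)
    nat_n[, j] <- as.integer(rowSums(nN))
    nat_d[, j] <- as.integer(rowSums(dN))
  }
  structure(list(sites = keep, removed_by_outgroup = out_obs,
                 removed_by_nonNAT = non_nat & !out_obs,
                 nat_n = nat_n, nat_d = nat_d, panels = names(tables)),
            class = "ascertainment")
}

#' @export
print.ascertainment <- function(x, ...) {
  cat(sprintf("<ascertainment> %d sites retained (%d removed by outgroup, %d by non-NAT observation)\n",
              length(x$sites), sum(x$removed_by_outgroup),
              sum(x$removed_by_nonNAT)))
  invisible(x)
}

#' Empirical singleton-bias correction from mock European panels
#'
#' Builds pseudo-samples made entirely of European/European diploid
#' segments, runs the same negative-ascertainment scheme on them, and
#' counts the surviving variants per derived-frequency class: that is the
#' expected leakage of European variation through the filter, dominated by
#' the singleton class.
#'
#' @param table an [ancestry_genotype_table()].
#' @param outgroup_genotypes as in [negative_ascertainment_filter()].
#' @param n_mock number of mock diploid individuals per pseudo-sample
#'   (mimicking the European haplotype count of the panel).
#' @param n_rep number of seeded pseudo-sample replicates to average.
#' @param seed integer seed.
#' @return object of class `ascertainment_bias`: `correction` (expected
#'   leakage count per derived-count class `1..2*n_mock`), `n_mock`.
#' @export
singleton_bias_estimate <- function(table, outgroup_genotypes = list(),
                                    n_mock, n_rep = 5, seed = 1) {
  set.seed(as.integer(seed))
  ns <- nrow(table$G)
  isEE <- table$A1 == "EUR" & table$A2 == "EUR" & !is.na(table$G)
  n_EE <- rowSums(isEE)
  usable <- n_EE >= n_mock
  if (!any(usable))
    stop("insufficient EUR/EUR material: need at least ", n_mock,
         " EUR/EUR diploids at some site")
  out_obs <- rep(FALSE, ns)
  for (og in outgroup_genotypes) {
    cnt <- if (is.matrix(og)) rowSums(og, na.rm = TRUE) else as.numeric(og)
    out_obs <- out_obs | (cnt > 0)
  }
  acc <- numeric(2L * n_mock)
  for (r in seq_len(n_rep)) {
    d_mock <- integer(ns)
    for (i in which(usable & !out_obs)) {
      cols <- sample(which(isEE[i, ]), n_mock)
      d_mock[i] <- sum(table$G[i, cols])
    }
    sel <- d_mock > 0
    acc <- acc + tabulate(d_mock[sel], nbins = 2L * n_mock)
  }
  structure(list(correction = acc / n_rep, n_mock = n_mock,
                 n_usable_sites = sum(usable)),
            class = "ascertainment_bias")
}

#' @export
print.ascertainment_bias <- function(x, ...) {
  cat(sprintf("<ascertainment_bias> excess singletons %.1f; largest non-singleton correction %.2f\n",
              x$correction[1L], if (length(x$correction) > 1L) max(x$correction[-1L]) else 0))
  invisible(x)
}

#' SFS over Native American haplotypes from ascertained sites
#'
#' Tabulates the NAT-attributed derived counts of the retained sites over
#' NAT haplotypes only. The per-site NAT sample size varies (it depends on
#' the local-ancestry mosaic), so every site is hypergeometrically projected
#' to the common target size; sites carrying fewer NAT haplotypes than the
#' target are dropped. A leakage correction vector, if supplied, is
#' projected to the same size and subtracted (truncating at zero).
#'
#' @param result an `ascertainment` object.
#' @param sample_sizes named vector of target NAT haploid sizes, one per
#'   panel (subset of `result$panels`).
#' @param correction optional [singleton_bias_estimate()] output (single
#'   panel) or named list of them.
#' @return a [joint_sfs()] over NAT haplotypes (1-3 panels; joint classes
#'   from per-site outer products of the panel projections).
#' @export
ascertained_nat_sfs <- function(result, sample_sizes, correction = NULL) {
  panels <- names(sample_sizes)
  if (!all(panels %in% colnames(result$nat_n)))
    stop("unknown panel in sample_sizes")
  ns <- nrow(result$nat_n)
  d <- sample_sizes + 1L
  if (ns == 0L)
    return(joint_sfs(array(0, dim = d), pops = panels))
  for (p in panels)
    if (sample_sizes[[p]] > max(result$nat_n[, p]))
      stop("target size exceeds the maximum observed NAT haplotypes for ", p)
  proj <- vector("list", length(panels)); names(proj) <- panels
  for (p in panels) {
    n_t <- sample_sizes[[p]]
    nn <- result$nat_n[, p]; dd <- result$nat_d[, p]
    M <- matrix(0, ns, n_t + 1L)
    ok <- nn >= n_t
    for (i in which(ok))
      M[i, ] <- stats::dhyper(0:n_t, dd[i], nn[i] - dd[i], n_t)
    M[!ok, ] <- 0
    proj[[p]] <- M
  }
  if (length(panels) == 1L) {
    spec <- colSums(proj[[1L]])
  } else {
    spec <- array(0, dim = d)
    for (i in seq_len(ns)) {
      v <- proj[[1L]][i, ]
      for (p in panels[-1L]) v <- outer(v, proj[[p]][i, ])
      spec <- spec + v
    }
  }
  if (!is.null(correction)) {
    if (inherits(correction, "ascertainment_bias"))
      correction <- stats::setNames(list(correction), panels[1L])
    for (p in intersect(names(correction), panels)) {
      cv <- correction[[p]]$correction
      nm <- 2L * correction[[p]]$n_mock
      # project the leakage counts (classes 1..nm out of nm) to target size
      P <- projection_matrix(nm, sample_sizes[[p]])
      cv_t <- as.vector(P %*% c(0, cv))
      if (length(panels) == 1L) {
        spec <- pmax(spec - cv_t, 0)
      } else {
        # subtract along panel p's margin at zero counts elsewhere
        idx <- as.list(rep(1L, length(panels))); names(idx) <- panels
        for (j in seq_along(cv_t)) {
          idx[[p]] <- j
          spec[do.call(cbind, idx)] <- max(spec[do.call(cbind, idx)] - cv_t[j], 0)
        }
      }
    }
  }
  joint_sfs(if (length(panels) == 1L) spec else spec, pops = panels)
}

#' Bottleneck approximation to negative ascertainment: validation harness
#'
#' Simulates two populations plus an earlier-diverging outgroup, negatively
#' ascertains against a sample of outgroup diploids, and fits the resulting
#' pairwise spectrum with a two-population model carrying a root bottleneck
#' at a free time. If the bottleneck approximation is sound, the inferred
#' bottleneck time recovers the outgroup divergence time.
#'
#' @param model a [split_model()] with 2 populations and an `outgroup`.
#' @param sizes named haploid sample sizes for the two populations.
#' @param n_loci standing variants for the forward simulation.
#' @param seed integer seed.
#' @param n_outgroup_diploid outgroup diploids used for ascertainment.
#' @param gen_years years per generation for reporting (default 30).
#' @param scale diffusion rescaling of the forward simulation.
#' @param n_starts optimizer starts.
#' @return list with `T_bottleneck_years` (inferred), `T_outgroup_years`
#'   (truth), `ratio`, `fit` (the `demography_fit`), `size_bias` (relative
#'   error of the two population sizes), `split_bias`.
#' @export
bottleneck_equivalence_report <- function(model, sizes, n_loci, seed,
                                          n_outgroup_diploid = 100,
                                          gen_years = 30, scale = 4,
                                          n_starts = 3) {
  if (is.null(model$outgroup)) stop("model must include an outgroup")
  sim <- simulate_split_sfs(model, sizes, n_loci, seed,
                            n_outgroup_diploid = n_outgroup_diploid,
                            scale = scale)
  keep <- !sim$outgroup_derived
  prs <- sfs_pairs(sim$counts[keep, , drop = FALSE], sizes)
  # fit template: free root bottleneck (time, size) + split + branch sizes
  # the approximation family is a brief drastic squeeze with full recovery
  # (fixed short duration; the free severity controls how much ancestral
  # variation survives), regardless of the truth model's trunk
  tmpl <- split_model(N_anc = model$N_anc,
                      T_found = model$outgroup$T_split * 0.9,
                      N_bot = model$N_anc / 1000, sizes = model$sizes,
                      T1 = model$T1, order = model$order, r = 100,
                      bottleneck_duration = 25)
  # the mutational scale of the harness is known from the generator; fixing
  # theta makes the reduced variant count itself part of the signal the
  # bottleneck has to explain
  fit <- fit_split_model(prs, tmpl, orderings = tmpl$order,
                         n_starts = n_starts, seed = seed,
                         fix = "nu_bot", theta = sim$theta)
  # the fit shares the simulation's reference size, so diffusion times
  # convert to years with the same 2 N_ref generations unit
  yrs_per_tau <- 2 * model$N_anc * gen_years
  T_b_years <- fit$par[["tau_found"]] * yrs_per_tau
  T_og_years <- model$outgroup$T_split * gen_years
  sz <- fit$model$sizes / model$sizes - 1
  list(T_bottleneck_years = T_b_years, T_outgroup_years = T_og_years,
       ratio = T_b_years / T_og_years, fit = fit, size_bias = sz,
       split_bias = fit$par[["tau1"]] * yrs_per_tau / (model$T1 * gen_years) - 1)
}
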