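# Forward simulation of allele frequencies through a split model.
#
# Per-locus binomial Wright-Fisher propagation through the population tree.
# Standing variation at the simulation root is drawn from the neutral
# stationary spectrum (density ~ 1/x); new mutations enter each population
# at rate theta*nu/2 per generation at frequency 1/(2N). To keep desk-scale
# runtimes the simulation may be diffusion-rescaled: dividing all sizes and
# times by `scale` leaves the expected spectrum invariant while cutting cost
# by scale^2 (documented; granularity error is O(scale/N)).

#' Simulate a joint SFS under a split model by forward Wright-Fisher
#'
#' @param model a [split_model()]; an `outgroup` component, if present, is
#'   simulated alongside for negative-ascertainment experiments.
#' @param sample_sizes named haploid sample sizes per model population.
#' @param n_loci number of standing variants at the simulation root; new
#'   mutations are injected at the matching rate, so the total locus count
#'   is larger.
#' @param seed integer seed.
#' @param n_outgroup_diploid outgroup diploids to genotype (default 100).
#' @param scale diffusion rescaling factor (default 4).
#' @return list of class `split_sim`: `sfs` (a [joint_sfs()]), `counts`
#'   (per-locus derived counts, loci x populations), `outgroup_derived`
#'   (logical; derived allele seen in the outgroup sample), `theta`
#'   (simulation theta in unscaled units), `n_loci_total`.
#' @export
simulate_split_sfs <- function(model, sample_sizes, n_loci, seed,
                               n_outgroup_diploid = 100, scale = 4) {
  if (n_loci < 1) stop("n_loci must be >= 1")
  set.seed(as.integer(seed))
  s <- scale
  pops <- names(model$sizes)
  first <- model$order
  rest <- setdiff(pops, first)
  has_og <- !is.null(model$outgroup)
  # scaled integer timeline
  Tf <- max(1L, as.integer(round(model$T_found / s)))
  T1 <- max(0L, as.integer(round(model$T1 / s)))
  T2 <- if (!is.null(model$T2)) max(0L, as.integer(round(model$T2 / s))) else NULL
  Tog <- if (has_og) as.integer(round(model$outgroup$T_split / s)) else NULL
  Troot <- max(Tf, T1, if (has_og) Tog else 0L)
  Nanc_s <- max(2, round(model$N_anc / s))
  theta_s <- n_loci / log(2 * Nanc_s)
  size_of <- function(pop, g) {
    # scaled diploid size of a lineage at scaled generation g (backward)
    nn <- if (pop == "trunk") {
      if (g > Tf) model$N_anc
      else if (!is.null(model$bottleneck_duration)) {
        if (g > Tf - model$bottleneck_duration / s) model$N_bot else model$N_anc
      } else {
        span <- max(Tf - T1, 1L)
        frac <- min(max((Tf - g) / span, 0), 1)
        model$N_bot * model$r^frac
      }
    } else if (pop == "outgroup") model$outgroup$N
    else model$sizes[[pop]]
    rb <- model$recent_bottleneck
    if (!is.null(rb) && pop %in% pops && rb$pop == pop &&
        g * s <= rb$T_start && g * s >= rb$T_end)
      nn <- nn * rb$severity
    max(2L, as.integer(round(nn / s)))
  }
  for (p in pops)
    if (sample_sizes[[p]] > 2 * size_of(p, 0))
      stop("sample size exceeds twice the simulated population size for ", p)
  # lineages alive during the step from generation g to g - 1
  live_at <- function(g) {
    c(if (has_og && g <= Tog) "outgroup",
      if (g <= T1) first,
      if (!is.null(T2)) {
        if (g <= T2) rest else "trunk"
      } else {
        if (g <= T1) rest[1L] else "trunk"
      })
  }
  # frequencies: environment of per-lineage frequency vectors over all loci
  # (loci born later sit at 0 until their birth generation)
  births <- list()
  for (g in Troot:1) {
    for (p in live_at(g)) {
      lam <- theta_s / 2 * size_of(p, g) / Nanc_s
      k <- rpois(1L, lam)
      if (k > 0) births[[length(births) + 1L]] <- list(g = g, pop = p, k = k)
    }
  }
  n_new <- sum(vapply(births, function(b) b$k, 0L))
  n_tot <- n_loci + n_new
  freqs <- list(); active <- list()
  # standing variation at the root, density ~ 1/x
  lo <- 1 / (2 * Nanc_s); hi <- 1 - lo
  freqs$trunk <- c(lo * (hi / lo)^runif(n_loci), numeric(n_new))
  active$trunk <- seq_len(n_loci)
  offs <- cumsum(c(n_loci, vapply(births, function(b) b$k, 0L)))
  bidx <- function(j) (offs[j] + 1L):offs[j + 1L]
  birth_by_g <- split(seq_along(births),
                      vapply(births, function(b) b$g, 0L))
  for (g in Troot:1) {
    live <- live_at(g)
    # lineage splits happening when stepping INTO generation g - 1
    if (has_og && g == Tog) {
      freqs$outgroup <- freqs$trunk; active$outgroup <- active$trunk
    }
    if (g == T1) {
      freqs[[first]] <- freqs$trunk; active[[first]] <- active$trunk
      if (is.null(T2)) {
        freqs[[rest[1L]]] <- freqs$trunk; active[[rest[1L]]] <- active$trunk
        freqs$trunk <- NULL; active$trunk <- NULL
      }
    }
    if (!is.null(T2) && g == T2) {
      freqs[[rest[1L]]] <- freqs$trunk; active[[rest[1L]]] <- active$trunk
      freqs[[rest[2L]]] <- freqs$trunk; active[[rest[2L]]] <- active$trunk
      freqs$trunk <- NULL; active$trunk <- NULL
    }
    # inject this generation's new mutations at 1/(2N) in their population
    for (j in birth_by_g[[as.character(g)]]) {
      b <- births[[j]]
      if (b$pop %in% names(freqs)) {
        ix <- bidx(j)
        freqs[[b$pop]][ix] <- 1 / (2 * size_of(b$pop, g - 0.5))
        active[[b$pop]] <- c(active[[b$pop]], ix)
      }
    }
    for (p in live) {
      # evaluate the (possibly growing) size at the step midpoint
      N2 <- 2L * size_of(p, g - 0.5)
      idx <- active[[p]]
      if (!length(idx)) next
      newx <- rbinom(length(idx), N2, freqs[[p]][idx]) / N2
      freqs[[p]][idx] <- newx
      active[[p]] <- idx[newx > 0 & newx < 1]
    }
  }
  # zero-divergence edge case: splits at scaled generation 0 never fire
  for (p in pops) if (is.null(freqs[[p]])) freqs[[p]] <- freqs$trunk
  counts <- vapply(pops, function(p)
    rbinom(n_tot, sample_sizes[[p]], freqs[[p]]), numeric(n_tot))
  counts <- matrix(as.integer(counts), ncol = length(pops),
                   dimnames = list(NULL, pops))
  og_der <- if (has_og)
    rbinom(n_tot, 2L * n_outgroup_diploid, freqs$outgroup) > 0L
  else rep(FALSE, n_tot)
  structure(list(sfs = counts_to_sfs(counts, sample_sizes[pops]),
                 counts = counts, outgroup_derived = og_der,
                 theta = theta_s, n_loci_total = n_tot),
            class = "split_sim")
}

#' Tabulate per-locus derived counts into a joint SFS
#'
#' @param counts integer matrix, loci x populations.
#' @param sample_sizes named haploid sizes (one per column).
#' @return a [joint_sfs()].
#' @export
counts_to_sfs <- function(counts, sample_sizes) {
  d <- unname(sample_sizes + 1L)
  idx <- as.integer(counts %*% cumprod(c(1L, utils::head(d, -1L)))) + 1L
  a <- array(tabulate(idx, nbins = prod(d)), dim = d)
  joint_sfs(a, pops = colnames(counts))
}

#' @export
print.split_sim <- function(x, ...) {
  cat(sprintf("<split_sim> %d loci, %.1f%% outgroup-derived\n",
              x$n_loci_total, 100 * mean(x$outgroup_derived)))
  print(x$sfs)
  invisible(x)
}
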