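ANCESTRIES <- c("NAT", "EUR", "AFR")

#' Migration history of an admixed population
#'
#' Encodes, for each generation `t` before present (most recent first), the
#' fraction of the admixed population replaced by migrants from each source
#' population. Generation indices are integers; the founding generation is the
#' oldest row and must sum to 1 (the population is created entirely from
#' migrants). Later rows must sum to at most 1.
#'
#' @param m numeric matrix; rows are generations before present (rownames are
#'   the integer generation indices, all `>= 2`), columns are source
#'   populations (subset of `NAT`, `EUR`, `AFR`). `m[t, p]` is the fraction of
#'   the population at generation `t` replaced by migrants from `p`.
#' @return an object of class `migration_history`.
#' @export
migration_history <- function(m) {
  if (!is.matrix(m) || is.null(rownames(m)) || is.null(colnames(m)))
    stop("m must be a matrix with generation rownames and ancestry colnames")
  gens <- as.integer(rownames(m))
  if (any(is.na(gens)) || any(gens < 2L))
    stop("invalid-history: generation indices must be integers >= 2")
  if (anyDuplicated(gens)) stop("duplicate generation rows")
  if (!all(colnames(m) %in% ANCESTRIES))
    stop("ancestry columns must be among NAT, EUR, AFR")
  m <- m[order(gens, decreasing = TRUE), , drop = FALSE]
  gens <- sort(gens, decreasing = TRUE)
  if (any(m < 0) || any(m > 1)) stop("migration fractions must lie in [0, 1]")
  tot <- rowSums(m)
  if (abs(tot[1L] - 1) > 1e-9)
    stop("invalid-history: founding generation must sum to 1")
  if (length(tot) > 1L && any(tot[-1L] > 1 + 1e-9))
    stop("total inflow per generation must be <= 1")
  structure(m, class = "migration_history", founding = gens[1L])
}

#' @export
print.migration_history <- function(x, ...) {
  cat(sprintf("<migration_history> founding %d generations ago; sources: %s\n",
              attr(x, "founding"),
              paste(colnames(x)[colSums(x) > 0], collapse = ", ")))
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

founding_generation <- function(mig) attr(mig, "founding")

# per-generation migration rows aligned to t = 2..T0 (list by generation)
mig_row <- function(mig, t) {
  i <- match(as.character(t), rownames(mig))
  if (is.na(i)) stats::setNames(numeric(ncol(mig)), colnames(mig)) else mig[i, ]
}

#' Present-day ancestry proportions implied by a migration history
#'
#' A migrant cohort entering at generation `t` contributes its fractions
#' diluted by all subsequent replacement: the genome fraction tracing to the
#' cohort at `t` is `m[t, ] * prod_{v < t} (1 - sum(m[v, ]))`.
#'
#' @param mig a [migration_history()].
#' @return named numeric vector of ancestry proportions (sums to 1).
#' @export
ancestry_proportions <- function(mig) {
  gens <- as.integer(rownames(mig))
  keep <- 1
  out <- stats::setNames(numeric(length(ANCESTRIES)), ANCESTRIES)
  # iterate oldest -> newest, diluting older contributions
  for (i in order(gens, decreasing = TRUE)) {
    tot <- sum(mig[i, ])
    out <- out * (1 - tot)
    out[colnames(mig)] <- out[colnames(mig)] + mig[i, ]
  }
  out
}

#' Discretize a continuous-time migration pulse onto integer generations
#'
#' Admixture onsets inferred by maximum likelihood are continuous; Wright-
#' Fisher histories live on integer generations. A pulse at non-integer time
#' `t` is distributed over the two neighbouring generations so that the net
#' ancestry contribution is preserved and the contribution is split linearly:
#' a fraction `t - floor(t)` of the pulse behaves as if it entered at
#' `ceiling(t)` and the rest at `floor(t)`. For a founding pulse
#' (`magnitude = 1`) this places the founding at `ceiling(t)` followed by a
#' near-complete replacement at `floor(t)`: an onset of 13.02 generations ago
#' founds the population 14 generations ago with a replacement of 0.98 at 13.
#'
#' @param t pulse time in generations before present (`> 1`).
#' @param magnitude total replacement fraction of the pulse, in (0, 1].
#' @return data.frame with columns `gen` (integer generation) and `weight`
#'   (replacement fraction applied at that generation), one row when `t` is an
#'   integer, two rows otherwise (oldest first).
#' @export
discretize_pulse <- function(t, magnitude = 1) {
  if (!is.finite(t) || t <= 1)
    stop("pulse time must exceed 1 generation (no time to recombine)")
  if (magnitude <= 0 || magnitude > 1) stop("magnitude must be in (0, 1]")
  lo <- floor(t); hi <- ceiling(t)
  if (lo == hi)
    return(data.frame(gen = as.integer(t), weight = magnitude))
  w_hi_net <- magnitude * (t - lo)   # net contribution meant to enter at hi
  w_lo_net <- magnitude * (hi - t)
  if (magnitude == 1) {
    # founding: full replacement at hi, then w_lo at lo dilutes it to w_hi_net
    data.frame(gen = as.integer(c(hi, lo)), weight = c(1, w_lo_net))
  } else {
    # apply w_hi at hi, then w_lo at lo; solve for w_hi so the net is exact
    w_hi <- w_hi_net / (1 - w_lo_net)
    data.frame(gen = as.integer(c(hi, lo)), weight = c(w_hi, w_lo_net))
  }
}

# ---- model families ---------------------------------------------------------

#' Migration-model families
#'
#' Four families of parametric migration histories are supported, named by
#' what they add to a simultaneous founding pulse of all three ancestries:
#'
#' * `three_pulses_simultaneous`: a single founding event at `t0` with
#'   fractions `(fNAT, fEUR, 1 - fNAT - fEUR)`; 3 parameters.
#' * `founding_plus_continuing`: founding at `t0` plus constant per-generation
#'   inflow `mEUR`, `mNAT` in every later generation; 5 parameters
#'   (the family used for MXL-style histories).
#' * `founding_plus_second_NAT_pulse`: founding at `t0` plus one later Native
#'   American pulse of magnitude `mNAT2` at `t2 < t0`; 5 parameters
#'   (CLM-style).
#' * `two_EUR_two_AFR_pulses`: founding at `t0` plus one later joint
#'   European/African pulse at `t2 < t0` with magnitudes `mEUR2`, `mAFR2`;
#'   6 parameters (PUR-style).
#'
#' Parameters are passed as named vectors; all times are continuous
#' generations before present and are discretized with [discretize_pulse()].
#'
#' @param family family id (see above).
#' @param par named parameter vector for that family.
#' @return a [migration_history()].
#' @export
family_history <- function(family, par) {
  family <- match.arg(family, TRACTS_FAMILIES)
  need <- family_param_names(family)
  if (!all(need %in% names(par)))
    stop("missing parameters: ", paste(setdiff(need, names(par)), collapse = ", "))
  t0 <- par[["t0"]]
  fNAT <- par[["fNAT"]]; fEUR <- par[["fEUR"]]
  fAFR <- 1 - fNAT - fEUR
  if (fNAT < 0 || fEUR < 0 || fAFR < -1e-9)
    stop("founding fractions must be in [0,1] and sum to at most 1")
  fAFR <- max(fAFR, 0)
  fr <- c(NAT = fNAT, EUR = fEUR, AFR = fAFR)
  T0 <- as.integer(ceiling(t0))
  m <- matrix(0, nrow = T0 - 1L, ncol = 3L,
              dimnames = list(as.character(T0:2), ANCESTRIES))
  add_pulse <- function(m, t, magnitude, fracs) {
    d <- discretize_pulse(t, magnitude)
    for (k in seq_len(nrow(d))) {
      g <- as.character(d$gen[k])
      m[g, ] <- m[g, ] + d$weight[k] * fracs / sum(fracs)
    }
    m
  }
  m <- add_pulse(m, t0, 1, fr)
  if (family == "founding_plus_continuing") {
    mEUR <- par[["mEUR"]]; mNAT <- par[["mNAT"]]
    if (mEUR < 0 || mNAT < 0 || mEUR + mNAT > 1) stop("invalid continuing rates")
    cont <- as.character(seq_len(max(floor(t0) - 1L, 1L))[-1L])  # gens 2..floor(t0)-1
    if (length(cont)) {
      m[cont, "EUR"] <- m[cont, "EUR"] + mEUR
      m[cont, "NAT"] <- m[cont, "NAT"] + mNAT
    }
  } else if (family == "founding_plus_second_NAT_pulse") {
    t2 <- par[["t2"]]; mNAT2 <- par[["mNAT2"]]
    if (t2 >= floor(t0)) stop("second pulse must predate the founding pulse row")
    if (mNAT2 > 0) m <- add_pulse(m, t2, mNAT2, c(NAT = 1, EUR = 0, AFR = 0))
  } else if (family == "two_EUR_two_AFR_pulses") {
    t2 <- par[["t2"]]; mE <- par[["mEUR2"]]; mA <- par[["mAFR2"]]
    if (t2 >= floor(t0)) stop("second pulse must predate the founding pulse row")
    if (mE + mA > 0)
      m <- add_pulse(m, t2, mE + mA, c(NAT = 0, EUR = mE, AFR = mA))
  }
  migration_history(m)
}

TRACTS_FAMILIES <- c("three_pulses_simultaneous", "founding_plus_continuing",
                     "founding_plus_second_NAT_pulse", "two_EUR_two_AFR_pulses")

family_param_names <- function(family) {
  switch(family,
    three_pulses_simultaneous      = c("t0", "fNAT", "fEUR"),
    founding_plus_continuing       = c("t0", "fNAT", "fEUR", "mEUR", "mNAT"),
    founding_plus_second_NAT_pulse = c("t0", "fNAT", "fEUR", "t2", "mNAT2"),
    two_EUR_two_AFR_pulses         = c("t0", "fNAT", "fEUR", "t2", "mEUR2", "mAFR2"))
}
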