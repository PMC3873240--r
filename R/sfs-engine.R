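# Deterministic frequency-grid engine for expected site frequency spectra.
#
# The density of derived-allele frequencies evolves under pure drift,
#   d phi / d tau = (1 / (2 nu)) d^2 [x (1 - x) phi] / dx^2,
# with time tau in units of 2*N_ref generations and nu = N/N_ref. The
# density is discretized as expected variant *mass* on a grid with a
# uniform backbone plus geometrically refined nodes near the boundaries,
# and propagated by Crank-Nicolson steps of a mass-conserving finite-volume
# stencil; boundary nodes (x = 0, 1) receive absorbed mass and, in joint
# spectra, keep evolving along the other axis (variants fixed or lost in
# one population still drift in the other). New mutations enter at the
# lowest interior node at rate theta/(2 x_inj) per unit tau; the resulting
# stationary sample spectrum is the neutral theta/i. Population splits copy
# the trunk mass onto the diagonal of a two-dimensional grid. Optional
# Richardson extrapolation over backbone sizes is available, but the
# refined grid is accurate at a single backbone of 60.

default_engine_opts <- function() {
  list(grids = 60L, extrap = FALSE, dt_max = 1e-3, dt_nu_frac = 0.05,
       max_steps = 300L)
}

.drift_cache <- new.env(parent = emptyenv())

# frequency grid: uniform backbone (accurate mid-frequency classes) with
# geometrically refined points inside the first and last uniform cells --
# the neutral density diverges as 1/x, so the young-variant classes need
# sub-cell resolution near the boundaries
engine_grid <- function(G, n_sub = 6) {
  base <- (0:G) / G
  lo <- 1 / (G * 2^(seq_len(n_sub)))
  sort(unique(c(base, lo, 1 - lo)))
}

# drift generator in mass form on the refined grid: finite-volume flux
# discretization of d(mass)/dtau = (1/2nu) d/dx [ d(w phi)/dx ], phi = P/h
drift_operator <- function(G) {
  key <- as.character(G)
  if (!is.null(.drift_cache[[key]])) return(.drift_cache[[key]])
  .drift_cache[[key]] <- drift_operator_build(G)
}

drift_operator_build <- function(G) {
  x <- engine_grid(G)
  n <- length(x)
  h <- numeric(n)                        # cell widths (trapezoid cells)
  h[1L] <- (x[2L] - x[1L]) / 2
  h[n] <- (x[n] - x[n - 1L]) / 2
  h[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / 2
  w <- x * (1 - x)
  dxe <- diff(x)                         # edge spacings x_{j+1} - x_j
  T_ <- matrix(0, n, n)
  # flux at edge j+1/2: (w_{j+1} P_{j+1}/h_{j+1} - w_j P_j/h_j) / dxe_j
  for (j in 1:(n - 1L)) {
    cj <- w[j] / (h[j] * dxe[j])
    cj1 <- w[j + 1L] / (h[j + 1L] * dxe[j])
    T_[j, j] <- T_[j, j] - cj
    T_[j + 1L, j] <- T_[j + 1L, j] + cj
    T_[j, j + 1L] <- T_[j, j + 1L] + cj1
    T_[j + 1L, j + 1L] <- T_[j + 1L, j + 1L] - cj1
  }
  list(T = T_, x = x, h = h)
}

# one epoch of 1D drift: P mass vector, duration dtau, nu(s) a function of
# elapsed time in the epoch (or constant), theta injection per unit tau
evolve_1d <- function(P, dtau, nu, G, opts, theta = 1) {
  if (dtau <= 0) return(P)
  nu_f <- if (is.function(nu)) nu else function(s) rep(nu, length(s))
  op <- drift_operator(G)
  T_ <- op$T
  nn <- length(op$x)
  Id <- diag(nn)
  inj <- numeric(nn); inj[2L] <- theta / (2 * op$x[2L])
  s <- 0
  last_c <- NA_real_; Mf <- NULL
  # adaptive steps: dt tracks the current size, so a brief passage through a
  # tiny bottleneck costs few steps while staying accurate where it matters
  dt_floor <- dtau / opts$max_steps
  while (s < dtau - 1e-15) {
    dt <- min(max(min(opts$dt_max, opts$dt_nu_frac * nu_f(s)), dt_floor),
              dtau - s)
    nu_mid <- nu_f(s + dt / 2)
    cfac <- dt / (2 * nu_mid)
    if (is.na(last_c) || abs(cfac - last_c) > 1e-12 * cfac) {
      # Crank-Nicolson: second order in dt at the cost of one dgemm per step
      Mf <- solve(Id - cfac / 2 * T_, Id + cfac / 2 * T_)
      last_c <- cfac
    }
    P <- Mf %*% (P + dt * inj)
    s <- s + dt
  }
  as.vector(P)
}

# one epoch of 2D drift by operator splitting; P is (G+1) x (G+1) mass,
# nu1/nu2 constants or functions of elapsed epoch time
evolve_2d <- function(P, dtau, nu1, nu2, G, opts, theta = 1) {
  if (dtau <= 0) return(P)
  f1 <- if (is.function(nu1)) nu1 else function(s) rep(nu1, length(s))
  f2 <- if (is.function(nu2)) nu2 else function(s) rep(nu2, length(s))
  op <- drift_operator(G)
  T_ <- op$T
  Id <- diag(length(op$x))
  inj <- theta / (2 * op$x[2L])
  s <- 0
  lc1 <- lc2 <- NA_real_; M1i <- M2i <- NULL
  dt_floor <- dtau / opts$max_steps
  while (s < dtau - 1e-15) {
    dt <- min(max(min(opts$dt_max, opts$dt_nu_frac * f1(s),
                      opts$dt_nu_frac * f2(s)), dt_floor),
              dtau - s)
    c1 <- dt / (2 * f1(s + dt / 2))
    c2 <- dt / (2 * f2(s + dt / 2))
    if (is.na(lc1) || abs(c1 - lc1) > 1e-12 * c1) {
      M1i <- solve(Id - c1 / 2 * T_, Id + c1 / 2 * T_); lc1 <- c1
    }
    if (is.na(lc2) || abs(c2 - lc2) > 1e-12 * c2) {
      M2i <- solve(Id - c2 / 2 * T_, Id + c2 / 2 * T_); lc2 <- c2
    }
    # injection: new mutations private to each population
    P[2L, 1L] <- P[2L, 1L] + dt * inj
    P[1L, 2L] <- P[1L, 2L] + dt * inj
    P <- M1i %*% P                              # drift along axis 1
    P <- P %*% t(M2i)                           # drift along axis 2
    s <- s + dt
  }
  P
}

# stationary standing-variation mass for a constant-size population (nu = 1)
stationary_mass <- function(G, theta = 1) {
  op <- drift_operator(G)
  nn <- length(op$x)
  int <- 2:(nn - 1L)
  rhs <- numeric(nn - 2L); rhs[1L] <- theta / (2 * op$x[2L])
  P <- numeric(nn)
  # mass balance at stationarity: (1/2) T P + injection = 0
  P[int] <- solve(op$T[int, int, drop = FALSE] / 2, -rhs)
  P
}

# expected sample SFS from grid mass: E[X_i] = sum_j P_j Binom(i; n, x_j)
sample_1d <- function(P, n, G) {
  x <- drift_operator(G)$x
  B <- outer(0:n, x, function(i, xx) stats::dbinom(i, n, xx))
  as.vector(B %*% P)
}

sample_2d <- function(P, n1, n2, G) {
  x <- drift_operator(G)$x
  B1 <- outer(0:n1, x, function(i, xx) stats::dbinom(i, n1, xx))
  B2 <- outer(0:n2, x, function(i, xx) stats::dbinom(i, n2, xx))
  B1 %*% P %*% t(B2)
}

#' Three- (or two-) population split demographic model
#'
#' An ancestral population of diploid size `N_anc` experiences a founding
#' bottleneck `T_found` generations ago: its size drops to `N_bot` and
#' recovers exponentially to `r * N_bot` by the first split. At `T1` the
#' first population branches off with its own constant size; for
#' three-population models the remaining trunk splits again at `T2 <= T1`.
#' The bottleneck-and-recovery epoch doubles as the negative-ascertainment
#' equivalent: conditioning variants on absence from an outgroup removes
#' most variation predating the outgroup split, which is what a drastic
#' root bottleneck does.
#'
#' @param N_anc ancestral diploid size (also the reference size `N_ref`).
#' @param T_found founding-bottleneck time in generations before present.
#' @param N_bot bottleneck diploid size.
#' @param sizes named vector of present diploid sizes, 2 or 3 populations;
#'   names give the population labels.
#' @param T1 first split time (generations); `T_found >= T1`.
#' @param T2 second split time (three-population models), `T2 <= T1`.
#' @param order name of the population that splits first (at `T1`).
#' @param r recovered/bottleneck size ratio (default 100; beyond this the
#'   likelihood is flat, so it is conventionally fixed).
#' @param outgroup optional `list(T_split =, N =)` outgroup used only by the
#'   forward simulator for negative-ascertainment experiments.
#' @param recent_bottleneck optional fixed post-contact bottleneck,
#'   `list(pop =, T_start =, T_end =, severity =)` (times in generations
#'   back, `T_start > T_end`; sizes multiplied by `severity` inside the
#'   window).
#' @param bottleneck_duration optional duration (generations) of the
#'   founding bottleneck. When given, the trunk passes through a brief
#'   squeeze of size `N_bot` lasting this long and returns to `N_anc`
#'   (`r` is ignored) -- the shape that mimics negative ascertainment.
#'   When `NULL` (default) the trunk instead recovers exponentially from
#'   `N_bot` to `r * N_bot` by `T1` and keeps that size.
#' @return object of class `split_model`.
#' @export
split_model <- function(N_anc, T_found, N_bot, sizes, T1, T2 = NULL,
                        order = names(sizes)[1L], r = 100,
                        outgroup = NULL, recent_bottleneck = NULL,
                        bottleneck_duration = NULL) {
  if (is.null(names(sizes)) || any(names(sizes) == ""))
    stop("sizes must be a named vector")
  np <- length(sizes)
  if (!np %in% 2:3) stop("2 or 3 populations supported")
  if (np == 3L && is.null(T2)) stop("three populations need T2")
  if (np == 2L) T2 <- NULL
  if (any(c(N_anc, N_bot, sizes) <= 0)) stop("sizes must be positive")
  if (r < 1) stop("r must be >= 1")
  if (T_found < T1) stop("times must be ordered T_found >= T1")
  if (!is.null(T2) && T1 < T2) stop("times must be ordered T1 >= T2")
  if (!order %in% names(sizes)) stop("order must name a population")
  if (!is.null(bottleneck_duration) && bottleneck_duration <= 0)
    stop("bottleneck_duration must be positive")
  structure(list(N_anc = N_anc, T_found = T_found, N_bot = N_bot, r = r,
                 sizes = sizes, T1 = T1, T2 = T2, order = order,
                 outgroup = outgroup, recent_bottleneck = recent_bottleneck,
                 bottleneck_duration = bottleneck_duration),
            class = "split_model")
}

#' @export
print.split_model <- function(x, ...) {
  cat(sprintf("<split_model> N_anc=%.0f, bottleneck %.0f @ %.0f gens (r=%g)\n",
              x$N_anc, x$N_bot, x$T_found, x$r))
  cat(sprintf("  %s splits at %.0f gens%s; sizes: %s\n", x$order, x$T1,
              if (!is.null(x$T2)) sprintf(", second split at %.0f", x$T2) else "",
              paste(sprintf("%s=%.0f", names(x$sizes), x$sizes), collapse = ", ")))
  if (!is.null(x$outgroup))
    cat(sprintf("  outgroup: N=%.0f split %.0f gens\n", x$outgroup$N,
                x$outgroup$T_split))
  invisible(x)
}

# effective size function (in nu units) for a present-day branch, honouring a
# fixed recent bottleneck; s = elapsed forward time within [T_from, 0] epoch
branch_nu <- function(model, pop, T_from) {
  nu <- model$sizes[[pop]] / model$N_anc
  rb <- model$recent_bottleneck
  if (is.null(rb) || rb$pop != pop) return(nu)
  Nref2 <- 2 * model$N_anc
  function(s) {
    t_back <- (T_from / Nref2) - s           # backward time in tau units
    inside <- t_back <= rb$T_start / Nref2 & t_back >= rb$T_end / Nref2
    ifelse(inside, nu * rb$severity, nu)
  }
}

#' Expected pairwise joint SFS under a split model
#'
#' Propagates the allele-frequency distribution through the model's epochs
#' on a discrete grid and returns the expected joint spectrum (per unit
#' theta, theta = 4 N_ref mu L) for every population pair — the inputs to
#' the pairwise composite likelihood. Optionally extrapolates over grid
#' sizes.
#'
#' @param model a [split_model()].
#' @param sizes named integer vector of haploid sample sizes per population.
#' @param engine_opts list of engine options; see Details. Defaults: grids
#'   20/40/60 with quadratic extrapolation in 1/G, time step bounded by
#'   0.002 x 2 N_ref generations and by a tenth of the smallest relative
#'   size in the epoch.
#' @return named list of [joint_sfs()] objects, one per population pair
#'   (single pair for two-population models).
#' @export
expected_joint_sfs <- function(model, sizes, engine_opts = list()) {
  opts <- utils::modifyList(default_engine_opts(), engine_opts)
  grids <- if (opts$extrap) opts$grids else max(opts$grids)
  per_grid <- lapply(grids, function(G) pairwise_spectra_grid(model, sizes, G, opts))
  if (!opts$extrap || length(grids) < 3L) return(per_grid[[length(per_grid)]])
  # quadratic extrapolation in u = 1/G, evaluated at u = 0
  u <- 1 / grids
  w <- solve(rbind(u^0, u, u^2), c(1, 0, 0))     # Lagrange weights at u = 0
  out <- per_grid[[1L]]
  for (nm in names(out)) {
    acc <- w[1L] * unclass(per_grid[[1L]][[nm]]) +
      w[2L] * unclass(per_grid[[2L]][[nm]]) +
      w[3L] * unclass(per_grid[[3L]][[nm]])
    out[[nm]] <- joint_sfs(pmax(acc, 0), pops = attr(out[[nm]], "pops"))
  }
  out
}

pairwise_spectra_grid <- function(model, sizes, G, opts) {
  Nref2 <- 2 * model$N_anc
  tauF <- model$T_found / Nref2
  tau1 <- model$T1 / Nref2
  nu_bot <- model$N_bot / model$N_anc
  nu_rec <- model$r * nu_bot
  pops <- names(model$sizes)
  first <- model$order
  rest <- setdiff(pops, first)
  # trunk: stationary ancestral, then the founding bottleneck
  P <- stationary_mass(G)
  dA <- tauF - tau1
  if (!is.null(model$bottleneck_duration)) {
    # brief squeeze at nu_bot, then full recovery to the ancestral size
    d_tau <- min(model$bottleneck_duration / Nref2, dA)
    P <- evolve_1d(P, d_tau, nu_bot, G, opts)
    if (dA - d_tau > 0) P <- evolve_1d(P, dA - d_tau, 1, G, opts)
    nu_rec <- 1
  } else if (dA > 0) {
    gr <- if (model$r > 1) function(s) nu_bot * model$r^(s / dA) else nu_bot
    P <- evolve_1d(P, dA, gr, G, opts)
  }
  out <- list()
  if (length(pops) == 2L) {
    second <- rest[1L]
    P2 <- diag(P)
    P2 <- evolve_2d(P2, tau1, branch_nu(model, first, model$T1),
                    branch_nu(model, second, model$T1), G, opts)
    nm <- paste(first, second, sep = "_")
    out[[nm]] <- joint_sfs(sample_2d(P2, sizes[[first]], sizes[[second]], G),
                           pops = c(first, second))
    return(out)
  }
  tau2 <- model$T2 / Nref2
  # pairs (first, x): 2D from T1; trunk axis at nu_rec until T2
  for (x in rest) {
    P2 <- diag(P)
    P2 <- evolve_2d(P2, tau1 - tau2, model$sizes[[first]] / model$N_anc,
                    nu_rec, G, opts)
    P2 <- evolve_2d(P2, tau2, branch_nu(model, first, model$T2),
                    branch_nu(model, x, model$T2), G, opts)
    out[[paste(first, x, sep = "_")]] <-
      joint_sfs(sample_2d(P2, sizes[[first]], sizes[[x]], G),
                pops = c(first, x))
  }
  # pair (second, third): trunk stays 1D until T2
  Pt <- evolve_1d(P, tau1 - tau2, nu_rec, G, opts)
  P2 <- diag(Pt)
  P2 <- evolve_2d(P2, tau2, branch_nu(model, rest[1L], model$T2),
                  branch_nu(model, rest[2L], model$T2), G, opts)
  out[[paste(rest[1L], rest[2L], sep = "_")]] <-
    joint_sfs(sample_2d(P2, sizes[[rest[1L]]], sizes[[rest[2L]]], G),
              pops = rest)
  out
}

#' Expected single-population SFS for a constant-size population
#'
#' The neutral equilibrium spectrum on the engine's grid; converges to
#' `theta / i` as the grid refines. Used as the engine's closed-form check.
#'
#' @param n haploid sample size.
#' @param engine_opts engine options (see [expected_joint_sfs()]).
#' @return a [joint_sfs()] per unit theta.
#' @export
expected_equilibrium_sfs <- function(n, engine_opts = list()) {
  opts <- utils::modifyList(default_engine_opts(), engine_opts)
  grids <- if (opts$extrap) opts$grids else max(opts$grids)
  vals <- vapply(grids, function(G) sample_1d(stationary_mass(G), n, G),
                 numeric(n + 1L))
  if (opts$extrap && length(grids) >= 3L) {
    u <- 1 / grids
    w <- solve(rbind(u^0, u, u^2), c(1, 0, 0))
    v <- as.vector(vals %*% w)
  } else v <- vals[, ncol(vals)]
  joint_sfs(pmax(v, 0))
}
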