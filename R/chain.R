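## Ground-truth metastable chains: the parameter-recovery oracle for every
## downstream stage.  A chain is a detailed-balance discrete-time Markov
## process whose stationary distribution is Boltzmann in prescribed state
## free energies; transition probabilities follow Metropolis-like barrier
## rates, which guarantees reversibility by construction.

#' Build a reversible metastable chain from free energies and barriers
#'
#' Constructs a discrete-time transition matrix at lag `dt` with
#' `T_ij = c * exp(-(B_ij - G_i)/kT)` for finite barriers `B_ij` (zero
#' otherwise) and the diagonal absorbing the remainder.  Because
#' `pi_i T_ij = (c/Z) exp(-B_ij/kT)` is symmetric, detailed balance holds
#' exactly and the stationary distribution is Boltzmann,
#' `pi_i = exp(-G_i/kT)/Z`.
#'
#' @param free_energies per-state free energy in kcal/mol (names become state
#'   names).
#' @param barriers symmetric matrix of pairwise barrier heights in kcal/mol;
#'   `Inf` means no direct transition.  Finite entries must satisfy
#'   `B_ij >= max(G_i, G_j)`.
#' @param dt lag per step, ns.
#' @param temperature Kelvin; default 300.
#' @param rate_scale attempt-frequency prefactor `c`.  Default chooses
#'   `0.99 / max_i sum_j exp(-(B_ij - G_i)/kT)` so every diagonal stays
#'   positive (metastability).
#' @param macro_labels optional per-state macrostate label, e.g. from
#'   `c("active","intermediate","src_like","dfg_out")`.
#' @return an object of class `dt_chain` with elements `transition_matrix`,
#'   `dt`, `free_energies`, `barriers`, `stationary`, `macro_labels`,
#'   `temperature`, `rate_scale`.
#' @export
build_kinase_chain <- function(free_energies, barriers, dt, temperature = 300,
                               rate_scale = NULL, macro_labels = NULL) {
  G <- as.numeric(free_energies)
  n <- length(G)
  B <- as.matrix(barriers)
  stopifnot(n >= 2L, all(dim(B) == n), dt > 0, temperature > 0)
  diag(B) <- Inf
  if (!isTRUE(all.equal(B, t(B)))) stop("barrier matrix must be symmetric")
  fin <- is.finite(B)
  pairmax <- outer(G, G, pmax)
  if (any(B[fin] < pairmax[fin] - 1e-12))
    stop("every finite barrier must be at least max(G_i, G_j)")
  ## connectivity over the finite-barrier graph
  if (!is_connected_undirected(fin))
    stop("barrier graph is disconnected: chain would not be irreducible")
  kt <- kT(temperature)
  ## row i gets exp(-(B[i,j] - G[i]) / kT)
  R <- exp(sweep(-B / kt, 1L, G / kt, "+"))
  R[!fin] <- 0
  S <- rowSums(R)
  if (is.null(rate_scale)) rate_scale <- 0.99 / max(S)
  if (max(S) * rate_scale > 1)
    stop("rate_scale too large: off-diagonal mass would exceed 1 (max row sum ",
         signif(max(S) * rate_scale, 4), ")")
  Tm <- rate_scale * R
  diag(Tm) <- 1 - rowSums(Tm)
  nm <- names(free_energies)
  if (!is.null(nm)) dimnames(Tm) <- list(nm, nm)
  pi <- exp(-G / kt)
  pi <- pi / sum(pi)
  names(pi) <- nm
  structure(list(transition_matrix = Tm, dt = dt, free_energies = G,
                 barriers = B, stationary = pi,
                 macro_labels = macro_labels %||% nm,
                 temperature = temperature, rate_scale = rate_scale),
            class = "dt_chain")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Undirected connectivity by breadth-first search on a logical adjacency.
is_connected_undirected <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    nb <- which(adj[i, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

#' @export
print.dt_chain <- function(x, ...) {
  n <- nrow(x$transition_matrix)
  cat("<dt_chain> ", n, " states, dt = ", x$dt, " ns, T = ",
      x$temperature, " K\n", sep = "")
  cat("stationary:", paste0(signif(x$stationary, 3), collapse = " "), "\n")
  if (!is.null(x$macro_labels))
    cat("macrostates:", paste(unique(x$macro_labels), collapse = ", "), "\n")
  invisible(x)
}

#' Stationary distribution
#'
#' @param object a model object (`dt_chain` or `msm`).
#' @param ... unused.
#' @export
stationary <- function(object, ...) UseMethod("stationary")

#' @export
stationary.dt_chain <- function(object, ...) object$stationary

#' Split each macrostate of a chain into fast-exchanging microstates
#'
#' Expands an `n`-state chain into `n * n_micro` states: each macrostate's
#' population is split equally over its microstates
#' (`G_micro = G_macro + kT log(n_micro)`), intra-macrostate barriers are low
#' (`intra_offset` above the state free energy, giving fast internal mixing)
#' and every cross-macrostate microstate pair inherits the macro barrier
#' plus `kT log(n_micro^2)`, which preserves the macrostate-level escape
#' fluxes of the parent chain.  This makes clustering and macrostate lumping
#' non-trivial for pipeline tests while keeping the macro thermodynamics and
#' kinetics of the calibrated parent.
#'
#' @param chain a `dt_chain`.
#' @param n_micro microstates per macrostate (default 3).
#' @param intra_offset intra-macrostate barrier height above the state free
#'   energy, kcal/mol (default 0.9).
#' @return a `dt_chain` whose `macro_labels` map microstates back to the
#'   parent states.
#' @export
expand_chain <- function(chain, n_micro = 3L, intra_offset = 0.9) {
  stopifnot(inherits(chain, "dt_chain"), n_micro >= 1L)
  kt <- kT(chain$temperature)
  n <- length(chain$free_energies)
  N <- n * n_micro
  macro_of <- rep(seq_len(n), each = n_micro)
  G <- chain$free_energies[macro_of] + kt * log(n_micro)
  B <- matrix(Inf, N, N)
  for (i in seq_len(N)) for (j in seq_len(N)) {
    mi <- macro_of[i]; mj <- macro_of[j]
    if (i == j) next
    if (mi == mj) {
      B[i, j] <- max(G[i], G[j]) + intra_offset
    } else if (is.finite(chain$barriers[mi, mj])) {
      B[i, j] <- chain$barriers[mi, mj] + kt * log(n_micro^2)
    }
  }
  labels <- chain$macro_labels %||% as.character(seq_len(n))
  build_kinase_chain(G, B, dt = chain$dt, temperature = chain$temperature,
                     rate_scale = chain$rate_scale,
                     macro_labels = labels[macro_of])
}

#' Calibrate the packaged BTK ground-truth chains
#'
#' Builds the two four-state fixture chains (deprotonated ASP and protonated
#' ASH ensembles) on the hub topology — the intermediate connects to the
#' active, Src-like and DFG-out states; no other direct transitions — at the
#' 80 ns Markov lag.  State free energies are fixed by Boltzmann inversion of
#' the target stationary populations; the intermediate/DFG-out barrier is then
#' tuned by 1-D root finding so the linear-solve mean first passage time from
#' the DFG-in states (active, intermediate, Src-like; stationary-weighted) to
#' DFG-out hits the target: 1.2 ms for ASP, 300 us for ASH.
#'
#' @param dt lag in ns (default 80, the Markov lag).
#' @param temperature Kelvin (default 300).
#' @param asp_populations,ash_populations named stationary targets for
#'   (active, intermediate, src_like, dfg_out); the defaults are the
#'   four-state BTK macrostate populations, with the intermediate absorbing
#'   the remainder.
#' @param asp_mfpt_ns,ash_mfpt_ns forward DFG-in -> DFG-out MFPT targets, ns.
#' @param access_barrier barrier height (kcal/mol) of the
#'   intermediate/active and intermediate/Src-like edges; controls how much
#'   of the passage time is spent reaching the hub (default 2.0).
#' @return list with elements `asp` and `ash`, each a `dt_chain`.
#' @export
calibrate_btk_chains <- function(dt = 80, temperature = 300,
                                 asp_populations = c(active = 0.07,
                                                     intermediate = 0.40,
                                                     src_like = 0.52,
                                                     dfg_out = 0.01),
                                 ash_populations = c(active = 0.06,
                                                     intermediate = 0.38,
                                                     src_like = 0.47,
                                                     dfg_out = 0.09),
                                 asp_mfpt_ns = 1.2e6, ash_mfpt_ns = 3e5,
                                 access_barrier = 2.0) {
  one <- function(pops, mfpt_ns) {
    stopifnot(abs(sum(pops) - 1) < 1e-9)
    kt <- kT(temperature)
    G <- -kt * log(pops / pops[["active"]])  # active is the zero reference
    states <- c("active", "intermediate", "src_like", "dfg_out")
    G <- G[states]
    hub <- function(b_dfg) {
      B <- matrix(Inf, 4, 4, dimnames = list(states, states))
      B["intermediate", "active"] <- B["active", "intermediate"] <- access_barrier
      B["intermediate", "src_like"] <- B["src_like", "intermediate"] <- access_barrier
      B["intermediate", "dfg_out"] <- B["dfg_out", "intermediate"] <- b_dfg
      build_kinase_chain(G, B, dt = dt, temperature = temperature,
                         rate_scale = 1, macro_labels = states)
    }
    lo <- max(G[["intermediate"]], G[["dfg_out"]]) + 1e-6
    f <- function(b) mfpt(hub(b), sources = 1:3, sinks = 4L) - mfpt_ns
    if (f(lo) > 0)
      stop("MFPT calibration cannot bracket target: even barrier ",
           signif(lo, 4), " kcal/mol is too slow")
    root <- stats::uniroot(f, lower = lo, upper = 20, tol = 1e-12)$root
    hub(root)
  }
  list(asp = one(asp_populations, asp_mfpt_ns),
       ash = one(ash_populations, ash_mfpt_ns))
}

#' Sample discrete state trajectories from a chain
#'
#' Forward simulation of the propagation law: each frame is a categorical
#' draw from the current state's transition-matrix row.
#'
#' @param chain a `dt_chain` (or any object with a `transition_matrix`).
#' @param n_steps frames per trajectory (>= 2).
#' @param n_trajs number of independent trajectories.
#' @param seed RNG seed; identical seeds reproduce identical output.
#' @param start `"stationary"` (default: initial states drawn from the
#'   stationary distribution) or a fixed state index.
#' @return list of integer vectors of state labels in `1..n_states`, with
#'   attribute `dt`.
#' @export
sample_discrete <- function(chain, n_steps, n_trajs = 1L, seed = 1L,
                            start = "stationary") {
  Tm <- chain$transition_matrix
  n <- nrow(Tm)
  stopifnot(n_steps >= 2L, n_trajs >= 1L)
  cumT <- t(apply(Tm, 1L, cumsum))
  set.seed(seed)
  if (identical(start, "stationary")) {
    starts <- sample.int(n, n_trajs, replace = TRUE, prob = chain$stationary)
  } else {
    start <- as.integer(start)
    if (start < 1L || start > n) stop("invalid start state: ", start)
    starts <- rep(start, n_trajs)
  }
  out <- lapply(seq_len(n_trajs), function(k)
    cpp_sample_chain(cumT, as.integer(n_steps), starts[k] - 1L))
  attr(out, "dt") <- chain$dt
  out
}

#' Gaussian emission specification
#'
#' Per-state mean vectors with isotropic Gaussian noise, plus optional
#' pure-noise dimensions appended (i.i.d. standard normal, carrying no
#' kinetic signal).
#'
#' @param means `n_states x d` matrix of state mean vectors; rows of distinct
#'   macrostates must be pairwise distinct.
#' @param sd emission standard deviation (isotropic); default 1.
#' @param noise_dims number of appended pure-noise dimensions.
#' @return object of class `emission_spec`.
#' @export
emission_spec <- function(means, sd = 1, noise_dims = 0L) {
  means <- as.matrix(means)
  stopifnot(sd >= 0, noise_dims >= 0L)
  if (nrow(means) > 1L && any(duplicated(means)))
    stop("state means must be pairwise distinct")
  structure(list(means = means, sd = sd, noise_dims = as.integer(noise_dims)),
            class = "emission_spec")
}

#' Default emission spec for a four-macrostate chain
#'
#' Places the four macrostate means on the vertices of a regular tetrahedron
#' in the first three feature dimensions, scaled to `separation` (in units of
#' the emission sd), offsets the microstates of each macrostate by
#' `micro_offset` along macrostate-specific later dimensions, and appends
#' `noise_dims` pure-noise dimensions.  The macrostate geometry lives in a
#' 3-dimensional subspace, so tICA must recover exactly three slow components
#' among the distractor dimensions.
#'
#' The default separation of 16 sd mirrors real structural order parameters,
#' where metastable kinase states differ by several Angstrom against
#' sub-Angstrom in-state fluctuations.  It also matters statistically: the
#' tICA amplitude of a state with population `p` at mean distance `d` is
#' attenuated by `B/(B + sigma^2)` with `B = p(1-p)d^2`, so a 1%-population
#' state needs `d >> 10 sigma` for its slow process to survive noise
#' attenuation and earn a cluster.
#'
#' @param chain a `dt_chain` whose `macro_labels` define the macrostates.
#' @param d signal feature dimension (default 20).
#' @param separation pairwise macrostate mean distance in sd units
#'   (default 16).
#' @param micro_offset intra-macrostate mean offset in sd units (default 1).
#' @param sd emission standard deviation (default 1).
#' @param noise_dims appended pure-noise dimensions (default 30).
#' @return an `emission_spec` for the chain's states.
#' @export
default_emission_spec <- function(chain, d = 20L, separation = 16,
                                  micro_offset = 1, sd = 1, noise_dims = 30L) {
  labels <- chain$macro_labels
  macros <- unique(labels)
  stopifnot(length(macros) <= 4L, d >= 3L + length(macros))
  tetra <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  tetra <- tetra * separation / sqrt(8)  # edge length -> separation
  n <- length(labels)
  means <- matrix(0, n, d)
  for (i in seq_len(n)) {
    m <- match(labels[i], macros)
    means[i, 1:3] <- tetra[m, ]
    ## j-th microstate of macrostate m: offset along dimension 3 + m
    j <- sum(labels[seq_len(i)] == labels[i])
    means[i, 3L + m] <- (j - 1L) * micro_offset * (-1)^j
  }
  emission_spec(means, sd = sd, noise_dims = noise_dims)
}

#' Emit Gaussian features along discrete label trajectories
#'
#' @param labels list of integer state sequences (as from
#'   [sample_discrete()]); attribute `dt` supplies the frame interval,
#'   overridable via `dt`.
#' @param spec an [emission_spec()].
#' @param seed RNG seed.
#' @param dt frame interval ns, if `labels` carries none.
#' @return list of [feature_traj()] objects.
#' @export
emit_features <- function(labels, spec, seed = 1L, dt = NULL) {
  stopifnot(inherits(spec, "emission_spec"))
  dt <- dt %||% attr(labels, "dt") %||% 1
  if (!is.list(labels)) labels <- list(labels)
  n_states <- nrow(spec$means)
  d <- ncol(spec$means)
  set.seed(seed)
  lapply(labels, function(lab) {
    lab <- as.integer(lab)
    if (any(lab < 1L | lab > n_states))
      stop("label outside emission spec (", n_states, " states)")
    n <- length(lab)
    x <- spec$means[lab, , drop = FALSE]
    if (spec$sd > 0) x <- x + matrix(rnorm(n * d, sd = spec$sd), n, d)
    if (spec$noise_dims > 0L)
      x <- cbind(x, matrix(rnorm(n * spec$noise_dims), n, spec$noise_dims))
    feature_traj(x, dt = dt,
                 names = c(sprintf("f%02d", seq_len(d)),
                           if (spec$noise_dims > 0L)
                             sprintf("noise%02d", seq_len(spec$noise_dims))))
  })
}

#' AR(1) process specification
#'
#' Analytic oracle for tICA: a stationary AR(1) process with relaxation time
#' `tau_r` has lag-`tau` autocorrelation `exp(-tau/tau_r)`, which the top
#' tICA eigenvalue must recover.
#'
#' @param relaxation_times per-dimension relaxation times tau_r in ns (> 0;
#'   `Inf` allowed, giving a frozen dimension).
#' @param stationary_variances per-dimension stationary variances (> 0).
#' @param dt frame interval ns.
#' @return object of class `ar1_spec`.
#' @export
ar1_spec <- function(relaxation_times, stationary_variances = 1, dt = 1) {
  stationary_variances <- rep_len(stationary_variances,
                                  length(relaxation_times))
  stopifnot(all(relaxation_times > 0), all(stationary_variances > 0), dt > 0)
  structure(list(relaxation_times = relaxation_times,
                 stationary_variances = stationary_variances, dt = dt),
            class = "ar1_spec")
}

#' Sample a stationary AR(1) feature trajectory
#'
#' Exact discrete-time update `x_{t+1} = a x_t + sqrt(v (1 - a^2)) xi` with
#' `a = exp(-dt/tau_r)`, started from the stationary distribution.
#'
#' @param spec an [ar1_spec()].
#' @param n_steps frames (>= 2).
#' @param seed RNG seed.
#' @return a [feature_traj()].
#' @export
sample_ar1 <- function(spec, n_steps, seed = 1L) {
  stopifnot(inherits(spec, "ar1_spec"), n_steps >= 2L)
  set.seed(seed)
  cols <- lapply(seq_along(spec$relaxation_times), function(k) {
    a <- exp(-spec$dt / spec$relaxation_times[k])
    v <- spec$stationary_variances[k]
    x0 <- rnorm(1L, sd = sqrt(v))
    if (a >= 1) return(rep(x0, n_steps))
    e <- rnorm(n_steps - 1L, sd = sqrt(v * (1 - a^2)))
    c(x0, stats::filter(e, a, method = "recursive", init = x0))
  })
  feature_traj(do.call(cbind, cols), dt = spec$dt,
               names = sprintf("ar1_%d", seq_along(cols)))
}
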