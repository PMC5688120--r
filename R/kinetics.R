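## Kinetic Monte Carlo synthesis, mean first passage times, and bootstrap
## uncertainty for the reported observables.

#' Kinetic Monte Carlo trajectory from an MSM
#'
#' Sequential categorical draws from the transition-matrix rows: a
#' 10,000-frame trajectory at an 80 ns lag synthesizes 800 microseconds of
#' mock dynamics.  When a per-state structure pool is given, each step also
#' records one uniformly drawn member frame of the current state, the
#' convention used to report instantaneous structural observables along a
#' KMC trajectory.
#'
#' @param object an `msm` (or `dt_chain`).
#' @param nsim number of frames (>= 1).
#' @param seed RNG seed.
#' @param start `"stationary"` or a state index (within the active set).
#' @param structure_pool optional list (per state) of frame-index vectors.
#' @param ... unused.
#' @return object of class `kmc_traj`: `states` (integer labels), `lag_ns`,
#'   `total_time_ns`, `seed`, optionally `frames`.
#' @export
simulate.msm <- function(object, nsim = 1L, seed = 1L, start = "stationary",
                         structure_pool = NULL, ...) {
  kmc_sample(object, n_frames = nsim, seed = seed, start = start,
             structure_pool = structure_pool)
}

#' @rdname simulate.msm
#' @param model an `msm` or `dt_chain`.
#' @param n_frames number of KMC frames.
#' @export
kmc_sample <- function(model, n_frames, seed = 1L, start = "stationary",
                       structure_pool = NULL) {
  Tm <- model$transition_matrix
  lag_ns <- model$lag_ns %||% model$dt
  n <- nrow(Tm)
  stopifnot(n_frames >= 1L)
  pi <- model$stationary
  set.seed(seed)
  s0 <- if (identical(start, "stationary")) {
    sample.int(n, 1L, prob = pi)
  } else {
    start <- as.integer(start)
    if (start < 1L || start > n) stop("start state outside active set")
    start
  }
  states <- if (n_frames == 1L) s0 else
    cpp_sample_chain(t(apply(Tm, 1L, cumsum)), as.integer(n_frames), s0 - 1L)
  frames <- NULL
  if (!is.null(structure_pool)) {
    if (length(structure_pool) < n)
      stop("structure pool must cover all ", n, " states")
    frames <- vapply(states, function(s) {
      pool <- structure_pool[[s]]
      pool[sample.int(length(pool), 1L)]
    }, 0)
  }
  structure(list(states = as.integer(states), lag_ns = lag_ns,
                 total_time_ns = n_frames * lag_ns, seed = seed,
                 frames = frames),
            class = "kmc_traj")
}

#' @export
print.kmc_traj <- function(x, ...) {
  cat("<kmc_traj> ", length(x$states), " frames x ", x$lag_ns,
      " ns = ", x$total_time_ns / 1e3, " us total\n", sep = "")
  invisible(x)
}

#' Mean first passage time
#'
#' Solves the linear system `m_i = tau + sum_j T_ij m_j` for `i` outside the
#' sink set, with `m_i = 0` on sinks.  The value for a source *set* is the
#' stationary-weighted average of `m_i` over the sources (weights
#' renormalized within the set).
#'
#' @param object an `msm`, `dt_chain`, or transition matrix (for a bare
#'   matrix, pass `lag` in the dots; default 1, so the result is in steps).
#' @param sources integer state indices (or macrostate labels when the model
#'   carries `macro_labels`).
#' @param sinks integer state indices (or macrostate labels).
#' @param ... method arguments, e.g. `lag`.
#' @return MFPT in ns (in steps when a bare matrix is given with `lag = 1`).
#' @export
mfpt <- function(object, sources, sinks, ...) UseMethod("mfpt")

#' @export
mfpt.msm <- function(object, sources, sinks, ...) {
  mfpt_core(object$transition_matrix, object$stationary, object$lag_ns,
            sources, sinks, labels = NULL)
}

#' @export
mfpt.dt_chain <- function(object, sources, sinks, ...) {
  mfpt_core(object$transition_matrix, object$stationary, object$dt,
            sources, sinks, labels = object$macro_labels)
}

#' @export
mfpt.matrix <- function(object, sources, sinks, lag = 1, ...) {
  ev <- eigen(t(object))
  i <- which.min(abs(ev$values - 1))
  pi <- abs(Re(ev$vectors[, i]))
  pi <- pi / sum(pi)
  mfpt_core(object, pi, lag, sources, sinks, labels = NULL)
}

mfpt_core <- function(Tm, pi, lag_ns, sources, sinks, labels = NULL) {
  n <- nrow(Tm)
  resolve <- function(set) {
    if (is.character(set)) {
      if (is.null(labels)) stop("state labels not available on this model")
      which(labels %in% set)
    } else as.integer(set)
  }
  sources <- resolve(sources)
  sinks <- resolve(sinks)
  if (!length(sinks)) stop("empty sink set")
  if (!length(sources)) stop("empty source set")
  notsink <- setdiff(seq_len(n), sinks)
  m <- numeric(n)
  if (length(notsink)) {
    A <- diag(length(notsink)) - Tm[notsink, notsink, drop = FALSE]
    b <- rep(lag_ns, length(notsink))
    sol <- tryCatch(solve(A, b), error = function(e)
      stop("sink set unreachable from some source (singular MFPT system): ",
           conditionMessage(e)))
    m[notsink] <- sol
  }
  w <- pi[sources]
  sum(w * m[sources]) / sum(w)
}

#' First-hit times by kinetic Monte Carlo
#'
#' Monte Carlo oracle for [mfpt()]: runs many independent KMC walkers from
#' the (stationary-weighted) source states until they enter the sink set and
#' returns the per-run first-hit times.
#'
#' @param model an `msm` or `dt_chain`.
#' @param sources,sinks state index sets (or macrostate labels for chains).
#' @param n_runs number of independent walkers.
#' @param seed RNG seed.
#' @param max_steps per-walker step cap (default 1e8).
#' @return numeric vector of first-hit times in ns (NA where capped).
#' @export
kmc_first_hit <- function(model, sources, sinks, n_runs = 1e4, seed = 1L,
                          max_steps = 1e8) {
  Tm <- model$transition_matrix
  lag_ns <- model$lag_ns %||% model$dt
  labels <- model$macro_labels
  n <- nrow(Tm)
  resolve <- function(set) {
    if (is.character(set)) which(labels %in% set) else as.integer(set)
  }
  sources <- resolve(sources)
  sinks <- resolve(sinks)
  set.seed(seed)
  w <- model$stationary[sources]
  starts <- sources[sample.int(length(sources), n_runs, replace = TRUE,
                               prob = w / sum(w))]
  is_sink <- seq_len(n) %in% sinks
  steps <- cpp_first_hit_steps(t(apply(Tm, 1L, cumsum)), starts - 1L,
                               is_sink, max_steps)
  steps * lag_ns
}

#' Bootstrap confidence intervals over trajectories
#'
#' Resamples whole trajectories with replacement (same count), re-estimates
#' the MSM from the resampled counts at each round, evaluates the requested
#' observables, and reports the median with the 2.5/97.5 percentile
#' interval — the sub/superscript convention of the reported numbers.
#' Rounds whose resample loses connectivity for a required state are
#' skipped, not imputed; the skip count is reported.
#'
#' @param dtrajs list of integer microstate trajectories.
#' @param lag Markov lag in frames.
#' @param observables named list of functions `function(msm) -> named
#'   numeric`; see [obs_populations()], [obs_mfpt()], [obs_timescales()].
#' @param n_rounds bootstrap rounds (default 200).
#' @param seed RNG seed.
#' @param dt frame interval ns.
#' @param n_states microstate count.
#' @return object of class `bootstrap_summary`: a `data.frame` with columns
#'   `observable`, `median`, `lo95`, `hi95`, `n_effective_rounds`;
#'   attributes `values` (rounds x observables matrix) and `n_skipped`.
#' @export
bootstrap_observables <- function(dtrajs, lag, observables, n_rounds = 200L,
                                  seed = 1L, dt = NULL, n_states = NULL) {
  dt <- dt %||% attr(dtrajs, "dt") %||% 1
  stopifnot(length(dtrajs) >= 2L, is.list(observables),
            !is.null(names(observables)))
  if (is.null(n_states)) n_states <- max(vapply(dtrajs, max, 1L))
  ## per-trajectory counts: a resample's count matrix is a weighted sum
  percounts <- lapply(dtrajs, function(s)
    tryCatch(count_transitions(list(s), lag, n_states),
             error = function(e) matrix(0, n_states, n_states)))
  set.seed(seed)
  rows <- vector("list", n_rounds)
  n_skipped <- 0L
  for (r in seq_len(n_rounds)) {
    take <- sample.int(length(dtrajs), length(dtrajs), replace = TRUE)
    C <- Reduce(`+`, percounts[take])
    res <- tryCatch({
      tr <- ergodic_trim(C)
      fit <- mle_reversible(tr$counts)
      sp <- spectral_decompose_matrix(fit$transition_matrix, fit$stationary,
                                      lag * dt)
      m <- structure(list(transition_matrix = fit$transition_matrix,
                          lag = as.integer(lag), lag_ns = lag * dt, dt = dt,
                          stationary = fit$stationary,
                          eigenvalues = sp$eigenvalues,
                          right_eigenvectors = sp$right_eigenvectors,
                          timescales = sp$timescales,
                          active = tr$active, counts = tr$counts,
                          estimator = list()), class = "msm")
      unlist(lapply(observables, function(f) f(m)))
    }, error = function(e) NULL)
    if (is.null(res)) n_skipped <- n_skipped + 1L else rows[[r]] <- res
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) stop("every bootstrap round failed estimation")
  ## align on the union of observable names (rounds may drop states)
  nms <- unique(unlist(lapply(rows, names)))
  vals <- do.call(rbind, lapply(rows, function(v) v[nms]))
  colnames(vals) <- nms
  summ <- data.frame(
    observable = nms,
    median = apply(vals, 2L, median, na.rm = TRUE),
    lo95 = apply(vals, 2L, quantile, 0.025, na.rm = TRUE, names = FALSE),
    hi95 = apply(vals, 2L, quantile, 0.975, na.rm = TRUE, names = FALSE),
    n_effective_rounds = apply(vals, 2L, function(z) sum(!is.na(z))),
    row.names = NULL)
  structure(summ, class = c("bootstrap_summary", "data.frame"),
            values = vals, n_skipped = n_skipped, n_rounds = n_rounds,
            seed = seed)
}

#' Observable builders for [bootstrap_observables()]
#'
#' `obs_populations` reports macrostate populations (given a microstate ->
#' macrostate map over original indices), `obs_mfpt` a single MFPT between
#' macrostate sets, and `obs_timescales` the leading implied timescales.
#'
#' @param map macrostate label per original microstate index.
#' @return a function `function(msm) -> named numeric`.
#' @export
obs_populations <- function(map) {
  function(m) {
    p <- macrostate_populations(m, map)
    names(p) <- paste0("pop_", names(p))
    p
  }
}

#' @rdname obs_populations
#' @param sources,sinks macrostate label sets.
#' @param name observable name.
#' @export
obs_mfpt <- function(map, sources, sinks, name = "mfpt") {
  function(m) {
    lab <- map[m$active]
    src <- which(lab %in% sources)
    snk <- which(lab %in% sinks)
    if (!length(src) || !length(snk))
      stop("macrostate lost after trimming; round skipped")
    out <- mfpt(m, src, snk)
    names(out) <- name
    out
  }
}

#' @rdname obs_populations
#' @param n number of timescales.
#' @export
obs_timescales <- function(n = 3L) {
  function(m) {
    ts <- head(m$timescales, n)
    names(ts) <- paste0("timescale_", seq_along(ts))
    ts
  }
}
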