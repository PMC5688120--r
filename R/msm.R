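## Discretization of tIC space, reversible MSM estimation, spectral
## thermodynamics and model-selection diagnostics.

#' K-means discretization of tICA space
#'
#' Clusters the pooled projected frames with K-means at a fixed seed, then
#' assigns every frame to its nearest center (Euclidean metric), returning
#' one discrete trajectory per input trajectory.
#'
#' @param tic_trajs list of [feature_traj()] or matrices in tIC space.
#' @param n_clusters number of microstates k (>= 2).
#' @param seed RNG seed; identical seeds give identical labels.
#' @param iter_max Lloyd/Hartigan-Wong iteration cap per restart.
#' @param nstart independent k-means++ seedings; the lowest-inertia solution
#'   wins, which reliably dedicates a center to small well-separated
#'   metastable blobs.
#' @return list with `model` (class `cluster_model`: `centers`, `inertia`,
#'   `seed`) and `dtrajs` (list of integer label vectors in `1..k`, with
#'   attribute `dt`).
#' @export
kmeans_discretize <- function(tic_trajs, n_clusters, seed = 1L,
                              iter_max = 100L, nstart = 10L) {
  xs <- as_feature_list(tic_trajs)
  dt <- attr(xs, "dt")
  X <- do.call(rbind, xs)
  if (n_clusters < 2L) stop("n_clusters must be >= 2")
  if (nrow(X) < n_clusters) stop("fewer frames than clusters")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(nstart)) {
    init <- kmeanspp_init(X, n_clusters)
    km <- tryCatch(
      suppressWarnings(stats::kmeans(X, centers = init, iter.max = iter_max)),
      error = function(e) NULL)
    if (!is.null(km) && (is.null(best) || km$tot.withinss < best$tot.withinss))
      best <- km
  }
  if (is.null(best)) stop("k-means failed on every restart")
  model <- structure(list(centers = unname(best$centers),
                          n_clusters = as.integer(n_clusters),
                          seed = seed, inertia = best$tot.withinss),
                     class = "cluster_model")
  dtrajs <- lapply(xs, function(x) assign_clusters(model, x))
  attr(dtrajs, "dt") <- dt
  list(model = model, dtrajs = dtrajs)
}

## k-means++ seeding: first center uniform, subsequent centers sampled with
## probability proportional to the squared distance to the nearest chosen
## center.  Uses the session RNG (caller fixes the seed).
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1L, ] <- X[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(X, 2L, centers[1L, ])^2)
  for (j in 2L:k) {
    pick <- sample.int(n, 1L, prob = d2)
    centers[j, ] <- X[pick, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[j, ])^2))
  }
  centers
}

#' Assign frames to nearest cluster centers
#'
#' @param model a `cluster_model`.
#' @param x frame matrix (or [feature_traj()]).
#' @return integer vector of 1-based cluster labels.
#' @export
assign_clusters <- function(model, x) {
  if (inherits(x, "feature_traj")) x <- x$values
  C <- model$centers
  ## ||x - c||^2 = |x|^2 + |c|^2 - 2 x.c ; |x|^2 constant per row
  D <- outer(rep(1, nrow(x)), rowSums(C^2)) - 2 * x %*% t(C)
  max.col(-D, ties.method = "first")
}

#' Sliding-window transition counts
#'
#' Every `(t, t + lag)` frame pair within each trajectory increments
#' `C[s_t, s_{t+lag}]`; pairs never cross trajectory boundaries.
#'
#' @param dtrajs list of integer label vectors (1-based).
#' @param lag lag in frames (>= 1).
#' @param n_states state-space size; default the maximum observed label.
#' @return `n_states x n_states` count matrix with attributes `lag`.
#' @export
count_transitions <- function(dtrajs, lag, n_states = NULL) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  lag <- as.integer(lag)
  stopifnot(lag >= 1L)
  if (is.null(n_states)) n_states <- max(unlist(lapply(dtrajs, max)))
  n <- as.integer(n_states)
  C <- matrix(0, n, n)
  any_pairs <- FALSE
  for (s in dtrajs) {
    m <- length(s)
    if (m <= lag) next
    any_pairs <- TRUE
    from <- s[1L:(m - lag)]
    to <- s[(1L + lag):m]
    idx <- (from - 1L) * n + to  # column-major: C[to, from] -> use t() later
    tab <- tabulate(idx, nbins = n * n)
    C <- C + t(matrix(tab, n, n))
  }
  if (!any_pairs) stop("lag >= length of every trajectory: no transition pairs")
  attr(C, "lag") <- lag
  C
}

#' Restrict counts to the largest ergodic component
#'
#' Keeps the largest strongly connected component of the directed graph with
#' an edge `i -> j` wherever `C_ij > 0` (ties broken toward the component
#' with the most counts).
#'
#' @param counts square count matrix.
#' @return list with `counts` (trimmed matrix) and `active` (original state
#'   indices retained).
#' @export
ergodic_trim <- function(counts) {
  n <- nrow(counts)
  keep <- which(rowSums(counts) + colSums(counts) > 0)
  if (!length(keep)) stop("all-zero count matrix")
  g <- igraph::graph_from_adjacency_matrix(counts[keep, keep, drop = FALSE] > 0,
                                           mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    wt <- vapply(best, function(b) {
      i <- keep[comp$membership == b]
      sum(counts[i, i])
    }, 0)
    best <- best[which.max(wt)]
  }
  active <- keep[comp$membership == best]
  list(counts = counts[active, active, drop = FALSE], active = active)
}

#' Reversible maximum-likelihood transition matrix
#'
#' Maximizes `prod T_ij^{C_ij}` subject to detailed balance via the
#' classical self-consistent iteration on symmetric edge weights
#' `x_ij = x_ji`: `x_ij <- (C_ij + C_ji) / (c_i/x_i + c_j/x_j)` with
#' `c_i = sum_j C_ij`, `x_i = sum_j x_ij`.  Convergence is declared when the
#' log-likelihood changes by less than `tol` between sweeps.  The stationary
#' distribution is `pi_i = x_i / sum x` and `T_ij = x_ij / x_i`; detailed
#' balance holds by construction.
#'
#' @param counts connected (post-trim) count matrix.
#' @param tol log-likelihood convergence threshold (default 1e-10).
#' @param max_iter maximum sweeps (default 1e6).
#' @return list with `transition_matrix`, `stationary`, `loglik`,
#'   `iterations`, `converged`, `last_delta`.
#' @export
mle_reversible <- function(counts, tol = 1e-10, max_iter = 1e6) {
  C <- as.matrix(counts)
  n <- nrow(C)
  if (any(rowSums(C) == 0) || any(colSums(C) == 0))
    stop("count matrix has empty rows/columns; run ergodic_trim first")
  Cs <- C + t(C)
  ci <- rowSums(C)
  x <- Cs
  ll_of <- function(Tm) {
    nz <- C > 0
    sum(C[nz] * log(Tm[nz]))
  }
  xi <- rowSums(x)
  Tm <- x / xi
  ll <- ll_of(Tm)
  it <- 0L
  delta <- Inf
  while (it < max_iter) {
    it <- it + 1L
    q <- ci / xi
    denom <- outer(q, q, "+")
    x <- ifelse(Cs > 0, Cs / denom, 0)
    xi <- rowSums(x)
    Tm <- x / xi
    ll_new <- ll_of(Tm)
    delta <- abs(ll_new - ll)
    ll <- ll_new
    if (delta < tol) break
  }
  pi <- xi / sum(xi)
  list(transition_matrix = Tm, stationary = pi, loglik = ll,
       iterations = it, converged = delta < tol, last_delta = delta)
}

#' Estimate a reversible Markov state model
#'
#' Full estimation chain: sliding-window counts at `lag`, ergodic trim to the
#' largest strongly connected component, reversible maximum-likelihood
#' transition matrix, and spectral decomposition (eigenvalues, implied
#' timescales, stationary distribution).
#'
#' @param dtrajs list of integer label vectors.
#' @param lag Markov lag in frames.
#' @param dt frame interval in ns (default taken from `attr(dtrajs, "dt")`,
#'   else 1), so `lag_ns = lag * dt`.
#' @param n_states optional state-space size.
#' @param tol,max_iter passed to [mle_reversible()].
#' @return an object of class `msm`: `transition_matrix`, `lag` (frames),
#'   `lag_ns`, `stationary`, `eigenvalues`, `timescales` (ns), `active`
#'   (original microstate indices), `counts` (trimmed), `estimator` metadata.
#' @export
markov_model <- function(dtrajs, lag, dt = NULL, n_states = NULL,
                         tol = 1e-10, max_iter = 1e6) {
  dt <- dt %||% attr(dtrajs, "dt") %||% 1
  C <- count_transitions(dtrajs, lag, n_states)
  tr <- ergodic_trim(C)
  fit <- mle_reversible(tr$counts, tol = tol, max_iter = max_iter)
  lag_ns <- lag * dt
  sp <- spectral_decompose_matrix(fit$transition_matrix, fit$stationary,
                                  lag_ns)
  structure(list(transition_matrix = fit$transition_matrix,
                 lag = as.integer(lag), lag_ns = lag_ns, dt = dt,
                 stationary = fit$stationary,
                 eigenvalues = sp$eigenvalues,
                 right_eigenvectors = sp$right_eigenvectors,
                 timescales = sp$timescales,
                 active = tr$active, counts = tr$counts,
                 estimator = list(tol = tol, iterations = fit$iterations,
                                  converged = fit$converged,
                                  loglik = fit$loglik)),
            class = "msm")
}

## Spectral decomposition of a reversible transition matrix via the
## pi-symmetrized form  S = D^{1/2} T D^{-1/2}, which is symmetric under
## detailed balance and therefore has a real spectrum.
spectral_decompose_matrix <- function(Tm, pi, lag_ns) {
  s <- sqrt(pi)
  S <- Tm * outer(s, 1 / s)
  asym <- max(abs(S - t(S)))
  if (asym > 1e-6)
    stop("transition matrix is not reversible (symmetrization residual ",
         signif(asym, 3), ")")
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  ord <- order(e$values, decreasing = TRUE)
  mu <- e$values[ord]
  ## right eigenvectors of T: psi = D^{-1/2} w
  psi <- e$vectors[, ord, drop = FALSE] / s
  list(eigenvalues = mu,
       right_eigenvectors = psi,
       timescales = timescale_of_component(mu[-1L], lag_ns))
}

#' Spectral decomposition of an MSM
#'
#' @param model an `msm`.
#' @param n_timescales number of implied timescales to return.
#' @return list with `eigenvalues` (descending, first = 1), `timescales`
#'   (ns, via `-tau/log(mu)`), `stationary`.
#' @export
spectral_decompose <- function(model, n_timescales = NULL) {
  stopifnot(inherits(model, "msm"))
  k <- n_timescales %||% (length(model$eigenvalues) - 1L)
  list(eigenvalues = model$eigenvalues,
       timescales = head(model$timescales, k),
       stationary = model$stationary)
}

#' @export
print.msm <- function(x, ...) {
  cat("<msm> ", nrow(x$transition_matrix), " states (",
      length(x$active), " active), lag = ", x$lag_ns, " ns\n", sep = "")
  cat("implied timescales (ns):",
      paste(signif(head(x$timescales, 5), 4), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.msm <- function(object, ...) {
  cat("Reversible Markov state model\n")
  cat("  states:     ", nrow(object$transition_matrix), "\n")
  cat("  lag:        ", object$lag_ns, "ns (", object$lag, "frames )\n")
  cat("  estimator:  ", object$estimator$iterations,
      "sweeps, converged =", object$estimator$converged, "\n")
  cat("  stationary: ", paste(signif(object$stationary, 3), collapse = " "),
      "\n")
  cat("  timescales: ", paste(signif(head(object$timescales, 5), 4),
                              collapse = " "), "ns\n")
  invisible(object)
}

#' @export
stationary.msm <- function(object, ...) object$stationary

#' Implied timescales
#'
#' @param object an `msm` or `tica` model.
#' @param ... unused.
#' @return implied timescales in ns.
#' @export
timescales <- function(object, ...) UseMethod("timescales")

#' @export
timescales.msm <- function(object, ...) object$timescales

#' @export
timescales.tica <- function(object, ...)
  timescale_of_component(head(object$eigenvalues, object$n_components),
                         object$lag_ns)

#' Implied-timescale convergence scan
#'
#' Re-estimates the full MSM (counts, trim, reversible MLE, spectral
#' decomposition) at each lag and tabulates the implied timescales.
#' Lag-independent timescales indicate Markovian behaviour; the scan flags
#' the smallest lag after which the slowest timescale varies by less than
#' 10% relative to the previous lag.
#'
#' @param dtrajs list of integer label vectors.
#' @param lags integer lags in frames.
#' @param n_timescales timescales per lag to keep (default 3).
#' @param dt frame interval ns.
#' @return `data.frame` with columns `lag`, `lag_ns`, `index`, `timescale`;
#'   attribute `suggested_lag` (frames, possibly NA).
#' @export
implied_timescale_scan <- function(dtrajs, lags, n_timescales = 3L,
                                   dt = NULL) {
  dt <- dt %||% attr(dtrajs, "dt") %||% 1
  rows <- list()
  top <- rep(NA_real_, length(lags))
  for (k in seq_along(lags)) {
    m <- markov_model(dtrajs, lags[k], dt = dt)
    ts <- head(m$timescales, n_timescales)
    if (length(ts)) top[k] <- ts[1L]
    if (length(ts))
      rows[[k]] <- data.frame(lag = lags[k], lag_ns = lags[k] * dt,
                              index = seq_along(ts), timescale = ts)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(lag = integer(), lag_ns = numeric(), index = integer(),
                      timescale = numeric())
  suggested <- NA_integer_
  if (length(lags) >= 2L) {
    rel <- abs(diff(top)) / head(top, -1L)
    i <- which(rel < 0.10)
    if (length(i)) suggested <- lags[min(i) + 1L]
  }
  attr(out, "suggested_lag") <- suggested
  out
}

#' Map microstates to macrostates by explicit predicates
#'
#' Each rule is a predicate evaluated on the cluster centers (a function of
#' the center matrix returning a logical per center).  Every center must
#' match exactly one rule; unmatched or multiply-matched centers raise an
#' error listing the offenders.
#'
#' @param cluster_model a `cluster_model` (or bare center matrix).
#' @param rules named list of predicate functions.
#' @return named character vector: macrostate label per microstate.
#' @export
assign_macrostates <- function(cluster_model, rules) {
  centers <- if (inherits(cluster_model, "cluster_model"))
    cluster_model$centers else as.matrix(cluster_model)
  stopifnot(is.list(rules), length(rules) >= 1L, !is.null(names(rules)))
  hits <- vapply(rules, function(f) as.logical(f(centers)),
                 logical(nrow(centers)))
  hits <- matrix(hits, nrow = nrow(centers))
  nhits <- rowSums(hits)
  if (any(nhits != 1L))
    stop("macrostate rules must partition the centers; offending centers: ",
         paste(which(nhits != 1L), collapse = ", "),
         " (matches: ", paste(nhits[nhits != 1L], collapse = ", "), ")")
  out <- names(rules)[apply(hits, 1L, which)]
  names(out) <- rownames(centers) %||% as.character(seq_along(out))
  out
}

#' Map microstates to macrostates by majority reference label
#'
#' For synthetic data with known generator labels: each microstate receives
#' the most frequent reference macrostate label among the frames assigned to
#' it (label-propagation rule).
#'
#' @param dtrajs list of integer microstate label vectors.
#' @param ref_labels list of character/integer reference macrostate labels,
#'   frame-aligned with `dtrajs`.
#' @param n_states microstate count (default max observed).
#' @return character vector: macrostate label per microstate (NA for
#'   microstates with no frames).
#' @export
macrostates_from_labels <- function(dtrajs, ref_labels, n_states = NULL) {
  stopifnot(length(dtrajs) == length(ref_labels))
  micro <- unlist(dtrajs, use.names = FALSE)
  ref <- unlist(lapply(ref_labels, as.character), use.names = FALSE)
  stopifnot(length(micro) == length(ref))
  if (is.null(n_states)) n_states <- max(micro)
  tab <- table(factor(micro, levels = seq_len(n_states)), ref)
  lab <- colnames(tab)[max.col(tab, ties.method = "first")]
  lab[rowSums(tab) == 0] <- NA_character_
  lab
}

#' Macrostate equilibrium populations
#'
#' Sums the MSM stationary distribution over the member microstates of each
#' macrostate.  Populations sum to 1.
#'
#' @param model an `msm`.
#' @param map macrostate label per microstate, indexed by *original*
#'   microstate id (length covering `model$active`).
#' @return named numeric vector of populations.
#' @export
macrostate_populations <- function(model, map) {
  stopifnot(inherits(model, "msm"))
  lab <- map[model$active]
  if (anyNA(lab)) stop("macrostate map does not cover the active set")
  p <- tapply(model$stationary, lab, sum)
  out <- as.numeric(p)
  names(out) <- names(p)
  out
}

#' Free energies from populations
#'
#' `G_i = -kT log(p_i / p_ref)`.  The reference defaults to the
#' highest-populated state; an external reference population (e.g. the
#' reference ensemble's top state, enabling cross-ensemble comparisons) may
#' be given instead.  Zero populations map to `Inf`, not an error.
#'
#' @param populations named numeric vector.
#' @param temperature Kelvin (default 300).
#' @param reference a state name, or a single numeric reference population.
#' @return named numeric vector of free energies in kcal/mol.
#' @export
free_energies <- function(populations, temperature = 300, reference = NULL) {
  p_ref <- if (is.numeric(reference) && length(reference) == 1L) {
    reference
  } else if (is.character(reference)) {
    populations[[reference]]
  } else {
    max(populations)
  }
  stopifnot(p_ref > 0)
  G <- -kT(temperature) * log(populations / p_ref)
  G[populations <= 0] <- Inf
  G
}

#' Cross-validated MSM hyperparameter selection
#'
#' Trajectory-level k-fold cross-validation with a variational (GMRQ-style)
#' score: for each hyperparameter combination, tICA + K-means + reversible
#' MSM are fit on the training folds; the score is the generalized matrix
#' Rayleigh quotient of the training eigenvectors under the test-fold
#' correlation matrices — on-sample it reduces to the sum of the top `m`
#' transition-matrix eigenvalues, and overfit discretizations score lower
#' out of sample.
#'
#' @param trajs list of [feature_traj()] (feature space, pre-normalization
#'   optional).
#' @param grid `data.frame` with columns `tica_lag`, `n_components`,
#'   `kinetic_mapping`, `n_clusters` (lags in frames).
#' @param msm_lag Markov lag in frames.
#' @param n_folds number of folds (whole trajectories per fold).
#' @param n_timescales `m - 1`; the score sums `m = n_timescales + 1`
#'   eigenvalues.
#' @param seed RNG seed (fold shuffle and K-means).
#' @return list with `scores` (`data.frame`: grid columns, `mean_score`,
#'   `n_folds_ok`) and `best` (row of `grid` with the highest mean score).
#' @export
cross_validate_msm <- function(trajs, grid, msm_lag, n_folds = 2L,
                               n_timescales = 3L, seed = 1L) {
  xs <- as_feature_list(trajs)
  stopifnot(nrow(grid) >= 1L, n_folds >= 2L, length(xs) >= n_folds)
  set.seed(seed)
  fold_of <- sample(rep_len(seq_len(n_folds), length(xs)))
  m_eigs <- n_timescales + 1L
  mean_score <- numeric(nrow(grid))
  n_ok <- integer(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    sc <- rep(NA_real_, n_folds)
    for (f in seq_len(n_folds)) {
      train <- xs[fold_of != f]
      test <- xs[fold_of == f]
      sc[f] <- tryCatch(
        gmrq_score(train, test,
                   tica_lag = grid$tica_lag[g],
                   n_components = grid$n_components[g],
                   kinetic_mapping = grid$kinetic_mapping[g],
                   n_clusters = grid$n_clusters[g],
                   msm_lag = msm_lag, m = m_eigs, seed = seed),
        error = function(e) NA_real_)
    }
    mean_score[g] <- mean(sc, na.rm = TRUE)
    n_ok[g] <- sum(!is.na(sc))
  }
  scores <- cbind(grid, mean_score = mean_score, n_folds_ok = n_ok)
  list(scores = scores, best = grid[which.max(mean_score), , drop = FALSE])
}

## GMRQ: trace of the Rayleigh quotient of the training MSM eigenvectors
## under test-set overlap (C00) and lagged (Ctau) matrices.
gmrq_score <- function(train, test, tica_lag, n_components, kinetic_mapping,
                       n_clusters, msm_lag, m, seed) {
  tic <- tica(train, lag = tica_lag, n_components = n_components,
              kinetic_mapping = kinetic_mapping)
  ytr <- predict(tic, train)
  km <- kmeans_discretize(ytr, n_clusters, seed = seed)
  msm <- markov_model(km$dtrajs, msm_lag)
  m <- min(m, length(msm$eigenvalues))
  V <- msm$right_eigenvectors[, seq_len(m), drop = FALSE]
  ## normalize: V^T diag(pi) V = I on the training model
  nrm <- sqrt(colSums(V^2 * msm$stationary))
  V <- sweep(V, 2L, nrm, "/")
  yte <- predict(tic, test)
  dte <- lapply(yte, function(y) assign_clusters(km$model, y))
  n_act <- length(msm$active)
  remap <- rep(NA_integer_, km$model$n_clusters)
  remap[msm$active] <- seq_len(n_act)
  Cte <- matrix(0, n_act, n_act)
  for (s in dte) {
    s <- remap[s]
    ok <- !is.na(s)
    ## break runs at frames falling outside the active set
    runs <- split(seq_along(s)[ok], cumsum(!ok)[ok])
    for (r in runs) {
      if (length(r) <= msm_lag) next
      sr <- s[r]
      mlen <- length(sr)
      from <- sr[1L:(mlen - msm_lag)]
      to <- sr[(1L + msm_lag):mlen]
      idx <- (from - 1L) * n_act + to
      Cte <- Cte + t(matrix(tabulate(idx, nbins = n_act^2), n_act, n_act))
    }
  }
  if (sum(Cte) == 0) stop("test fold has no transition pairs in active set")
  S <- (Cte + t(Cte)) / (2 * sum(Cte))
  D <- diag(rowSums(S), n_act)
  A <- crossprod(V, D %*% V)
  B <- crossprod(V, S %*% V)
  sum(diag(solve(A, B)))
}
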