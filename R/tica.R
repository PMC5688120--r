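## Time-lagged independent component analysis: slow-coordinate discovery via
## the generalized eigenproblem  C(tau) v = lambda Sigma v.

#' Pooled covariance and time-lagged correlation matrices
#'
#' Mean-free estimates pooled across trajectories: the instantaneous
#' covariance `Sigma_ij = E[X_i(t) X_j(t)]` over all frames, and the
#' time-lagged correlation `C(tau)_ij = E[X_i(t) X_j(t+tau)]` over all valid
#' `(t, t+tau)` pairs taken within each trajectory only (no cross-trajectory
#' pairs).  `C(tau)` is returned both raw and symmetrized as
#' `(C + C^T)/2`, the reversible estimator used by [tica()].
#'
#' @param trajs list of [feature_traj()] (or matrices).
#' @param lag lag in frames (>= 0); 0 gives `C(0) = Sigma` exactly.
#' @return list with `means`, `sigma`, `ctau` (symmetrized), `ctau_raw`,
#'   `n_frames`, `n_pairs`, `lag`.
#' @export
estimate_covariances <- function(trajs, lag) {
  xs <- as_feature_list(trajs)
  lag <- as.integer(lag)
  stopifnot(lag >= 0L)
  lens <- vapply(xs, nrow, 1L)
  if (any(lens <= lag))
    stop("lag (", lag, " frames) must be shorter than every trajectory ",
         "(shortest: ", min(lens), ")")
  d <- ncol(xs[[1L]])
  n <- sum(lens)
  mu <- Reduce(`+`, lapply(xs, colSums)) / n
  sigma <- matrix(0, d, d)
  ctau <- matrix(0, d, d)
  n_pairs <- 0L
  for (x in xs) {
    xc <- sweep(x, 2L, mu)
    sigma <- sigma + crossprod(xc)
    m <- nrow(xc)
    if (lag == 0L) {
      ctau <- ctau + crossprod(xc)
      n_pairs <- n_pairs + m
    } else {
      ctau <- ctau + crossprod(xc[1L:(m - lag), , drop = FALSE],
                               xc[(1L + lag):m, , drop = FALSE])
      n_pairs <- n_pairs + (m - lag)
    }
  }
  sigma <- sigma / n
  ctau <- ctau / n_pairs
  list(means = mu, sigma = (sigma + t(sigma)) / 2,
       ctau = (ctau + t(ctau)) / 2, ctau_raw = ctau,
       n_frames = n, n_pairs = n_pairs, lag = lag)
}

#' Fit a tICA model
#'
#' Solves the generalized eigenproblem `C(tau) v = lambda Sigma v` with the
#' symmetrized lagged correlation and a shrinkage-regularized covariance
#' `Sigma_gamma = (1 - gamma) Sigma + gamma diag(Sigma)`, via Cholesky
#' reduction to an ordinary symmetric eigenproblem.  Eigenpairs are sorted
#' by descending eigenvalue, eigenvectors are `Sigma_gamma`-orthonormal and
#' the sign convention fixes the largest-magnitude loading of each component
#' positive so projections are reproducible.
#'
#' @param trajs list of [feature_traj()] or matrices.
#' @param lag tICA lag in frames, or give `lag_ns` with feature trajectories
#'   carrying `dt`.
#' @param n_components number of components to keep (default
#'   `min(10, rank)`).
#' @param kinetic_mapping logical; scale projected component `i` by
#'   `lambda_i` so Euclidean distance approximates kinetic distance
#'   (default TRUE).
#' @param shrinkage shrinkage weight `gamma` in `[0, 1]`; default `1e-8`
#'   guards against rank-deficient feature sets.
#' @param lag_ns alternative lag specification in ns (requires `dt`).
#' @return an object of class `tica`: `means`, `sigma`, `ctau`,
#'   `eigenvalues`, `eigenvectors` (columns), `lag` (frames), `lag_ns`,
#'   `n_components`, `kinetic_mapping`, `shrinkage`.
#' @export
tica <- function(trajs, lag = NULL, n_components = NULL,
                 kinetic_mapping = TRUE, shrinkage = 1e-8, lag_ns = NULL) {
  xs <- as_feature_list(trajs)
  dt <- attr(xs, "dt")
  if (is.null(lag)) {
    if (is.null(lag_ns)) stop("give lag (frames) or lag_ns")
    if (is.na(dt)) stop("lag_ns requires trajectories carrying dt")
    lag <- lag_ns / dt
    if (abs(lag - round(lag)) > 1e-9)
      stop("lag_ns = ", lag_ns, " is not a multiple of dt = ", dt)
    lag <- as.integer(round(lag))
  }
  cov <- estimate_covariances(xs, lag)
  model <- solve_tica(cov$sigma, cov$ctau, n_components = n_components,
                      shrinkage = shrinkage)
  model$means <- cov$means
  model$lag <- cov$lag
  model$lag_ns <- if (is.na(dt)) NA_real_ else cov$lag * dt
  model$dt <- dt
  model$kinetic_mapping <- isTRUE(kinetic_mapping)
  model
}

#' Solve the tICA generalized eigenproblem from given matrices
#'
#' @param sigma instantaneous covariance (symmetric PSD).
#' @param ctau symmetrized time-lagged correlation.
#' @param n_components components to keep; default all.
#' @param shrinkage shrinkage weight gamma.
#' @return a `tica` object (without data-dependent metadata).
#' @export
solve_tica <- function(sigma, ctau, n_components = NULL, shrinkage = 1e-8) {
  stopifnot(is.matrix(sigma), is.matrix(ctau), all(dim(sigma) == dim(ctau)))
  if (!all(is.finite(sigma)) || !all(is.finite(ctau)))
    stop("non-finite covariance matrices")
  if (all(sigma == 0)) stop("all-zero covariance matrix")
  d <- ncol(sigma)
  gamma <- shrinkage
  sig_g <- (1 - gamma) * sigma + gamma * diag(diag(sigma), d)
  L <- tryCatch(t(chol(sig_g)), error = function(e)
    stop("regularized covariance is not positive definite; ",
         "increase shrinkage (", conditionMessage(e), ")"))
  ## whiten: M = L^-1 Csym L^-T, ordinary symmetric eigenproblem
  Li_C <- forwardsolve(L, (ctau + t(ctau)) / 2)
  M <- t(forwardsolve(L, t(Li_C)))
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  ord <- order(e$values, decreasing = TRUE)
  lambda <- e$values[ord]
  V <- backsolve(t(L), e$vectors[, ord, drop = FALSE])
  ## sign convention: largest-magnitude loading positive
  for (k in seq_len(ncol(V))) {
    i <- which.max(abs(V[, k]))
    if (V[i, k] < 0) V[, k] <- -V[, k]
  }
  if (is.null(n_components)) n_components <- d
  n_components <- min(n_components, d)
  structure(list(means = rep(0, d), sigma = sigma, ctau = ctau,
                 eigenvalues = lambda,
                 eigenvectors = V,
                 n_components = as.integer(n_components),
                 kinetic_mapping = TRUE, shrinkage = gamma,
                 lag = NA_integer_, lag_ns = NA_real_, dt = NA_real_),
            class = "tica")
}

#' @export
print.tica <- function(x, ...) {
  cat("<tica> ", nrow(x$eigenvectors), " features -> ", x$n_components,
      " components, lag = ", x$lag, " frames",
      if (!is.na(x$lag_ns)) paste0(" (", x$lag_ns, " ns)"), "\n", sep = "")
  cat("top eigenvalues:",
      paste(signif(head(x$eigenvalues, x$n_components), 4), collapse = " "),
      "\n")
  cat("kinetic mapping:", x$kinetic_mapping, " shrinkage:", x$shrinkage, "\n")
  invisible(x)
}

#' Project feature trajectories onto tICA components
#'
#' Mean-free projection onto the leading eigenvectors; with kinetic mapping
#' each component `i` is scaled by its eigenvalue `lambda_i`.
#'
#' @param object a `tica` model.
#' @param trajs list of [feature_traj()] or matrices (feature dimension must
#'   match the model).
#' @param ... unused.
#' @return list of projected [feature_traj()]s (matrices if the input had no
#'   dt), columns `tic1..tick`.
#' @export
predict.tica <- function(object, trajs, ...) {
  xs <- as_feature_list(trajs)
  dt <- attr(xs, "dt")
  d <- nrow(object$eigenvectors)
  if (ncol(xs[[1L]]) != d)
    stop("feature dimension ", ncol(xs[[1L]]), " does not match model (",
         d, ")")
  k <- object$n_components
  V <- object$eigenvectors[, seq_len(k), drop = FALSE]
  if (object$kinetic_mapping)
    V <- sweep(V, 2L, object$eigenvalues[seq_len(k)], "*")
  out <- lapply(xs, function(x) {
    y <- sweep(x, 2L, object$means) %*% V
    colnames(y) <- sprintf("tic%d", seq_len(k))
    if (is.na(dt)) y else feature_traj(y, dt = dt)
  })
  out
}

#' Relaxation timescale of a tICA component or MSM eigenvalue
#'
#' The spectral mapping `t_i = -tau / log(lambda_i)`.  Non-positive
#' eigenvalues have no relaxation interpretation and map to `NaN`;
#' eigenvalues at or above 1 map to `Inf`.
#'
#' @param lambda eigenvalue(s) in (0, 1).
#' @param lag_ns lag tau in ns.
#' @return relaxation time(s) in ns.
#' @export
timescale_of_component <- function(lambda, lag_ns) {
  out <- rep(NaN, length(lambda))
  out[lambda >= 1] <- Inf
  ok <- lambda > 0 & lambda < 1
  out[ok] <- -lag_ns / log(lambda[ok])
  out
}
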