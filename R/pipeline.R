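## Configuration-driven orchestration: end-to-end runs, shared state
## definitions across two ensembles, free-energy surfaces.

#' Pipeline configuration
#'
#' Declarative configuration for the end-to-end analysis.  The defaults are
#' the selected model hyperparameters of the BTK study (tICA lag 208 ns,
#' 3 components, kinetic mapping on, 190 clusters, 80 ns Markov lag);
#' fixture-scale runs override them.  All seeds are explicit so a rerun with
#' the same config and inputs is bit-identical.  Lags are validated as
#' positive multiples of the frame interval at run time.
#'
#' @param tica_lag_ns tICA lag, ns.
#' @param n_components tICA components kept.
#' @param kinetic_mapping scale components by their eigenvalues.
#' @param shrinkage tICA covariance shrinkage.
#' @param n_clusters K-means microstate count (>= 2).
#' @param cluster_seed K-means seed.
#' @param msm_lag_ns Markov lag, ns.
#' @param msm_tol reversible-MLE convergence tolerance.
#' @param temperature Kelvin.
#' @param normalize z-score features before tICA.
#' @param bootstrap_rounds bootstrap rounds (0 disables).
#' @param bootstrap_seed bootstrap seed.
#' @param macrostates macrostate rule: `NULL` (none), `"reference_labels"`
#'   (majority vote against generator labels supplied to [run_pipeline()]),
#'   or a named list of predicates for [assign_macrostates()].
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(tica_lag_ns = 208, n_components = 3L,
                            kinetic_mapping = TRUE, shrinkage = 1e-8,
                            n_clusters = 190L, cluster_seed = 1L,
                            msm_lag_ns = 80, msm_tol = 1e-10,
                            temperature = 300, normalize = TRUE,
                            bootstrap_rounds = 200L, bootstrap_seed = 1L,
                            macrostates = "reference_labels") {
  cfg <- list(tica_lag_ns = tica_lag_ns, n_components = as.integer(n_components),
              kinetic_mapping = isTRUE(kinetic_mapping), shrinkage = shrinkage,
              n_clusters = as.integer(n_clusters),
              cluster_seed = as.integer(cluster_seed),
              msm_lag_ns = msm_lag_ns, msm_tol = msm_tol,
              temperature = temperature, normalize = isTRUE(normalize),
              bootstrap_rounds = as.integer(bootstrap_rounds),
              bootstrap_seed = as.integer(bootstrap_seed),
              macrostates = macrostates)
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg, dt = NULL) {
  stopifnot(cfg$tica_lag_ns > 0, cfg$msm_lag_ns > 0, cfg$n_components >= 1L,
            cfg$n_clusters >= 2L, cfg$temperature > 0,
            cfg$bootstrap_rounds >= 0L)
  if (!is.null(dt)) {
    for (lag in c(cfg$tica_lag_ns, cfg$msm_lag_ns)) {
      r <- lag / dt
      if (abs(r - round(r)) > 1e-9 || round(r) < 1)
        stop("lag ", lag, " ns is not a positive multiple of dt = ", dt, " ns")
    }
  }
  invisible(cfg)
}

#' Read a pipeline configuration from a YAML file
#'
#' @param file path to a YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(file) {
  vals <- yaml::read_yaml(file)
  do.call(pipeline_config, vals)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat("  ", k, ": ",
        if (is.list(v)) paste0("<", length(v), " rules>") else
          paste(v, collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

#' Run the full analysis pipeline
#'
#' Normalization, tICA, K-means discretization, reversible MSM, macrostate
#' lumping, populations, free energies and (optionally) trajectory
#' bootstrap, in one configured pass.  Every stage's artifact is retained in
#' the returned bundle; a rerun with identical config and inputs is
#' bit-identical because every seed is explicit.
#'
#' @param trajs list of [feature_traj()].
#' @param config a [pipeline_config()].
#' @param ref_labels optional list of per-frame reference macrostate labels
#'   (frame-aligned with `trajs`); required when
#'   `config$macrostates == "reference_labels"`.
#' @return object of class `pipeline_result`: `config`, `normalization`,
#'   `tica`, `cluster_model`, `dtrajs`, `msm`, `macro_map`, `populations`,
#'   `free_energies`, `bootstrap`, `log`.
#' @export
run_pipeline <- function(trajs, config = pipeline_config(),
                         ref_labels = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.list(trajs) || length(trajs) == 0L)
    stop("empty trajectory list")
  xs <- as_feature_list(trajs)
  dt <- attr(xs, "dt")
  if (is.na(dt)) stop("trajectories must carry a frame interval dt")
  validate_config(config, dt = dt)
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))
  note("input: ", length(xs), " trajectories, ",
       sum(vapply(xs, nrow, 1L)), " frames, d = ", ncol(xs[[1L]]),
       ", dt = ", dt, " ns")

  norm <- NULL
  if (config$normalize) {
    norm <- normalize_features(trajs)
    trajs <- norm$trajs
    note("normalized features (", sum(norm$constant), " constant columns)")
  }
  tic <- tica(trajs, lag_ns = config$tica_lag_ns,
              n_components = config$n_components,
              kinetic_mapping = config$kinetic_mapping,
              shrinkage = config$shrinkage)
  note("tICA: top eigenvalues ",
       paste(signif(head(tic$eigenvalues, config$n_components), 4),
             collapse = " "))
  proj <- predict(tic, trajs)
  km <- kmeans_discretize(proj, config$n_clusters, seed = config$cluster_seed)
  note("k-means: k = ", config$n_clusters, ", inertia = ",
       signif(km$model$inertia, 6))
  msm_lag <- as.integer(round(config$msm_lag_ns / dt))
  m <- markov_model(km$dtrajs, msm_lag, dt = dt, tol = config$msm_tol)
  note("msm: ", length(m$active), "/", config$n_clusters,
       " states active, timescales (ns) ",
       paste(signif(head(m$timescales, 3), 4), collapse = " "))

  macro_map <- NULL
  populations <- NULL
  G <- NULL
  boot <- NULL
  if (identical(config$macrostates, "reference_labels")) {
    if (is.null(ref_labels))
      stop("config requests reference-label macrostates but ref_labels missing")
    macro_map <- macrostates_from_labels(km$dtrajs, ref_labels,
                                         n_states = config$n_clusters)
  } else if (is.list(config$macrostates)) {
    macro_map <- assign_macrostates(km$model, config$macrostates)
  }
  if (!is.null(macro_map)) {
    populations <- macrostate_populations(m, macro_map)
    G <- free_energies(populations, temperature = config$temperature)
    note("populations: ",
         paste(names(populations), signif(populations, 4), collapse = ", "))
    if (config$bootstrap_rounds > 0L) {
      boot <- bootstrap_observables(
        km$dtrajs, msm_lag,
        observables = list(pop = obs_populations(macro_map)),
        n_rounds = config$bootstrap_rounds, seed = config$bootstrap_seed,
        dt = dt, n_states = config$n_clusters)
      note("bootstrap: ", attr(boot, "n_skipped"), " rounds skipped")
    }
  }
  structure(list(config = config, normalization = norm, tica = tic,
                 cluster_model = km$model, dtrajs = km$dtrajs, msm = m,
                 macro_map = macro_map, populations = populations,
                 free_energies = G, bootstrap = boot, log = log),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(paste0("  ", x$log, "\n"), sep = "")
  invisible(x)
}

#' Compare two ensembles on a shared discretization
#'
#' Fits tICA and K-means on the pooled data, estimates a separate MSM per
#' ensemble on the shared microstates, and reports per-macrostate
#' populations, free energies and `ddG = G_b - G_a`, with both ensembles'
#' free energies referenced to ensemble A's highest-populated macrostate
#' (the single-set-of-state-definitions convention that makes relative free
#' energies directly comparable).  A macrostate absent from one ensemble
#' after trimming yields `NA` for its `ddG`.
#'
#' @param trajs_a,trajs_b feature-trajectory lists, featurized identically.
#' @param config a [pipeline_config()].
#' @param ref_labels_a,ref_labels_b reference macrostate labels when the
#'   config uses `"reference_labels"`.
#' @return object of class `ensemble_comparison`: `tica`, `cluster_model`,
#'   `macro_map`, `msm_a`, `msm_b`, `populations` (list a/b),
#'   `free_energies` (list a/b, shared reference), `ddG`.
#' @export
compare_ensembles <- function(trajs_a, trajs_b, config = pipeline_config(),
                              ref_labels_a = NULL, ref_labels_b = NULL) {
  xa <- as_feature_list(trajs_a)
  xb <- as_feature_list(trajs_b)
  if (ncol(xa[[1L]]) != ncol(xb[[1L]]))
    stop("ensembles must be featurized identically")
  dt <- attr(xa, "dt")
  validate_config(config, dt = dt)
  pooled <- c(trajs_a, trajs_b)
  norm <- NULL
  if (config$normalize) {
    norm <- normalize_features(pooled)
    pooled <- norm$trajs
    na <- length(trajs_a)
    trajs_a <- pooled[seq_len(na)]
    trajs_b <- pooled[-seq_len(na)]
  }
  tic <- tica(pooled, lag_ns = config$tica_lag_ns,
              n_components = config$n_components,
              kinetic_mapping = config$kinetic_mapping,
              shrinkage = config$shrinkage)
  km <- kmeans_discretize(predict(tic, pooled), config$n_clusters,
                          seed = config$cluster_seed)
  na <- length(trajs_a)
  dtr_a <- km$dtrajs[seq_len(na)]
  dtr_b <- km$dtrajs[-seq_len(na)]
  attr(dtr_a, "dt") <- dt; attr(dtr_b, "dt") <- dt
  msm_lag <- as.integer(round(config$msm_lag_ns / dt))
  m_a <- markov_model(dtr_a, msm_lag, dt = dt, n_states = config$n_clusters,
                      tol = config$msm_tol)
  m_b <- markov_model(dtr_b, msm_lag, dt = dt, n_states = config$n_clusters,
                      tol = config$msm_tol)
  macro_map <- if (identical(config$macrostates, "reference_labels")) {
    if (is.null(ref_labels_a) || is.null(ref_labels_b))
      stop("reference labels required for both ensembles")
    macrostates_from_labels(km$dtrajs, c(ref_labels_a, ref_labels_b),
                            n_states = config$n_clusters)
  } else if (is.list(config$macrostates)) {
    assign_macrostates(km$model, config$macrostates)
  } else stop("compare_ensembles requires a macrostate rule")
  pops <- function(m) {
    p <- macrostate_populations(m, macro_map)
    p[setdiff(unique(macro_map), names(p))] <- NA_real_
    p[sort(names(p))]
  }
  p_a <- pops(m_a); p_b <- pops(m_b)
  ref_state <- names(p_a)[which.max(p_a)]
  g_a <- free_energies(p_a, config$temperature, reference = ref_state)
  g_b <- free_energies(p_b, config$temperature,
                       reference = p_a[[ref_state]])
  ddG <- g_b - g_a
  structure(list(tica = tic, cluster_model = km$model, macro_map = macro_map,
                 msm_a = m_a, msm_b = m_b,
                 populations = list(a = p_a, b = p_b),
                 free_energies = list(a = g_a, b = g_b),
                 reference_state = ref_state, ddG = ddG),
            class = "ensemble_comparison")
}

#' @export
print.ensemble_comparison <- function(x, ...) {
  cat("<ensemble_comparison> reference:", x$reference_state, "\n")
  out <- rbind(pop_a = x$populations$a, pop_b = x$populations$b,
               ddG = x$ddG)
  print(signif(out, 3))
  invisible(x)
}

#' Per-frame MSM stationary weights
#'
#' The unbiased reweighting for MSM-weighted surfaces: each frame carries
#' `pi(state) / count(state)` of its assigned microstate, so each
#' microstate's total weight equals its stationary probability.
#'
#' @param model an `msm`.
#' @param dtrajs list of integer microstate trajectories.
#' @return list of per-frame weight vectors (frames in trimmed-away states
#'   get weight 0).
#' @export
frame_weights <- function(model, dtrajs) {
  n_states <- max(vapply(dtrajs, max, 1L), model$active)
  w_state <- rep(0, n_states)
  cnt <- table(factor(unlist(dtrajs), levels = seq_len(n_states)))
  w_state[model$active] <- model$stationary / pmax(1, as.numeric(cnt)[model$active])
  lapply(dtrajs, function(s) w_state[s])
}

#' Two-dimensional free-energy surface
#'
#' Weighted 2-D histogram over the first two projection coordinates with
#' `G(bin) = -kT log(w(bin) / w_ref)`; the reference weight defaults to the
#' maximum-weight bin, putting the surface minimum at 0.  Empty bins are
#' `NA`, not 0.  For cross-ensemble comparisons, pass the reference
#' ensemble's maximum bin weight as `ref_weight` so both surfaces share one
#' zero.
#'
#' @param projections list of projected [feature_traj()] or matrices
#'   (>= 2 columns; first two used).
#' @param weights list of per-frame weights (e.g. from [frame_weights()]);
#'   default uniform.
#' @param bins number of bins per axis (default 50).
#' @param temperature Kelvin.
#' @param ref_weight reference bin weight; default the surface's own max.
#' @param xlim,ylim axis ranges; default the data range.
#' @return list with `G` (bins x bins matrix, kcal/mol), `x`, `y` (bin
#'   midpoints), `weight` (bin weights), `ref_weight`.
#' @export
fes_histogram <- function(projections, weights = NULL, bins = 50L,
                          temperature = 300, ref_weight = NULL,
                          xlim = NULL, ylim = NULL) {
  xs <- lapply(as_feature_list(projections), function(m) m[, 1:2, drop = FALSE])
  X <- do.call(rbind, xs)
  w <- if (is.null(weights)) rep(1, nrow(X)) else unlist(weights)
  stopifnot(length(w) == nrow(X))
  if (all(w == 0)) stop("all frame weights are zero")
  xlim <- xlim %||% range(X[, 1L])
  ylim <- ylim %||% range(X[, 2L])
  bx <- seq(xlim[1L], xlim[2L], length.out = bins + 1L)
  by <- seq(ylim[1L], ylim[2L], length.out = bins + 1L)
  ix <- pmin(pmax(findInterval(X[, 1L], bx, all.inside = TRUE), 1L), bins)
  iy <- pmin(pmax(findInterval(X[, 2L], by, all.inside = TRUE), 1L), bins)
  W <- matrix(0, bins, bins)
  agg <- rowsum(w, group = (iy - 1L) * bins + ix)
  W[as.integer(rownames(agg))] <- agg
  if (is.null(ref_weight)) ref_weight <- max(W)
  if (ref_weight <= 0) stop("all-empty histogram")
  G <- -kT(temperature) * log(W / ref_weight)
  G[W == 0] <- NA_real_
  list(G = G, x = (bx[-1L] + head(bx, -1L)) / 2,
       y = (by[-1L] + head(by, -1L)) / 2, weight = W, ref_weight = ref_weight)
}
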