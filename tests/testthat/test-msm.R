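# Discretization, counting, reversible MLE, spectrum, macrostates, CV.

test_that("k-means++ discretization separates blobs and is deterministic", {
  set.seed(41)
  centers_true <- rbind(c(0, 0), c(10, 0), c(0, 10))
  X <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(400, sd = 0.5), 200, 2), 2, -centers_true[k, ])))
  km <- kmeans_discretize(list(X), 3, seed = 1)
  lab <- assign_clusters(km$model, X)
  truth <- rep(1:3, each = 200)
  # each blob maps to exactly one cluster
  expect_equal(length(unique(paste(truth, lab))), 3)
  # inertia equals the within-blob sum under brute-force assignment
  inertia_oracle <- sum(vapply(1:3, function(k) {
    pts <- X[lab == k, , drop = FALSE]
    sum(sweep(pts, 2, colMeans(pts))^2)
  }, 0))
  expect_equal(km$model$inertia, inertia_oracle, tolerance = 1e-8)
  # determinism and error contracts
  km2 <- kmeans_discretize(list(X), 3, seed = 1)
  expect_identical(km$dtrajs, km2$dtrajs)
  expect_error(kmeans_discretize(list(X), 1, seed = 1), "n_clusters")
  expect_error(kmeans_discretize(list(X[1:2, ]), 3, seed = 1), "fewer")
})

test_that("sliding-window counts match hand enumeration", {
  expect_equal(count_transitions(list(c(1, 2, 1, 2)), 1),
               rbind(c(0, 2), c(1, 0)), ignore_attr = TRUE)
  # lag 2 on [1,2,1,2]: pairs (1,1) and (2,2) only
  expect_equal(count_transitions(list(c(1, 2, 1, 2)), 2),
               oracle_counts(list(c(1, 2, 1, 2)), 2, 2), ignore_attr = TRUE)
  expect_equal(count_transitions(list(c(1, 2, 1, 2)), 2),
               rbind(c(1, 0), c(0, 1)), ignore_attr = TRUE)
  # constant trajectory: single diagonal entry L - 1
  expect_equal(count_transitions(list(rep(2L, 7)), 1, n_states = 2),
               rbind(c(0, 0), c(0, 6)), ignore_attr = TRUE)
  # random trajectories against the explicit pair-enumeration oracle
  set.seed(3)
  dtr <- lapply(1:4, function(i) sample.int(5, 50, replace = TRUE))
  for (lag in c(1, 3, 7)) {
    expect_equal(count_transitions(dtr, lag, n_states = 5),
                 oracle_counts(dtr, lag, 5), ignore_attr = TRUE)
  }
  # pairs never cross trajectory boundaries
  a <- c(1L, 1L); b <- c(2L, 2L)
  C_split <- count_transitions(list(a, b), 1, n_states = 2)
  C_concat <- count_transitions(list(c(a, b)), 1, n_states = 2)
  expect_equal(sum(C_split), 2)
  expect_equal(sum(C_concat), 3)
  expect_error(count_transitions(list(c(1L, 2L)), 5), "no transition")
})

test_that("ergodic trim keeps the largest strongly connected component", {
  # block diagonal 3 + 2: larger block retained
  C <- matrix(0, 5, 5)
  C[1:3, 1:3] <- 1; C[4:5, 4:5] <- 1
  tr <- ergodic_trim(C)
  expect_equal(tr$active, 1:3)
  # fully connected counts: identity operation
  C2 <- matrix(1, 4, 4)
  expect_equal(ergodic_trim(C2)$active, 1:4)
  # one-way edge: the SCCs split as in the textbook algorithm
  C3 <- rbind(c(1, 1), c(0, 1))
  tr3 <- ergodic_trim(C3)
  expect_equal(length(tr3$active), 1)
  # random sparse counts match the Kosaraju oracle
  set.seed(7)
  for (rep in 1:10) {
    C <- matrix(rbinom(49, 1, 0.25), 7, 7)
    keep <- which(rowSums(C) + colSums(C) > 0)
    if (!length(keep)) next
    comp <- oracle_scc(C[keep, keep, drop = FALSE] > 0)
    sizes <- table(comp)
    tr <- ergodic_trim(C)
    expect_equal(length(tr$active), max(sizes))
    # the trimmed set is one oracle component
    expect_equal(length(unique(comp[match(tr$active, keep)])), 1)
  }
  expect_error(ergodic_trim(matrix(0, 3, 3)), "all-zero")
})

test_that("reversible MLE reproduces closed forms and satisfies detailed balance", {
  # symmetric counts: T is exactly the row-normalized count matrix
  C <- rbind(c(8, 2), c(2, 8))
  fit <- mle_reversible(C)
  expect_equal(fit$transition_matrix, rbind(c(0.8, 0.2), c(0.2, 0.8)),
               tolerance = 1e-12)
  expect_equal(fit$stationary, c(0.5, 0.5), tolerance = 1e-12)
  set.seed(19)
  Cs <- matrix(rpois(16, 20), 4); Cs <- Cs + t(Cs)
  fit <- mle_reversible(Cs)
  expect_equal(fit$transition_matrix, Cs / rowSums(Cs), tolerance = 1e-9)

  # asymmetric counts: detailed balance to 1e-8, and the reversible MLE
  # beats the symmetrized row-normalization competitor in likelihood
  set.seed(23)
  for (rep in 1:5) {
    C <- matrix(rpois(25, 8) * matrix(rbinom(25, 1, 0.8), 5), 5)
    diag(C) <- diag(C) + 5  # keep connected-ish
    C <- ergodic_trim(C)$counts
    if (nrow(C) < 2) next
    fit <- mle_reversible(C)
    flux <- fit$stationary * fit$transition_matrix
    expect_lt(max(abs(flux - t(flux))), 1e-8)
    expect_lt(max(abs(rowSums(fit$transition_matrix) - 1)), 1e-10)
    Tsym <- (C + t(C)) / rowSums(C + t(C))
    ll <- function(Tm) sum(C[C > 0] * log(Tm[C > 0]))
    expect_gte(ll(fit$transition_matrix), ll(Tsym) - 1e-9)
  }
  expect_error(mle_reversible(rbind(c(1, 0), c(0, 0))), "empty")
})

test_that("estimator is consistent for data from a ground-truth chain", {
  ch <- toy_chain(4, seed = 5)
  labs <- sample_discrete(ch, 2.5e5, 4, seed = 6)
  m <- markov_model(labs, 1, dt = ch$dt)
  expect_lt(max(abs(m$transition_matrix - ch$transition_matrix)), 0.02)
  expect_lt(max(abs(m$stationary - ch$stationary)), 0.02)
  # free energies reproduce generator free energies (up to the reference)
  G_hat <- free_energies(m$stationary, reference = NULL)
  G_true <- ch$free_energies - min(ch$free_energies)
  expect_equal(unname(G_hat - min(G_hat)), unname(G_true), tolerance = 0.05)
})

test_that("spectral decomposition matches 2x2 arithmetic and Boltzmann", {
  dtr <- NULL
  Tm <- rbind(c(0.9, 0.1), c(0.1, 0.9))
  sp <- kinemsm:::spectral_decompose_matrix(Tm, c(0.5, 0.5), lag_ns = 80)
  expect_equal(sp$eigenvalues, c(1, 0.8), tolerance = 1e-12)
  expect_equal(sp$timescales[1], 80 / log(1.25), tolerance = 1e-12)
  expect_equal(sp$timescales[1], 358.5, tolerance = 1e-3)
  # stationary eigenvector of a fixture chain equals Boltzmann pi
  ch <- btk()$asp
  sp2 <- kinemsm:::spectral_decompose_matrix(ch$transition_matrix,
                                             ch$stationary, 80)
  expect_equal(sp2$eigenvalues[1], 1, tolerance = 1e-10)
  # timescales decrease with index
  expect_true(all(diff(sp2$timescales) < 0))
})

test_that("implied timescales are flat for Markov data and clean for degenerate input", {
  # slow, well-metastable 3-state chain so eigenvalues stay well-resolved
  # at every scanned lag
  B <- matrix(Inf, 3, 3)
  B[1, 2] <- B[2, 1] <- 2.0; B[2, 3] <- B[3, 2] <- 2.2; B[1, 3] <- B[3, 1] <- 2.4
  ch <- build_kinase_chain(c(0, 0.2, -0.1), B, dt = 1, rate_scale = 1)
  labs <- sample_discrete(ch, 1e5, 4, seed = 10)
  scan <- implied_timescale_scan(labs, lags = c(1, 2, 4), n_timescales = 2,
                                 dt = 1)
  top <- scan$timescale[scan$index == 1]
  # exact Markov chain: flat within sampling error
  expect_lt(max(abs(top - mean(top))) / mean(top), 0.1)
  expect_equal(attr(scan, "suggested_lag"), 2)

  # discretizing a continuous AR(1) process gives lag-increasing timescales
  x <- sample_ar1(ar1_spec(50, dt = 1), 2e5, seed = 12)$values[, 1]
  dtr <- list(ifelse(x > 0, 1L, 2L))
  scan2 <- implied_timescale_scan(dtr, lags = c(1, 5, 15), n_timescales = 1,
                                  dt = 1)
  expect_true(all(diff(scan2$timescale) > 0))

  # single-state data: no finite timescales, clean report
  scan3 <- implied_timescale_scan(list(rep(1L, 100)), lags = c(1, 2),
                                  n_timescales = 2, dt = 1)
  expect_equal(nrow(scan3), 0)
})

test_that("macrostate rules partition, propagate labels, and sum populations", {
  centers <- rbind(c(-2, 0), c(2, 0), c(2, 3))
  rules <- list(left = function(C) C[, 1] < 0,
                right = function(C) C[, 1] >= 0)
  map <- assign_macrostates(centers, rules)
  expect_equal(unname(map), c("left", "right", "right"))
  # single rule matching everything
  map1 <- assign_macrostates(centers, list(all = function(C) rep(TRUE, nrow(C))))
  expect_true(all(map1 == "all"))
  # overlapping and non-covering rules are errors listing offenders
  expect_error(assign_macrostates(centers,
                                  list(a = function(C) C[, 1] < 3,
                                       b = function(C) C[, 1] > -3)),
               "partition")
  expect_error(assign_macrostates(centers,
                                  list(none = function(C) C[, 1] > 99)),
               "partition")

  # label propagation: majority generator label per microstate
  ch <- btk()$asp
  micro <- expand_chain(ch)
  labs <- sample_discrete(micro, 2000, 40, seed = 31)
  ft <- emit_features(labs, default_emission_spec(micro), seed = 32)
  km <- kmeans_discretize(lapply(ft, function(t) t$values[, 1:3]), 12,
                          seed = 33)
  ref <- lapply(labs, function(s) micro$macro_labels[s])
  map <- macrostates_from_labels(km$dtrajs, ref, n_states = 12)
  # every macrostate present and each cluster's frames dominated by its label
  expect_setequal(unique(na.omit(map)), unique(micro$macro_labels))

  # populations: identity map returns pi; sums to 1
  m <- markov_model(km$dtrajs, 1, dt = micro$dt)
  pops <- macrostate_populations(m, map)
  expect_equal(sum(pops), 1, tolerance = 1e-12)
  ident_map <- sprintf("s%02d", seq_len(12))
  p_ident <- macrostate_populations(m, ident_map)
  expect_equal(unname(p_ident[ident_map[m$active]]), unname(m$stationary),
               tolerance = 1e-12)
})

test_that("free energies follow the Boltzmann relation and its invariances", {
  expect_equal(unname(free_energies(c(a = 0.3, b = 0.3))[["a"]]), 0)
  G <- free_energies(c(x = 0.01, ref = 0.52), reference = "ref")
  expect_equal(unname(G[["x"]]), -kT(300) * log(0.01 / 0.52))
  expect_equal(unname(G[["x"]]), 2.35, tolerance = 0.01)
  # scaling all populations leaves differences unchanged
  p <- c(a = 0.2, b = 0.5, c = 0.3)
  G1 <- free_energies(p); G2 <- free_energies(p * 7)
  expect_equal(diff(G1), diff(G2), tolerance = 1e-12)
  # zero population: infinite marker, not an exception
  expect_identical(unname(free_energies(c(a = 0, b = 1))[["a"]]), Inf)
})

test_that("cross-validation scores penalize under-splitting and shuffled data", {
  ch <- btk()$asp
  micro <- expand_chain(ch)
  labs <- sample_discrete(micro, 1500, 12, seed = 51)
  ft <- emit_features(labs, small_emission(micro, d = 6, separation = 12,
                                           sd = 0.3), seed = 52)
  grid1 <- data.frame(tica_lag = 3, n_components = 3, kinetic_mapping = TRUE,
                      n_clusters = 12)
  cv1 <- cross_validate_msm(ft, grid1, msm_lag = 1, n_folds = 2,
                            n_timescales = 3, seed = 1)
  expect_equal(cv1$best, grid1, ignore_attr = TRUE)

  grid <- data.frame(tica_lag = 3, n_components = 3, kinetic_mapping = TRUE,
                     n_clusters = c(2, 12))
  cv <- cross_validate_msm(ft, grid, msm_lag = 1, n_folds = 2,
                           n_timescales = 3, seed = 1)
  s2 <- cv$scores$mean_score[cv$scores$n_clusters == 2]
  s12 <- cv$scores$mean_score[cv$scores$n_clusters == 12]
  expect_gte(s12, s2)
  expect_equal(cv$best$n_clusters, 12)

  # shuffling frames in time destroys autocorrelation: scores collapse to ~1
  set.seed(53)
  shuf <- lapply(ft, function(t)
    feature_traj(t$values[sample.int(nrow(t$values)), ], dt = t$dt))
  cvs <- cross_validate_msm(shuf, grid1, msm_lag = 1, n_folds = 2,
                            n_timescales = 3, seed = 1)
  expect_lt(cvs$scores$mean_score, s12)
  expect_lt(abs(cvs$scores$mean_score - 1), 0.35)
})
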