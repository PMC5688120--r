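# Shared fixtures, built once per test run.

# Calibrated BTK chains (deterministic; ~1 s).
btk <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- calibrate_btk_chains()
    cache
  }
})

dfg_in_states <- c("active", "intermediate", "src_like")

# A small well-mixed reversible chain for estimator tests.
toy_chain <- function(n = 3, seed = 1, dt = 1) {
  set.seed(seed)
  G <- runif(n, -1, 1)
  B <- matrix(Inf, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    B[i, j] <- B[j, i] <- max(G[i], G[j]) + runif(1, 0.3, 1.2)
  }
  build_kinase_chain(G, B, dt = dt)
}

# Low-dimensional, high-SNR emission spec for speed-sensitive tests.
small_emission <- function(chain, d = 6, separation = 12, sd = 1,
                           noise_dims = 0) {
  n <- nrow(chain$transition_matrix)
  means <- matrix(0, n, d)
  for (i in seq_len(n)) means[i, 1 + (i - 1) %% d] <- separation * i / n
  means[, d] <- seq_len(n)  # guarantee distinct rows
  emission_spec(means, sd = sd, noise_dims = noise_dims)
}
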