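# Shared fixtures: reduced grids and an independent dense-solve GP oracle.

# Small two-parameter grid (one free numeric, one contextual) for tests that
# enumerate or brute-force the search space.
tiny_grid <- function(n_free = 25L, ctx_levels = seq(5, 23, by = 3)) {
  search_grid(list(
    parameter_spec("A", "free knob", "numeric-grid",
                   seq(0, 1, length.out = n_free)),
    parameter_spec("DP", "context knob", "contextual-grid", ctx_levels, "min")
  ))
}

# Grid with a wide contextual range so both down- and up-shifted windows stay
# in range (for probing the context decision rule).
wide_ctx_grid <- function() {
  search_grid(list(
    parameter_spec("A", "free knob", "numeric-grid", seq(0, 1, by = 0.25)),
    parameter_spec("DP", "context knob", "contextual-grid",
                   seq(2, 29, by = 3), "min")
  ))
}

# Independent GP oracle: plain-loop kernel, direct solve(), no Cholesky, no
# package internals. Latent (noise-free) posterior sd, matching posterior().
ref_gp_posterior <- function(X, y, Xstar, lengthscales, signal_variance,
                             noise_variance, prior_mean, jitter = 1e-8) {
  kern <- function(a, b) {
    signal_variance * exp(-0.5 * sum(((a - b) / lengthscales)^2))
  }
  n <- nrow(X)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) K[i, j] <- kern(X[i, ], X[j, ])
  Kinv <- solve(K + diag(noise_variance + jitter, n))
  w <- Kinv %*% (y - prior_mean)
  out <- matrix(0, nrow(Xstar), 2, dimnames = list(NULL, c("mean", "sd")))
  for (q in seq_len(nrow(Xstar))) {
    ks <- vapply(seq_len(n), function(i) kern(Xstar[q, ], X[i, ]), numeric(1))
    out[q, "mean"] <- prior_mean + sum(ks * w)
    v <- signal_variance - drop(t(ks) %*% Kinv %*% ks)
    out[q, "sd"] <- sqrt(max(v, 0))
  }
  out
}

# Random observation set on a grid, seeded.
random_observations <- function(grid, n, seed, scores = NULL) {
  cond <- sample_uniform(grid, n, seed = seed, window = NULL)
  if (is.null(scores)) {
    scores <- withr::with_seed(seed + 1L, runif(n, 0.1, 0.9))
  }
  observation_set(cond, scores, round = "1", plate = 1L, well = seq_len(n),
                  grid = grid)
}
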