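one_point_cfg <- function() {
  surrogate_config(noise_variance = 0.0039, lengthscales = 1,
                   signal_variance = 1, prior_mean = 0, optimize = FALSE,
                   jitter = 0)
}

test_that("single-observation posterior matches the 1x1 closed form", {
  g <- default_search_grid()
  x0 <- data.frame(PC = 250, PP = 3, DP = 14, DS = 50, DL = "long",
                   KP = 10, "3P" = 10, check.names = FALSE)
  D <- observation_set(x0, score = 0.8, grid = g)
  s <- fit_surrogate(D, g, one_point_cfg())
  p <- posterior(s, x0)
  # k (K + sigma^2)^-1 y with k = K = 1
  expect_equal(p$mean, 0.8 / 1.0039, tolerance = 1e-9)
  expect_equal(p$sd, sqrt(1 - 1 / 1.0039), tolerance = 1e-9)
  # shrinkage bound at a noisy training point
  expect_lt(abs(p$mean - 0.8), 0.8 * 0.0039 / 1 + 1e-9)
})

test_that("posterior reverts to the prior far from all data", {
  g <- default_search_grid()
  corner <- data.frame(PC = 0, PP = 1, DP = 5, DS = 10, DL = "short",
                       KP = 1, "3P" = 3, check.names = FALSE)
  far <- data.frame(PC = 505, PP = 6, DP = 23, DS = 100, DL = "long",
                    KP = 19, "3P" = 19, check.names = FALSE)
  cfg <- surrogate_config(lengthscales = 0.05, signal_variance = 0.5,
                          prior_mean = 0.3, optimize = FALSE)
  s <- fit_surrogate(observation_set(corner, 0.9, grid = g), g, cfg)
  p <- posterior(s, far)
  expect_equal(p$mean, 0.3, tolerance = 1e-6)
  expect_equal(p$sd, sqrt(0.5), tolerance = 1e-6)
  # information monotonicity: sd at the training site < sd at the far corner
  expect_lt(posterior(s, corner)$sd, p$sd)
})

test_that("posterior is invariant to permutation of the training set", {
  g <- default_search_grid()
  D <- random_observations(g, 15, seed = 3)
  cfg <- surrogate_config(lengthscales = 0.4, signal_variance = 0.2,
                          prior_mean = 0.5, optimize = FALSE)
  perm <- withr::with_seed(9, sample.int(nrow(D)))
  s1 <- fit_surrogate(D, g, cfg)
  s2 <- fit_surrogate(D[perm, ], g, cfg)
  test <- sample_uniform(g, 25, seed = 5, window = NULL)
  p1 <- posterior(s1, test)
  p2 <- posterior(s2, test)
  expect_lt(max(abs(p1$mean - p2$mean)), 1e-8)
  expect_lt(max(abs(p1$sd - p2$sd)), 1e-8)
})

test_that("posterior agrees with an independent dense-solve oracle", {
  g <- default_search_grid()
  for (n in c(3, 7, 12, 20)) {
    D <- random_observations(g, n, seed = n)
    ls <- withr::with_seed(n + 50L, runif(7, 0.1, 1))
    sv <- withr::with_seed(n + 60L, runif(1, 0.05, 1))
    cfg <- surrogate_config(lengthscales = ls, signal_variance = sv,
                            prior_mean = 0.4, optimize = FALSE)
    s <- fit_surrogate(D, g, cfg)
    test <- sample_uniform(g, 10, seed = n + 70L, window = NULL)
    p <- posterior(s, test)
    ref <- ref_gp_posterior(encode_conditions(D[g$codes], g), D$score,
                            encode_conditions(test, g),
                            ls, sv, 0.0039, 0.4)
    expect_lt(max(abs(p$mean - ref[, "mean"])), 1e-6)
    expect_lt(max(abs(p$sd - ref[, "sd"])), 1e-6)
  }
})

test_that("kernel Gram matrices are symmetric positive semi-definite", {
  g <- default_search_grid()
  X <- encode_conditions(sample_uniform(g, 40, seed = 2, window = NULL), g)
  K <- rpeopt:::ard_rbf(X, X, rep(0.3, 7), 1.5)
  expect_equal(K, t(K), tolerance = 1e-12)
  expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
})

test_that("ML-II never degrades the log marginal likelihood", {
  g <- default_search_grid()
  D <- random_observations(g, 25, seed = 13)
  init <- list(lengthscales = 0.3, signal_variance = 0.05)
  s0 <- fit_surrogate(D, g, surrogate_config(
    lengthscales = init$lengthscales, signal_variance = init$signal_variance,
    optimize = FALSE))
  s1 <- fit_surrogate(D, g, surrogate_config(
    lengthscales = init$lengthscales, signal_variance = init$signal_variance,
    restarts = 3, seed = 4))
  expect_gte(s1$lml, s0$lml - 1e-8)
})

test_that("infinite noise collapses the posterior onto the prior mean", {
  g <- default_search_grid()
  D <- random_observations(g, 10, seed = 21)
  cfg <- surrogate_config(noise_variance = 1e6, lengthscales = 0.3,
                          signal_variance = 1, prior_mean = 0.5,
                          optimize = FALSE)
  s <- fit_surrogate(D, g, cfg)
  p <- posterior(s, sample_uniform(g, 20, seed = 22, window = NULL))
  expect_lt(max(abs(p$mean - 0.5)), 1e-4)
})

test_that("degenerate observation sets are handled as specified", {
  g <- default_search_grid()
  D <- random_observations(g, 5, seed = 31)
  expect_error(fit_surrogate(D[0, ], g), "no observations")
  D$score[2] <- NA
  expect_warning(s <- fit_surrogate(D, g, one_point_cfg()), "unscored")
  expect_length(s$y, 4)
  # duplicate (x, y) rows are permitted: the noise model absorbs them
  dup <- rbind(D[1, ], D[1, ])
  dup$well <- 1:2
  expect_silent(fit_surrogate(dup, g, one_point_cfg()))
})

test_that("observation tables round-trip through the CSV schema", {
  g <- default_search_grid()
  D <- random_observations(g, 6, seed = 41)
  D$score[3] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  write_observations(D, path, g)
  header <- readLines(path, n = 1)
  expect_match(header, "PC_nM,PP_day,DP_min,DS_mm_s,DL,KP_day,P3_day,score")
  D2 <- read_observations(path, g)
  expect_equal(D2[names(D)], D, ignore_attr = TRUE)
  # duplicate slot keys are rejected
  D$well <- 1L
  expect_error(validate_observations(D, g), "duplicate")
})
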