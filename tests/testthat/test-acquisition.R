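test_that("expected improvement matches its closed form and a MC oracle", {
  expect_equal(expected_improvement(0.4, 0, 0.5), 0)
  expect_equal(expected_improvement(0.6, 0, 0.5), 0.1)
  # mean at the incumbent: EI = sd / sqrt(2*pi)
  expect_equal(expected_improvement(0.5, 0.1, 0.5), 0.1 / sqrt(2 * pi),
               tolerance = 1e-12)
  mc <- withr::with_seed(1, {
    y <- rnorm(1e6, 0.5, 0.1)
    imp <- pmax(y - 0.5, 0)
    c(mean(imp), sd(imp) / sqrt(1e6))
  })
  expect_lt(abs(expected_improvement(0.5, 0.1, 0.5) - mc[1]), 3 * mc[2])
  # non-negativity over random inputs
  vals <- withr::with_seed(2, expected_improvement(runif(100), runif(100),
                                                   runif(100)))
  expect_true(all(vals >= 0))
})

test_that("softplus utility transform preserves the argmax", {
  a <- withr::with_seed(3, runif(500, 0, 0.2))
  expect_identical(which.max(rpeopt:::softplus(a)), which.max(a))
})

test_that("Lipschitz estimate floors at 1e-4 for a flat posterior", {
  g <- default_search_grid()
  x0 <- sample_uniform(g, 1, seed = 1, window = NULL)
  # score equal to the prior mean: zero shrinkage, constant posterior mean
  D <- observation_set(x0, 0.5, grid = g)
  s <- fit_surrogate(D, g, surrogate_config(
    lengthscales = 0.5, signal_variance = 1, prior_mean = 0.5,
    optimize = FALSE))
  L <- estimate_lipschitz(s, g, seed = 2)
  expect_s3_class(L, "lipschitz_estimate")
  expect_equal(L$value, 1e-4)
})

test_that("Lipschitz estimate recovers the slope of a linear response", {
  grid <- tiny_grid(n_free = 41L, ctx_levels = 5)
  a <- 0.5
  cond <- data.frame(A = grid$specs$A$levels, DP = 5)
  D <- observation_set(cond, a * cond$A, plate = 1, well = seq_len(nrow(cond)),
                       grid = grid)
  s <- fit_surrogate(D, grid, surrogate_config(restarts = 3, seed = 1))
  L <- estimate_lipschitz(s, grid, seed = 3)
  expect_lt(abs(L$value - a), 0.2 * a)
  # seeded determinism
  L2 <- estimate_lipschitz(s, grid, seed = 3)
  expect_identical(L$value, L2$value)
})

test_that("local penalizer matches the normal-CDF formula exactly", {
  g <- default_search_grid()
  D <- random_observations(g, 10, seed = 5)
  s <- fit_surrogate(D, g, surrogate_config(lengthscales = 0.4,
                                            signal_variance = 0.3,
                                            optimize = FALSE))
  x <- sample_uniform(g, 20, seed = 6, window = NULL)
  center <- sample_uniform(g, 1, seed = 7, window = NULL)
  L <- 1.7
  M <- max(D$score)
  got <- local_penalizer(x, center, L, M, s)
  pc <- posterior(s, center)
  d <- sqrt(rowSums(sweep(encode_conditions(x, g), 2,
                          encode_conditions(center, g)[1, ])^2))
  want <- pnorm((L * d - M + pc$mean) / (sqrt(2) * max(pc$sd, 1e-6)))
  expect_equal(got, want, tolerance = 1e-10)
  expect_true(all(got > 0 & got <= 1))
  # smallest at the center itself
  expect_true(all(local_penalizer(center, center, L, M, s) <= got))
  # far-field limit: no penalty
  expect_gt(min(local_penalizer(x, center, 1e3, M, s)), 1 - 1e-6)
})

test_that("generate_batch fills the plate-well geometry with the context", {
  g <- default_search_grid()
  w <- context_window(c(5, 8, 11, 14, 17, 20))
  D <- observation_set(sample_uniform(g, 48, seed = 1, window = w),
                       withr::with_seed(2, runif(48, 0.1, 0.6)),
                       plate = rep(1:8, each = 6), well = rep(1:6, 8), grid = g)
  s <- fit_surrogate(D, g, surrogate_config(restarts = 2, seed = 1))
  cfg <- policy_config(candidate_pool = 300, seed = 9)
  plan <- generate_batch(s, g, w, cfg, D)
  expect_equal(nrow(plan), 48)
  expect_setequal(paste(plan$plate, plan$well),
                  paste(rep(1:8, each = 6), rep(1:6, 8)))
  expect_silent(assert_on_grid(plan[g$codes], g))
  expect_equal(plan$DP, unclass(w)[plan$well])
  expect_true(all(plan$provenance == "generated"))
  # no two generated slots hold identical conditions
  expect_equal(anyDuplicated(plan[g$codes]), 0)
  # seeded determinism of the full maximization-penalization loop
  plan2 <- generate_batch(s, g, w, cfg, D)
  expect_identical(as.data.frame(plan), as.data.frame(plan2))
  # geometry error when the window does not match the well count
  expect_error(generate_batch(s, g, context_window(c(5, 8, 11)), cfg, D),
               "window length")
})

test_that("penalization is what diversifies a well's plate slots", {
  g <- default_search_grid()
  w <- context_window(c(5, 8, 11, 14, 17, 20))
  D <- observation_set(sample_uniform(g, 30, seed = 3, window = NULL),
                       withr::with_seed(4, runif(30, 0.2, 0.7)),
                       plate = 1, well = 1:30, grid = g)
  s <- fit_surrogate(D, g, surrogate_config(restarts = 2, seed = 2))
  base <- policy_config(candidate_pool = 200, seed = 5,
                        duplicate_mask = FALSE)
  off <- base; off$penalization <- FALSE
  plan_off <- generate_batch(s, g, w, off, D)
  plan_on <- generate_batch(s, g, w, base, D)
  for (well in 1:6) {
    rows_off <- plan_off[plan_off$well == well, g$codes]
    rows_on <- plan_on[plan_on$well == well, g$codes]
    # without the penalizer all plates of a well collapse to one condition
    expect_equal(nrow(unique(rows_off)), 1)
    # with it they are pairwise distinct
    expect_equal(nrow(unique(rows_on)), nrow(rows_on))
  }
})

test_that("first batch point is the brute-force EI argmax on a tiny grid", {
  grid <- tiny_grid(n_free = 60L, ctx_levels = c(5, 8, 11))
  w <- context_window(c(5, 8, 11), grid)
  cond <- sample_uniform(grid, 12, seed = 6, window = NULL)
  D <- observation_set(cond, withr::with_seed(7, runif(12, 0.2, 0.8)),
                       plate = 1, well = 1:12, grid = grid)
  s <- fit_surrogate(D, grid, surrogate_config(restarts = 2, seed = 3))
  cfg <- policy_config(plates = 2, wells = 3, enumerate = TRUE, seed = 8)
  plan <- generate_batch(s, grid, w, cfg, D)

  # independent enumeration of EI over the full slice DP = window[1]
  slice <- expand.grid(A = grid$specs$A$levels, DP = unclass(w)[1],
                       KEEP.OUT.ATTRS = FALSE)
  p <- posterior(s, slice)
  ei <- expected_improvement(p$mean, p$sd, max(D$score))
  best <- slice[which.max(ei), ]
  first <- plan[plan$plate == 1 & plan$well == 1, ]
  expect_equal(first$A, best$A)
  expect_equal(first$DP, best$DP)
})

test_that("controls replace the previous round's top-two slots", {
  g <- default_search_grid()
  w <- context_window(c(5, 8, 11, 14, 17, 20))
  D <- observation_set(sample_uniform(g, 48, seed = 10, window = w),
                       withr::with_seed(11, runif(48, 0.1, 0.5)),
                       plate = rep(1:8, each = 6), well = rep(1:6, 8), grid = g)
  # put the top two at known positions
  D$score[D$plate == 2 & D$well == 3] <- 0.9
  D$score[D$plate == 5 & D$well == 1] <- 0.8
  s <- fit_surrogate(D, g, surrogate_config(restarts = 2, seed = 4))
  plan <- generate_batch(s, g, w, policy_config(candidate_pool = 150, seed = 12), D)
  planned_23 <- plan[plan$plate == 2 & plan$well == 3, g$codes]
  out <- inject_controls(plan, D, g)

  expect_equal(nrow(out), 48)
  expect_equal(sum(out$provenance == "control"), 2)
  ctrl1 <- out[out$plate == 2 & out$well == 3, ]
  expect_equal(ctrl1$provenance, "control")
  expect_equal(ctrl1[g$codes], D[D$plate == 2 & D$well == 3, g$codes],
               ignore_attr = TRUE)
  ctrl2 <- out[out$plate == 5 & out$well == 1, ]
  expect_equal(ctrl2[g$codes], D[D$plate == 5 & D$well == 1, g$codes],
               ignore_attr = TRUE)
  # the overwritten slot really changed (verbatim reuse, not regeneration)
  expect_false(isTRUE(all.equal(ctrl1[g$codes], planned_23,
                                check.attributes = FALSE)))

  # ties broken by (plate, well) ascending
  Dt <- D
  Dt$score <- 0.2
  Dt$score[Dt$plate == 7 & Dt$well == 4] <- 0.9
  Dt$score[Dt$plate == 3 & Dt$well == 2] <- 0.9
  Dt$score[Dt$plate == 3 & Dt$well == 5] <- 0.9
  out_t <- inject_controls(plan, Dt, g)
  ctrl_slots <- out_t[out_t$provenance == "control", c("plate", "well")]
  expect_equal(ctrl_slots[order(ctrl_slots$plate), ],
               data.frame(plate = c(3L, 3L), well = c(2L, 5L)),
               ignore_attr = TRUE)

  # empty previous data: warn, return unchanged
  expect_warning(same <- inject_controls(plan, D[0, ], g), "no previous")
  expect_identical(as.data.frame(same), as.data.frame(plan))
})
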