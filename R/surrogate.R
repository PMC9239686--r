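#' Configuration of the GP surrogate
#'
#' The surrogate is Gaussian-process regression on unit-cube-encoded
#' conditions with an ARD-RBF kernel (one lengthscale per parameter plus a
#' signal variance) and a *fixed* observation-noise variance; 0.0039 is the
#' replicate spread measured in the baseline plates, in squared score units.
#' Kernel hyperparameters are fitted by maximizing the log marginal
#' likelihood (ML-II) with seeded multi-restart L-BFGS-B; the noise variance
#' is never fitted. The prior mean is a constant, by default the mean of the
#' observed scores (scores live in \[0,1\], so a zero mean would be
#' misspecified).
#'
#' @param noise_variance fixed observation-noise variance (score units^2).
#' @param lengthscales optional initial/fixed ARD lengthscales (unit-cube
#'   coordinates), one per parameter or a scalar to recycle.
#' @param signal_variance optional initial/fixed kernel signal variance.
#' @param prior_mean optional constant prior mean; default mean of scores.
#' @param restarts number of ML-II restarts (first start is
#'   lengthscales/signal_variance above or a standard init; the rest are
#'   seeded log-uniform draws within the bounds).
#' @param seed integer seed for the restarts.
#' @param optimize if `FALSE`, hyperparameters are used as given (no ML-II).
#' @param jitter diagonal jitter added to the Gram matrix for stability.
#' @param lengthscale_bounds,signal_variance_bounds box bounds for ML-II.
#' @return an object of class `surrogate_config`.
#' @export
surrogate_config <- function(noise_variance = 0.0039,
                             lengthscales = NULL,
                             signal_variance = NULL,
                             prior_mean = NULL,
                             restarts = 5L,
                             seed = 1L,
                             optimize = TRUE,
                             jitter = 1e-8,
                             lengthscale_bounds = c(1e-2, 10),
                             signal_variance_bounds = c(1e-6, 25)) {
  stopifnot(noise_variance > 0, jitter >= 0, restarts >= 1)
  structure(
    list(noise_variance = noise_variance, lengthscales = lengthscales,
         signal_variance = signal_variance, prior_mean = prior_mean,
         restarts = as.integer(restarts), seed = as.integer(seed),
         optimize = isTRUE(optimize), jitter = jitter,
         lengthscale_bounds = lengthscale_bounds,
         signal_variance_bounds = signal_variance_bounds),
    class = "surrogate_config"
  )
}

# ARD-RBF cross-covariance between rows of X1 and X2 (both already scaled by
# 1/lengthscale): sv * exp(-0.5 * squared distance).
ard_rbf <- function(X1, X2, lengthscales, signal_variance) {
  S1 <- sweep(X1, 2, lengthscales, "/")
  S2 <- sweep(X2, 2, lengthscales, "/")
  d2 <- outer(rowSums(S1^2), rowSums(S2^2), "+") - 2 * tcrossprod(S1, S2)
  d2[d2 < 0] <- 0
  signal_variance * exp(-0.5 * d2)
}

# Negative log marginal likelihood at theta = c(log lengthscales, log sv),
# noise variance held fixed.
gp_neg_lml <- function(theta, X, yc, noise_variance, jitter) {
  d <- ncol(X)
  ls <- exp(theta[seq_len(d)])
  sv <- exp(theta[d + 1L])
  K <- ard_rbf(X, X, ls, sv)
  diag(K) <- diag(K) + noise_variance + jitter
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(1e10)
  alpha <- backsolve(L, forwardsolve(t(L), yc))
  0.5 * sum(yc * alpha) + sum(log(diag(L))) + 0.5 * length(yc) * log(2 * pi)
}

#' Fit the GP surrogate to an observation set
#'
#' Conditions are encoded to the unit cube, scores centered by the prior
#' mean, and the ARD lengthscales and signal variance are chosen by ML-II
#' (unless `cfg$optimize` is `FALSE`), with the observation-noise variance
#' held fixed at `cfg$noise_variance`. Rows with missing scores are dropped
#' with a warning; duplicate conditions are permitted (the noise model
#' absorbs replicates).
#'
#' @param D observation data frame (see [observation_set()]).
#' @param grid a [search_grid()].
#' @param cfg a [surrogate_config()].
#' @return an object of class `gp_surrogate` with elements `lengthscales`,
#'   `signal_variance`, `noise_variance`, `prior_mean`, `lml` (log marginal
#'   likelihood at the returned hyperparameters), and the retained training
#'   set.
#' @examples
#' g <- default_search_grid()
#' D <- observation_set(sample_uniform(g, 10, seed = 1),
#'                      score = runif(10, 0.2, 0.6), plate = 1:10)
#' s <- fit_surrogate(D, g, surrogate_config(restarts = 2))
#' posterior(s, D[g$codes][1:2, ])
#' @export
fit_surrogate <- function(D, grid, cfg = surrogate_config()) {
  stopifnot(inherits(cfg, "surrogate_config"))
  D <- drop_unscored(D)
  if (nrow(D) < 1L) stop_rpe("no observations; use uniform initialization")
  validate_observations(D, grid)
  X <- encode_conditions(D[grid$codes], grid)
  y <- D$score
  m0 <- cfg$prior_mean %||% mean(y)
  yc <- y - m0
  d <- ncol(X)

  ls0 <- cfg$lengthscales %||% 0.3
  ls0 <- rep_len(ls0, d)
  sv0 <- cfg$signal_variance %||% max(var(y), 1e-3, na.rm = TRUE)
  if (is.na(sv0)) sv0 <- 0.1

  clamp <- function(x, b) pmin(pmax(x, b[1]), b[2])
  ls0 <- clamp(ls0, cfg$lengthscale_bounds)
  sv0 <- clamp(sv0, cfg$signal_variance_bounds)

  if (cfg$optimize) {
    lower <- c(rep(log(cfg$lengthscale_bounds[1]), d), log(cfg$signal_variance_bounds[1]))
    upper <- c(rep(log(cfg$lengthscale_bounds[2]), d), log(cfg$signal_variance_bounds[2]))
    starts <- list(c(log(ls0), log(sv0)))
    if (cfg$restarts > 1L) {
      extra <- withr::with_seed(derive_seed(cfg$seed, 17L), {
        lapply(seq_len(cfg$restarts - 1L), function(i) runif(d + 1L, lower, upper))
      })
      starts <- c(starts, extra)
    }
    best <- NULL
    for (st in starts) {
      fit <- tryCatch(
        optim(st, gp_neg_lml, method = "L-BFGS-B", lower = lower, upper = upper,
              X = X, yc = yc, noise_variance = cfg$noise_variance, jitter = cfg$jitter),
        error = function(e) NULL)
      if (is.null(fit)) next
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    if (is.null(best)) {
      theta <- c(log(ls0), log(sv0))  # fall back to the initial hyperparameters
    } else {
      # never return a fit worse than the starting hyperparameters
      v0 <- gp_neg_lml(starts[[1]], X, yc, cfg$noise_variance, cfg$jitter)
      theta <- if (best$value <= v0) best$par else starts[[1]]
    }
    ls <- exp(theta[seq_len(d)])
    sv <- exp(theta[d + 1L])
  } else {
    ls <- ls0
    sv <- sv0
  }

  K <- ard_rbf(X, X, ls, sv)
  diag(K) <- diag(K) + cfg$noise_variance + cfg$jitter
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), yc))
  lml <- -(0.5 * sum(yc * alpha) + sum(log(diag(L))) + 0.5 * length(yc) * log(2 * pi))

  structure(
    list(X = X, y = y, prior_mean = m0, lengthscales = ls, signal_variance = sv,
         noise_variance = cfg$noise_variance, jitter = cfg$jitter,
         chol_K = L, alpha = alpha, lml = lml, grid = grid, config = cfg),
    class = "gp_surrogate"
  )
}

# Posterior mean and latent (noise-free) sd at encoded coordinates.
gp_posterior_at <- function(s, Xstar) {
  Ks <- ard_rbf(Xstar, s$X, s$lengthscales, s$signal_variance)
  mean <- s$prior_mean + as.numeric(Ks %*% s$alpha)
  V <- forwardsolve(t(s$chol_K), t(Ks))
  var <- s$signal_variance - colSums(V^2)
  var[var < 0] <- 0
  list(mean = mean, sd = sqrt(var))
}

#' Posterior mean and standard deviation at conditions
#'
#' The reported standard deviation is that of the latent (noise-free)
#' pigmentation response.
#'
#' @param s a fitted [fit_surrogate()] object.
#' @param conditions data frame of on-grid conditions.
#' @return data frame with columns `mean` and `sd`.
#' @export
posterior <- function(s, conditions) {
  stopifnot(inherits(s, "gp_surrogate"))
  Xs <- encode_conditions(conditions, s$grid)
  p <- gp_posterior_at(s, Xs)
  data.frame(mean = p$mean, sd = p$sd)
}

#' @export
predict.gp_surrogate <- function(object, newdata, ...) posterior(object, newdata)

#' @export
print.gp_surrogate <- function(x, ...) {
  cat(sprintf("<gp_surrogate> n = %d, prior mean = %.4f, signal var = %.4f, noise var = %.4g\n",
              length(x$y), x$prior_mean, x$signal_variance, x$noise_variance))
  cat("  lengthscales:", paste(sprintf("%s=%.3f", colnames(x$X), x$lengthscales),
                               collapse = ", "), "\n")
  cat(sprintf("  log marginal likelihood: %.3f\n", x$lml))
  invisible(x)
}
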