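#' Synthetic pigmentation-response surface
#'
#' A deterministic stand-in for the wet-lab pigmentation response, used to
#' exercise and benchmark the optimizer end to end. The surface is a product
#' of per-parameter Gaussian bumps in unit-cube coordinates,
#' `0.05 + 0.9 * prod_j exp(-0.5 ((x_j - c_j) / w_j)^2)`,
#' with a unimodal trypsin-period factor peaking at DP = 14 min (the best
#' trypsin time of the pre-optimized baseline), so the maximum 0.95 is
#' attained at the documented optimum condition and the range is a subset of
#' \[0, 1\]. On the default grid the optimum is PC = 305 nM, PP = 4 d,
#' DP = 14 min, DS = 40 mm/s, DL = long, KP = 10 d, 3P = 11 d; on other
#' grids, parameters without a documented center peak at their middle level.
#' The bump widths are chosen so that uniformly sampled conditions score
#' around 0.37 +/- 0.13 — the regime of real pre-optimized plates — while
#' scores above 0.85 remain confined to a small basin around the optimum.
#'
#' @param grid a [search_grid()].
#' @return an object of class `toy_response` with elements `optimum` (the
#'   maximizing condition, a one-row data frame), `max_value` (0.95), and
#'   `predict(conditions)`.
#' @examples
#' resp <- toy_response()
#' resp$max_value
#' resp$predict(resp$optimum)
#' @export
toy_response <- function(grid = default_search_grid()) {
  opt_default <- list(PC = 305, PP = 4, DP = 14, DS = 40, DL = "long",
                      KP = 10, "3P" = 11)
  width_default <- c(PC = 0.55, PP = 0.60, DP = 0.50, DS = 0.55, DL = 1.4,
                     KP = 0.60, "3P" = 0.60)

  opt <- vector("list", length(grid$codes))
  names(opt) <- grid$codes
  widths <- numeric(length(grid$codes))
  names(widths) <- grid$codes
  for (code in grid$codes) {
    spec <- grid$specs[[code]]
    v <- opt_default[[code]]
    on_grid <- !is.null(v) && !is.na(level_index(v, spec))
    opt[[code]] <- if (on_grid) v else spec$levels[ceiling(length(spec$levels) / 2)]
    widths[code] <- if (code %in% names(width_default)) width_default[[code]] else 0.3
  }
  optimum <- as.data.frame(opt, check.names = FALSE, stringsAsFactors = FALSE)
  centers <- encode_conditions(optimum, grid)[1, ]

  predict_fn <- function(conditions) {
    X <- encode_conditions(conditions, grid)
    z <- sweep(sweep(X, 2, centers), 2, widths, "/")
    0.05 + 0.9 * exp(-0.5 * rowSums(z^2))
  }

  structure(list(grid = grid, optimum = optimum, max_value = 0.95,
                 centers = centers, widths = widths, predict = predict_fn),
            class = "toy_response")
}

#' Noisy observation of a response surface
#'
#' Evaluates the response at each condition and adds seeded zero-mean
#' Gaussian noise of the given variance (0.0039 by default, the replicate
#' spread of the baseline plates); scores are area fractions, so the result
#' is clipped to \[0, 1\].
#'
#' @param resp a [toy_response()].
#' @param conditions data frame of on-grid conditions.
#' @param seed integer seed.
#' @param noise_variance observation-noise variance.
#' @return numeric scores in \[0, 1\].
#' @export
observe <- function(resp, conditions, seed = 1L, noise_variance = 0.0039) {
  stopifnot(inherits(resp, "toy_response"), noise_variance >= 0)
  y <- resp$predict(conditions)
  if (noise_variance > 0) {
    y <- withr::with_seed(seed, y + rnorm(length(y), 0, sqrt(noise_variance)))
  }
  pmin(pmax(y, 0), 1)
}

#' @export
print.toy_response <- function(x, ...) {
  cat(sprintf("<toy_response> max %.2f at:\n", x$max_value))
  print(x$optimum)
  invisible(x)
}
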