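#' Expected improvement over the incumbent
#'
#' Closed-form EI for maximization under a Gaussian posterior:
#' `(mean - incumbent) * pnorm(z) + sd * dnorm(z)` with
#' `z = (mean - incumbent) / sd`; at `sd = 0` it degenerates to
#' `max(mean - incumbent, 0)`. Always non-negative.
#'
#' @param mean,sd posterior mean and standard deviation (vectorized).
#' @param incumbent best observed score so far.
#' @return EI values, same length as `mean`.
#' @export
expected_improvement <- function(mean, sd, incumbent) {
  stopifnot(all(sd >= 0))
  delta <- mean - incumbent
  out <- pmax(delta, 0)
  pos <- sd > 0
  if (any(pos)) {
    z <- delta[pos] / sd[pos]
    out[pos] <- delta[pos] * pnorm(z) + sd[pos] * dnorm(z)
  }
  pmax(out, 0)
}

#' Bind a surrogate into an acquisition function
#'
#' Returns a function mapping a data frame of on-grid conditions to EI
#' values, with the surrogate and incumbent bound in. The incumbent is the
#' maximum *observed* score (not the maximum posterior mean), which is
#' simpler and robust to observation noise.
#'
#' @param s a fitted [fit_surrogate()] object.
#' @param incumbent best observed score; defaults to `max(s$y)`.
#' @return a function of class `acquisition_function`.
#' @export
make_acquisition <- function(s, incumbent = max(s$y)) {
  stopifnot(inherits(s, "gp_surrogate"))
  f <- function(conditions) {
    p <- posterior(s, conditions)
    expected_improvement(p$mean, p$sd, incumbent)
  }
  structure(f, class = c("acquisition_function", "function"),
            surrogate = s, incumbent = incumbent)
}

#' Estimate a Lipschitz constant of the posterior mean
#'
#' Local penalization needs a bound on how fast the (estimated) response can
#' change. Following the local-penalization approach, the constant is taken
#' as the maximum posterior-mean gradient norm over a seeded sample of grid
#' points, with the gradient computed by central finite differences in
#' unit-cube coordinates, floored at 1e-4.
#'
#' @param s a fitted [fit_surrogate()] object.
#' @param grid a [search_grid()].
#' @param seed integer seed for the probe sample.
#' @param n_probe number of probe points.
#' @param h finite-difference half-step in unit-cube coordinates.
#' @return an object of class `lipschitz_estimate` with element `value`
#'   (score units per unit-cube distance).
#' @export
estimate_lipschitz <- function(s, grid, seed = 1L, n_probe = 2000, h = 1e-3) {
  probe <- sample_uniform(grid, n_probe, seed = seed, window = NULL)
  X <- encode_conditions(probe, grid)
  d <- ncol(X)
  g2 <- matrix(0, nrow(X), d)
  for (j in seq_len(d)) {
    up <- X; up[, j] <- pmin(X[, j] + h, 1)
    dn <- X; dn[, j] <- pmax(X[, j] - h, 0)
    span <- up[, j] - dn[, j]
    span[span == 0] <- 1  # degenerate single-level coordinate: zero gradient
    mu_up <- gp_posterior_at(s, up)$mean
    mu_dn <- gp_posterior_at(s, dn)$mean
    g2[, j] <- ((mu_up - mu_dn) / span)^2
  }
  L <- max(sqrt(rowSums(g2)), 1e-4)
  structure(list(value = L), class = "lipschitz_estimate")
}

lipschitz_value <- function(L) {
  if (inherits(L, "lipschitz_estimate")) L$value else as.numeric(L)
}

# Soft local penalizer on encoded coordinates: Phi of
# (L * dist - incumbent_max + mu(center)) / (sqrt(2) * sd(center)).
# Values in (0, 1]; smallest at the center, -> 1 in the far field.
penalizer_at <- function(Xenc, center_enc, L, incumbent_max, mu_c, sd_c) {
  sd_c <- max(sd_c, 1e-6)
  dist <- sqrt(rowSums(sweep(Xenc, 2, center_enc)^2))
  pnorm((L * dist - incumbent_max + mu_c) / (sqrt(2) * sd_c))
}

#' Soft local penalizer around a selected batch point
#'
#' Multiplicative penalty that suppresses the acquisition near an
#' already-selected batch point. With `d = ||x - center||` in unit-cube
#' coordinates, the penalty is `Phi((L d - M + mu(center)) / (sqrt(2)
#' sd(center)))` where `M` is the incumbent maximum and `(mu, sd)` the
#' posterior at the center (sd floored at 1e-6). It is smallest at the
#' center and tends to 1 far away, so distant regions are left untouched.
#'
#' @param x data frame of conditions to penalize.
#' @param center data frame with the single selected condition.
#' @param L a [estimate_lipschitz()] result or a positive number.
#' @param incumbent_max best observed score.
#' @param s the fitted [fit_surrogate()] object.
#' @return penalties in (0, 1\], one per row of `x`.
#' @export
local_penalizer <- function(x, center, L, incumbent_max, s) {
  Xenc <- encode_conditions(x, s$grid)
  c_enc <- encode_conditions(center, s$grid)[1, ]
  pc <- gp_posterior_at(s, matrix(c_enc, nrow = 1))
  penalizer_at(Xenc, c_enc, lipschitz_value(L), incumbent_max, pc$mean, pc$sd)
}

#' Batch policy configuration
#'
#' Geometry and sampling knobs of the batch contextual local penalization
#' (BCLP) policy.
#'
#' @param plates number of plates P per round.
#' @param wells number of wells W per plate (= context window length).
#' @param candidate_pool free-parameter candidates sampled per context value.
#' @param seed integer seed for pools and tie-breaking.
#' @param duplicate_mask exclude already-selected conditions from the pool.
#' @param penalization apply the local penalizer (disable only to study the
#'   policy's diversification role).
#' @param hill_climb refine each pool argmax with one coordinate-wise sweep
#'   over every free parameter's levels.
#' @param enumerate enumerate all free-parameter combinations instead of
#'   sampling a pool (only sensible on reduced grids).
#' @param loop_order `"well_outer"` fills well slots in ascending context
#'   order with plates inner (matching the ascending-DP fill of the
#'   maximization-penalization loop); `"plate_outer"` nests wells inside
#'   plates. Both orders produce a full P x W plan.
#' @return an object of class `policy_config`.
#' @export
policy_config <- function(plates = 8L, wells = 6L, candidate_pool = 100000L,
                          seed = 1L, duplicate_mask = TRUE,
                          penalization = TRUE, hill_climb = TRUE,
                          enumerate = FALSE,
                          loop_order = c("well_outer", "plate_outer")) {
  stopifnot(plates >= 1, wells >= 1, candidate_pool >= 1)
  structure(
    list(plates = as.integer(plates), wells = as.integer(wells),
         candidate_pool = as.integer(candidate_pool), seed = as.integer(seed),
         duplicate_mask = isTRUE(duplicate_mask),
         penalization = isTRUE(penalization),
         hill_climb = isTRUE(hill_climb),
         enumerate = isTRUE(enumerate),
         loop_order = match.arg(loop_order)),
    class = "policy_config"
  )
}

# All free-parameter combinations with the context fixed at `ctx`.
enumerate_pool <- function(grid, ctx) {
  lv <- lapply(grid$specs, function(s) s$levels)
  lv[[grid$context_code]] <- ctx
  out <- expand.grid(lv, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  names(out) <- grid$codes
  out
}

condition_key <- function(Xenc) apply(round(Xenc, 10), 1, paste, collapse = "|")

#' Generate the next-round batch with BCLP
#'
#' The maximization-penalization loop: the EI acquisition is mapped through
#' a softplus to a strictly positive utility (softplus is monotone, so the
#' argmax is unchanged); then, for each well slot (context value) and plate,
#' the condition maximizing the running penalized utility is selected, after
#' which the utility is multiplied by the local penalizer centered on the
#' selection. Each context value gets its own seeded candidate pool over the
#' free parameters (optionally refined by a coordinate-wise hill-climb
#' sweep); every generated slot carries the context value of its well.
#'
#' @param s a fitted [fit_surrogate()] object.
#' @param grid a [search_grid()].
#' @param window a [context_window()] of length `cfg$wells`.
#' @param cfg a [policy_config()].
#' @param D observation data frame supplying the incumbent (max observed
#'   score); defaults to the surrogate's training scores.
#' @return a `batch_plan`: data frame with columns `plate`, `well`, one per
#'   parameter code, and `provenance` (`"generated"`), with the window kept
#'   as an attribute.
#' @export
generate_batch <- function(s, grid, window, cfg = policy_config(), D = NULL) {
  stopifnot(inherits(s, "gp_surrogate"), inherits(cfg, "policy_config"))
  vals <- as.numeric(unclass(window))
  if (length(vals) != cfg$wells) {
    stop_rpe("context window length (%d) must equal the number of wells (%d)",
             length(vals), cfg$wells)
  }
  incumbent <- if (!is.null(D)) {
    max(D$score, na.rm = TRUE)
  } else max(s$y)

  L <- lipschitz_value(estimate_lipschitz(s, grid, seed = derive_seed(cfg$seed, 999L)))

  pools <- vector("list", cfg$wells)
  centers_enc <- NULL
  centers_key <- character(0)
  center_stats <- list()

  new_pool <- function(w) {
    pool <- if (cfg$enumerate) {
      enumerate_pool(grid, vals[w])
    } else {
      sample_uniform(grid, cfg$candidate_pool, seed = derive_seed(cfg$seed, w),
                     window = vals[w])
    }
    enc <- encode_conditions(pool, grid)
    p <- gp_posterior_at(s, enc)
    u0 <- softplus(expected_improvement(p$mean, p$sd, incumbent))
    u <- u0
    if (cfg$penalization && !is.null(centers_enc)) {
      for (j in seq_len(nrow(centers_enc))) {
        st <- center_stats[[j]]
        u <- u * penalizer_at(enc, centers_enc[j, ], L, incumbent, st$mean, st$sd)
      }
    }
    list(df = pool, enc = enc, key = condition_key(enc), u0 = u0, u = u)
  }

  # penalized utility of arbitrary conditions, for the hill-climb refinement
  utility_of <- function(enc) {
    p <- gp_posterior_at(s, enc)
    u <- softplus(expected_improvement(p$mean, p$sd, incumbent))
    if (cfg$penalization && !is.null(centers_enc)) {
      for (j in seq_len(nrow(centers_enc))) {
        st <- center_stats[[j]]
        u <- u * penalizer_at(enc, centers_enc[j, ], L, incumbent, st$mean, st$sd)
      }
    }
    u
  }

  hill_climb <- function(cond) {
    free <- setdiff(grid$codes, grid$context_code)
    for (code in free) {
      spec <- grid$specs[[code]]
      cand <- cond[rep(1L, length(spec$levels)), , drop = FALSE]
      cand[[code]] <- spec$levels
      enc <- encode_conditions(cand, grid)
      u <- utility_of(enc)
      if (cfg$duplicate_mask && length(centers_key)) {
        u[condition_key(enc) %in% centers_key] <- -Inf
      }
      cond <- cand[which.max(u), , drop = FALSE]
    }
    cond
  }

  slots <- if (cfg$loop_order == "well_outer") {
    expand.grid(plate = seq_len(cfg$plates), well = seq_len(cfg$wells))[, 2:1]
  } else {
    expand.grid(well = seq_len(cfg$wells), plate = seq_len(cfg$plates))
  }

  rows <- vector("list", nrow(slots))
  for (i in seq_len(nrow(slots))) {
    w <- slots$well[i]
    if (is.null(pools[[w]])) pools[[w]] <- new_pool(w)
    pool <- pools[[w]]
    u <- pool$u
    if (cfg$duplicate_mask && length(centers_key)) {
      u[pool$key %in% centers_key] <- -Inf
    }
    best <- which.max(u)
    chosen <- pool$df[best, , drop = FALSE]
    if (cfg$hill_climb) chosen <- hill_climb(chosen)
    enc <- encode_conditions(chosen, grid)
    key <- condition_key(enc)
    if (cfg$duplicate_mask && key %in% centers_key) {
      chosen <- pool$df[best, , drop = FALSE]  # hill climb ran into a duplicate
      enc <- encode_conditions(chosen, grid)
      key <- condition_key(enc)
    }

    pc <- gp_posterior_at(s, enc)
    centers_enc <- rbind(centers_enc, enc)
    centers_key <- c(centers_key, key)
    center_stats[[length(center_stats) + 1L]] <- list(mean = pc$mean, sd = pc$sd)
    if (cfg$penalization) {
      for (w2 in seq_len(cfg$wells)) {
        if (!is.null(pools[[w2]])) {
          pools[[w2]]$u <- pools[[w2]]$u *
            penalizer_at(pools[[w2]]$enc, enc[1, ], L, incumbent, pc$mean, pc$sd)
        }
      }
    }
    rows[[i]] <- cbind(data.frame(plate = slots$plate[i], well = w), chosen,
                       data.frame(provenance = "generated",
                                  stringsAsFactors = FALSE))
  }
  plan <- do.call(rbind, rows)
  plan <- plan[order(plan$plate, plan$well), , drop = FALSE]
  rownames(plan) <- NULL
  structure(plan, class = c("batch_plan", "data.frame"),
            window = window, seed = cfg$seed)
}

#' Inject positive-control slots into a batch plan
#'
#' Overwrites the two plan slots whose (plate, well) positions held the
#' previous round's two highest scores with those two previous conditions,
#' marked `provenance = "control"`. Ties are broken by (plate, well)
#' ascending. Control slots re-run the old condition verbatim, so their
#' context value may differ from the window value of their well; the context
#' invariant applies to generated slots only.
#'
#' @param plan a `batch_plan` from [generate_batch()].
#' @param previous observation data frame of the previous round (with
#'   `plate`, `well`, `score`); if empty, the plan is returned unchanged
#'   with a warning.
#' @param grid a [search_grid()].
#' @param n_controls number of top conditions to carry over (default 2).
#' @return the plan with control slots replaced.
#' @export
inject_controls <- function(plan, previous, grid = default_search_grid(),
                            n_controls = 2L) {
  if (is.null(previous) || nrow(previous) == 0L) {
    warn_rpe("no previous observations; returning the plan without controls")
    return(plan)
  }
  prev <- previous[!is.na(previous$score), , drop = FALSE]
  if (nrow(prev) == 0L) {
    warn_rpe("no scored previous observations; returning the plan without controls")
    return(plan)
  }
  ord <- order(-prev$score, prev$plate, prev$well)
  top <- prev[ord[seq_len(min(n_controls, nrow(prev)))], , drop = FALSE]
  for (i in seq_len(nrow(top))) {
    at <- which(plan$plate == top$plate[i] & plan$well == top$well[i])
    if (length(at) != 1L) {
      warn_rpe("plan has no slot (plate %d, well %d); control skipped",
               top$plate[i], top$well[i])
      next
    }
    for (code in grid$codes) plan[[code]][at] <- top[[code]][i]
    plan$provenance[at] <- "control"
  }
  plan
}

#' @export
print.batch_plan <- function(x, ...) {
  cat(sprintf("<batch_plan> %d slots (%d generated, %d control)\n",
              nrow(x), sum(x$provenance == "generated"),
              sum(x$provenance == "control")))
  w <- attr(x, "window")
  if (!is.null(w)) print(w)
  print(as.data.frame(head(x, 6)))
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}
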