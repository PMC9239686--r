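#' Context window for the trypsin period
#'
#' Within a round every plate is processed with the same ordered set of
#' trypsin periods, one per well slot: the apparatus can only realize the
#' detachment trypsin period (DP) at fixed values spaced 3 minutes apart,
#' corresponding to the number of wells. A context window is therefore an
#' increasing arithmetic sequence of DP grid levels whose common difference
#' equals the DP grid spacing.
#'
#' @param values ordered trypsin periods in minutes, e.g. `c(5, 8, 11, 14, 17, 20)`.
#' @param grid a [search_grid()] whose contextual parameter the window must
#'   live on.
#' @return an object of class `context_window` (a numeric vector).
#' @export
context_window <- function(values, grid = default_search_grid()) {
  values <- as.numeric(values)
  spec <- grid$specs[[grid$context_code]]
  if (any(diff(values) <= 0)) stop_rpe("context window must be strictly increasing")
  spacing <- unique(diff(spec$levels))
  if (length(spacing) != 1L) stop_rpe("contextual grid must be arithmetic")
  if (length(values) > 1L && any(abs(diff(values) - spacing) > 1e-9)) {
    stop_rpe("context window spacing must equal the contextual grid spacing (%g)", spacing)
  }
  if (anyNA(level_index(values, spec))) {
    stop_rpe("context window values must be levels of the %s grid", grid$context_code)
  }
  structure(values, class = "context_window", context_code = grid$context_code)
}

#' @export
print.context_window <- function(x, ...) {
  cat(sprintf("<context_window> %s = {%s} min\n",
              attr(x, "context_code") %||% "DP",
              paste(unclass(x), collapse = ", ")))
  invisible(x)
}

#' Decide the next trypsin context window
#'
#' After each round the context window for the trypsin period may stay, shift
#' down, or shift up by one grid step. The rule integrates the acquisition
#' function over the free parameters at each context value, for the current
#' window `c`, the down-shifted `c - delta_c`, and the up-shifted
#' `c + delta_c`; the accumulated masses V, V-, V+ give ratios R- = V-/V and
#' R+ = V+/V, and:
#' \itemize{
#'   \item `max(R-, R+) < 1.05` -> stay;
#'   \item else `R- > R+` -> shift down;
#'   \item else (`R- <= R+`, including exact ties) -> shift up.
#' }
#' The integral over the free parameters is approximated by the mean of the
#' acquisition over `mc_samples` seeded uniform draws, shared across all
#' context values for variance reduction. A candidate entry outside the
#' contextual grid range contributes zero mass, which biases the rule against
#' infeasible shifts; should an infeasible shift nevertheless win, the
#' decision falls back to stay with a warning so the returned window is
#' always valid.
#'
#' @param acq acquisition function: a function taking a data frame of
#'   conditions and returning non-negative values (see [make_acquisition()]).
#' @param grid a [search_grid()].
#' @param window current [context_window()].
#' @param delta_c shift width in context units; defaults to the contextual
#'   grid spacing (3 min on the default grid).
#' @param mc_samples Monte-Carlo draws per context value.
#' @param seed integer seed for the shared draws.
#' @return an object of class `context_decision`: list with `V`, `V_minus`,
#'   `V_plus`, `R_minus`, `R_plus`, `action` (`"stay"`, `"shift_down"`,
#'   `"shift_up"`), and `next_window`.
#' @export
adjust_context <- function(acq, grid, window, delta_c = NULL,
                           mc_samples = 10000, seed = 1L) {
  stopifnot(mc_samples >= 1)
  spec <- grid$specs[[grid$context_code]]
  spacing <- unique(diff(spec$levels))
  if (length(spacing) != 1L) stop_rpe("contextual grid must be arithmetic")
  delta_c <- delta_c %||% spacing
  if (abs(delta_c - spacing) > 1e-9) {
    stop_rpe("delta_c (%g) must equal the contextual grid spacing (%g)", delta_c, spacing)
  }
  vals <- as.numeric(unclass(window))

  # shared free-parameter draws across all context values
  draws <- sample_uniform(grid, mc_samples, seed = seed, window = vals[1])
  lo <- min(spec$levels) - 1e-9
  hi <- max(spec$levels) + 1e-9
  mass_at <- function(v) {
    if (v < lo || v > hi) return(0)
    # snap to the contextual grid (entries are grid levels when in range)
    v <- spec$levels[which.min(abs(spec$levels - v))]
    draws[[grid$context_code]] <- v
    mean(acq(draws))
  }
  V <- sum(vapply(vals, mass_at, numeric(1)))
  V_minus <- sum(vapply(vals - delta_c, mass_at, numeric(1)))
  V_plus <- sum(vapply(vals + delta_c, mass_at, numeric(1)))

  if (V <= 0) {
    warn_rpe("degenerate acquisition mass (V = 0); keeping the current context window")
    return(structure(list(V = V, V_minus = V_minus, V_plus = V_plus,
                          R_minus = NA_real_, R_plus = NA_real_,
                          action = "stay", next_window = window),
                     class = "context_decision"))
  }
  R_minus <- V_minus / V
  R_plus <- V_plus / V

  action <- if (max(R_minus, R_plus) < 1.05) "stay"
            else if (R_minus > R_plus) "shift_down"
            else "shift_up"
  cand <- switch(action, stay = vals,
                 shift_down = vals - delta_c, shift_up = vals + delta_c)
  if (action != "stay" && (min(cand) < lo || max(cand) > hi)) {
    warn_rpe("winning context shift leaves the %s grid; keeping the current window",
             grid$context_code)
    action <- "stay"
    cand <- vals
  }
  structure(
    list(V = V, V_minus = V_minus, V_plus = V_plus,
         R_minus = R_minus, R_plus = R_plus, action = action,
         next_window = context_window(cand, grid)),
    class = "context_decision"
  )
}

#' @export
print.context_decision <- function(x, ...) {
  cat(sprintf("<context_decision> %s (V=%.4g, R-=%.3f, R+=%.3f)\n",
              x$action, x$V, x$R_minus, x$R_plus))
  print(x$next_window)
  invisible(x)
}
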