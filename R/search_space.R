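#' Parameter specification for one protocol parameter
#'
#' A parameter of the differentiation protocol is searched over a finite,
#' ordered set of admissible levels. Three kinds exist: `numeric-grid`
#' (ordinary discretized numeric range), `categorical` (unordered labels,
#' stored in a fixed documented order), and `contextual-grid` (a numeric grid
#' whose value is constrained by the apparatus to a shared per-well context
#' within a round; here the trypsin period DP).
#'
#' @param code short parameter code, e.g. `"PC"`, `"DP"`, `"3P"`.
#' @param name human-readable parameter name.
#' @param kind one of `"numeric-grid"`, `"categorical"`, `"contextual-grid"`.
#' @param levels ordered vector of admissible values; strictly increasing for
#'   numeric kinds.
#' @param unit unit string (informational), e.g. `"nM"`, `"day"`, `"min"`.
#' @param protocol_step protocol step the parameter belongs to.
#' @return an object of class `parameter_spec`.
#' @export
parameter_spec <- function(code, name, kind, levels, unit = "", protocol_step = "") {
  kind <- match.arg(kind, c("numeric-grid", "categorical", "contextual-grid"))
  if (length(levels) < 1L) stop_rpe("parameter %s: levels must be non-empty", code)
  if (kind != "categorical") {
    levels <- as.numeric(levels)
    if (any(diff(levels) <= 0)) {
      stop_rpe("parameter %s: numeric levels must be strictly increasing", code)
    }
  } else {
    levels <- as.character(levels)
    if (anyDuplicated(levels)) stop_rpe("parameter %s: duplicate levels", code)
  }
  structure(
    list(code = code, name = name, kind = kind, levels = levels,
         unit = unit, protocol_step = protocol_step),
    class = "parameter_spec"
  )
}

#' Search grid over protocol parameters
#'
#' Bundles an ordered list of [parameter_spec()] objects into the finite
#' search space the optimizer works on. Exactly one spec must be contextual
#' (the trypsin period, shared per well slot within a round).
#'
#' @param specs list of [parameter_spec()] objects.
#' @return an object of class `search_grid`.
#' @seealso [default_search_grid()] for the 7-parameter protocol grid.
#' @export
search_grid <- function(specs) {
  stopifnot(is.list(specs), length(specs) >= 1L)
  codes <- vapply(specs, function(s) s$code, character(1))
  if (anyDuplicated(codes)) stop_rpe("duplicate parameter codes in grid")
  kinds <- vapply(specs, function(s) s$kind, character(1))
  n_ctx <- sum(kinds == "contextual-grid")
  if (n_ctx != 1L) stop_rpe("grid must contain exactly one contextual parameter (found %d)", n_ctx)
  names(specs) <- codes
  structure(
    list(specs = specs, codes = codes,
         context_code = codes[kinds == "contextual-grid"]),
    class = "search_grid"
  )
}

#' Default 7-parameter iPSC-RPE protocol search grid
#'
#' The discretized search space of the differentiation protocol:
#' \describe{
#'   \item{PC}{FGFRi preconditioning concentration, 0-505 nM (default step 5).}
#'   \item{PP}{FGFRi preconditioning period, 1-6 days.}
#'   \item{DP}{detachment trypsin period at room temperature,
#'     \{5, 8, 11, 14, 17, 20, 23\} min — the contextual parameter.}
#'   \item{DS}{detachment pipetting strength, 10-100 mm/s (default step 1).}
#'   \item{DL}{detachment pipetting length, short / long.}
#'   \item{KP}{KSR taper period, 1-19 days.}
#'   \item{3P}{three-supplement (Y/SB/CKI) period, 3-19 days.}
#' }
#' The continuous ranges (PC, DS) carry no published step size; the defaults
#' give a total cardinality of 251,839,224, i.e. the documented "around 2.5e8"
#' space, and are overridable here and from config files.
#'
#' @param pc_step step (nM) for the PC grid.
#' @param ds_step step (mm/s) for the DS grid.
#' @return a [search_grid()] with 7 parameter specs.
#' @examples
#' g <- default_search_grid()
#' grid_cardinality(g)
#' g$specs$DP$levels
#' @export
default_search_grid <- function(pc_step = 5, ds_step = 1) {
  search_grid(list(
    parameter_spec("PC", "Preconditioning concentration", "numeric-grid",
                   seq(0, 505, by = pc_step), "nM", "Preconditioning"),
    parameter_spec("PP", "Preconditioning period", "numeric-grid",
                   1:6, "day", "Preconditioning"),
    parameter_spec("DP", "Detachment trypsin period", "contextual-grid",
                   seq(5, 23, by = 3), "min", "Passage"),
    parameter_spec("DS", "Detachment pipetting strength", "numeric-grid",
                   seq(10, 100, by = ds_step), "mm/s", "Passage"),
    parameter_spec("DL", "Detachment pipetting length", "categorical",
                   c("short", "long"), "", "Passage"),
    parameter_spec("KP", "KSR period", "numeric-grid",
                   1:19, "day", "RPE differentiation"),
    parameter_spec("3P", "Three supplements period", "numeric-grid",
                   3:19, "day", "RPE differentiation")
  ))
}

#' Number of conditions in a search grid
#'
#' Exact integer product of per-parameter level counts.
#'
#' @param grid a [search_grid()].
#' @return a numeric count (may exceed .Machine$integer.max).
#' @export
grid_cardinality <- function(grid) {
  stopifnot(inherits(grid, "search_grid"))
  prod(vapply(grid$specs, function(s) length(s$levels), numeric(1)))
}

# Encoded [0,1] position of each level of a spec. Categorical levels sit at
# equally spaced points in their documented order (so DL short -> 0, long -> 1);
# numeric levels are placed linearly in value. A single-level spec maps to 0.
level_positions <- function(spec) {
  k <- length(spec$levels)
  if (k == 1L) return(0)
  if (spec$kind == "categorical") {
    seq(0, 1, length.out = k)
  } else {
    (spec$levels - spec$levels[1]) / (spec$levels[k] - spec$levels[1])
  }
}

# Level index of each value in `values` for one spec; NA when off-grid.
level_index <- function(values, spec) {
  if (spec$kind == "categorical") {
    idx <- match(as.character(values), spec$levels)
  } else {
    idx <- match(round(as.numeric(values), 10), round(spec$levels, 10))
  }
  idx
}

#' Validate that conditions lie on the grid
#'
#' @param conditions data frame with one column per parameter code.
#' @param grid a [search_grid()].
#' @return invisibly `conditions`; signals an error naming the offending
#'   parameter code otherwise.
#' @export
assert_on_grid <- function(conditions, grid) {
  stopifnot(is.data.frame(conditions))
  missing <- setdiff(grid$codes, names(conditions))
  if (length(missing)) stop_rpe("invalid condition: missing parameter(s) %s",
                                paste(missing, collapse = ", "))
  for (code in grid$codes) {
    idx <- level_index(conditions[[code]], grid$specs[[code]])
    if (anyNA(idx)) {
      bad <- conditions[[code]][which(is.na(idx))[1]]
      stop_rpe("invalid condition: %s value '%s' is not a grid level", code, bad)
    }
  }
  invisible(conditions)
}

#' Encode conditions to the unit cube
#'
#' Maps each parameter linearly to \[0,1\] (min level -> 0, max level -> 1;
#' categorical levels at equally spaced points, so DL short/long -> 0/1).
#' This is the representation the GP surrogate and the penalizer distances
#' operate in.
#'
#' @param conditions data frame of on-grid conditions (one column per code).
#' @param grid a [search_grid()].
#' @return numeric matrix, one row per condition, columns in grid spec order.
#' @export
encode_conditions <- function(conditions, grid) {
  assert_on_grid(conditions, grid)
  out <- matrix(0, nrow(conditions), length(grid$codes),
                dimnames = list(NULL, grid$codes))
  for (code in grid$codes) {
    spec <- grid$specs[[code]]
    pos <- level_positions(spec)
    out[, code] <- pos[level_index(conditions[[code]], spec)]
  }
  out
}

#' Decode unit-cube coordinates to on-grid conditions
#'
#' Each coordinate snaps to the nearest level in encoded space; exact ties
#' snap to the lower level, for reproducibility.
#'
#' @param coords numeric matrix (or vector for a single condition) with one
#'   column per parameter, values in \[0,1\].
#' @param grid a [search_grid()].
#' @return data frame of on-grid conditions.
#' @export
decode_conditions <- function(coords, grid) {
  if (is.null(dim(coords))) coords <- matrix(coords, nrow = 1)
  stopifnot(ncol(coords) == length(grid$codes))
  out <- vector("list", length(grid$codes))
  names(out) <- grid$codes
  for (j in seq_along(grid$codes)) {
    spec <- grid$specs[[grid$codes[j]]]
    pos <- level_positions(spec)
    # nearest level; on a tie the lower level wins
    idx <- vapply(coords[, j], function(v) {
      d <- abs(pos - v)
      which(d <= min(d) + 1e-12)[1]
    }, integer(1))
    out[[j]] <- spec$levels[idx]
  }
  as.data.frame(out, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Uniform seeded sampling of grid conditions
#'
#' Free (non-contextual) parameters are sampled independently and uniformly
#' over their levels. The contextual parameter is fixed by `window`: a single
#' value pins every sample; a full context window assigns its values to well
#' slots cyclically (sample i gets `window[((i-1) %% length(window)) + 1]`);
#' `NULL` samples it uniformly like the free parameters (used e.g. for
#' Lipschitz probing of the whole space).
#'
#' @param grid a [search_grid()].
#' @param n number of conditions.
#' @param seed integer seed; identical seeds give identical output.
#' @param window `NULL`, a single context value, or a [context_window()].
#' @return data frame of `n` on-grid conditions.
#' @export
sample_uniform <- function(grid, n, seed, window = NULL) {
  stopifnot(n >= 1)
  withr::with_seed(seed, {
    out <- vector("list", length(grid$codes))
    names(out) <- grid$codes
    for (code in grid$codes) {
      spec <- grid$specs[[code]]
      if (code == grid$context_code && !is.null(window)) {
        vals <- as.numeric(unclass(window))
        out[[code]] <- rep_len(vals, n)
      } else {
        out[[code]] <- spec$levels[sample.int(length(spec$levels), n, replace = TRUE)]
      }
    }
    as.data.frame(out, check.names = FALSE, stringsAsFactors = FALSE)
  })
}

#' @export
print.search_grid <- function(x, ...) {
  cat(sprintf("<search_grid> %d parameters, cardinality %s\n",
              length(x$specs), format(grid_cardinality(x), big.mark = ",")))
  for (s in x$specs) {
    lv <- if (length(s$levels) > 8) {
      paste0(paste(head(s$levels, 4), collapse = ", "), ", ..., ",
             tail(s$levels, 1), " (", length(s$levels), " levels)")
    } else paste(s$levels, collapse = ", ")
    ctx <- if (s$kind == "contextual-grid") " [contextual]" else ""
    cat(sprintf("  %-3s %s%s: %s %s\n", s$code, s$name, ctx, lv, s$unit))
  }
  invisible(x)
}
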