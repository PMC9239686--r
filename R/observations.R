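#' Assemble an observation set
#'
#' An observation set is the running dataset D of executed conditions and
#' their pigmentation scores: a data frame with columns `round`, `plate`,
#' `well`, one column per parameter code, and `score` in \[0,1\] (`NA` for a
#' condition that was executed but could not be scored). No two rows may
#' share the same (round, plate, well).
#'
#' @param conditions data frame of on-grid conditions.
#' @param score numeric scores in \[0,1\] (NA allowed).
#' @param round round label (recycled), e.g. `"1"` or `"baseline"`.
#' @param plate,well plate (1..P) and well (1..W) indices (recycled).
#' @param grid a [search_grid()] used for validation.
#' @return a validated observation data frame.
#' @export
observation_set <- function(conditions, score, round = "1",
                            plate = 1L, well = 1L,
                            grid = default_search_grid()) {
  assert_on_grid(conditions, grid)
  n <- nrow(conditions)
  d <- cbind(
    data.frame(round = as.character(rep_len(round, n)),
               plate = as.integer(rep_len(plate, n)),
               well = as.integer(rep_len(well, n)),
               stringsAsFactors = FALSE),
    conditions[grid$codes],
    data.frame(score = as.numeric(rep_len(score, n)))
  )
  validate_observations(d, grid)
}

#' Validate an observation data frame
#'
#' @param d observation data frame (see [observation_set()]).
#' @param grid a [search_grid()].
#' @return invisibly `d`.
#' @export
validate_observations <- function(d, grid = default_search_grid()) {
  need <- c("round", "plate", "well", grid$codes, "score")
  missing <- setdiff(need, names(d))
  if (length(missing)) stop_rpe("observation table missing column(s): %s",
                                paste(missing, collapse = ", "))
  assert_on_grid(d[grid$codes], grid)
  sc <- d$score[!is.na(d$score)]
  if (length(sc) && (any(sc < 0) || any(sc > 1))) {
    stop_rpe("scores must lie in [0,1]")
  }
  key <- paste(d$round, d$plate, d$well)
  if (anyDuplicated(key)) stop_rpe("duplicate (round, plate, well) in observation table")
  invisible(d)
}

# CSV header for a parameter code. The 3P parameter is written P3_day because
# leading digits are hostile to most tabular tooling; codes outside the
# default protocol grid are written verbatim.
csv_name_for_code <- function(code) {
  map <- c(PC = "PC_nM", PP = "PP_day", DP = "DP_min", DS = "DS_mm_s",
           DL = "DL", KP = "KP_day", "3P" = "P3_day")
  ifelse(code %in% names(map), unname(map[code]), code)
}

#' Read / write observation tables as CSV
#'
#' The on-disk schema is `round, plate, well, PC_nM, PP_day, DP_min, DS_mm_s,
#' DL, KP_day, P3_day, score` (plus `provenance` for batch plans). Scores may
#' be empty (unscored / deficient wells -> `NA`).
#'
#' @param path CSV file path.
#' @param grid a [search_grid()].
#' @return `read_observations()`: a validated observation data frame.
#' @export
read_observations <- function(path, grid = default_search_grid()) {
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  cols <- csv_name_for_code(grid$codes)
  missing <- setdiff(c("round", "plate", "well", cols, "score"), names(raw))
  if (length(missing)) stop_rpe("%s: missing column(s) %s", path,
                                paste(missing, collapse = ", "))
  d <- data.frame(round = as.character(raw$round),
                  plate = as.integer(raw$plate),
                  well = as.integer(raw$well),
                  stringsAsFactors = FALSE)
  for (i in seq_along(grid$codes)) d[[grid$codes[i]]] <- raw[[cols[i]]]
  d$score <- suppressWarnings(as.numeric(raw$score))
  if ("provenance" %in% names(raw)) d$provenance <- as.character(raw$provenance)
  validate_observations(d, grid)
  d
}

#' @param d observation data frame to write.
#' @rdname read_observations
#' @return `write_observations()`: invisibly `path`.
#' @export
write_observations <- function(d, path, grid = default_search_grid()) {
  out <- data.frame(round = d$round, plate = d$plate, well = d$well,
                    stringsAsFactors = FALSE)
  for (code in grid$codes) out[[csv_name_for_code(code)]] <- d[[code]]
  out$score <- d$score
  if ("provenance" %in% names(d)) out$provenance <- d$provenance
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Drop unscored observations
#'
#' Removes rows whose score is missing (e.g. an experimentally deficient
#' well), with a warning naming how many were dropped. The surrogate is fit
#' on the remainder.
#'
#' @param d observation data frame.
#' @return `d` without NA-score rows.
#' @export
drop_unscored <- function(d) {
  bad <- is.na(d$score)
  if (any(bad)) {
    warn_rpe("dropping %d unscored observation(s)", sum(bad))
    d <- d[!bad, , drop = FALSE]
  }
  d
}
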