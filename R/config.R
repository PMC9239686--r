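#' Serialize a search grid to a config list
#'
#' One block per parameter: `code`, `name`, `kind`, `unit`, and either
#' `min`/`max`/`step` (uniformly spaced numeric grids) or an explicit
#' `levels` list.
#'
#' @param grid a [search_grid()].
#' @return a plain list suitable for [yaml::write_yaml()].
#' @export
grid_to_config <- function(grid) {
  blocks <- lapply(grid$specs, function(s) {
    b <- list(code = s$code, name = s$name, kind = s$kind, unit = s$unit,
              protocol_step = s$protocol_step)
    if (s$kind != "categorical" && length(s$levels) > 1L) {
      st <- unique(round(diff(s$levels), 10))
      if (length(st) == 1L) {
        b$min <- s$levels[1]; b$max <- s$levels[length(s$levels)]; b$step <- st
        return(b)
      }
    }
    b$levels <- as.list(s$levels)
    b
  })
  list(parameters = unname(blocks))
}

#' Build a search grid from a config list
#'
#' @param conf a list as produced by [grid_to_config()] (or parsed from the
#'   `grid:` section of a YAML config file).
#' @return a [search_grid()].
#' @export
grid_from_config <- function(conf) {
  blocks <- conf$parameters %||% conf
  specs <- lapply(blocks, function(b) {
    levels <- if (!is.null(b$levels)) {
      unlist(b$levels)
    } else {
      seq(b$min, b$max, by = b$step %||% 1)
    }
    parameter_spec(b$code, b$name %||% b$code,
                   b$kind %||% "numeric-grid", levels,
                   unit = b$unit %||% "", protocol_step = b$protocol_step %||% "")
  })
  search_grid(specs)
}

#' Read a campaign configuration from a YAML file
#'
#' Recognized top-level keys (all optional; missing keys take package
#' defaults): `rounds`, `plates`, `wells`, `noise_variance`, `seed`,
#' `window` (list of context values), `grid` (see [grid_from_config()]),
#' `surrogate` (fields of [surrogate_config()]), `policy` (fields of
#' [policy_config()]), `mc_samples`.
#'
#' @param path YAML file path.
#' @return a [campaign_config()].
#' @export
read_campaign_config <- function(path) {
  y <- yaml::read_yaml(path)
  grid <- if (!is.null(y$grid)) grid_from_config(y$grid) else default_search_grid()
  scfg <- do.call(surrogate_config,
                  y$surrogate %||% list(restarts = 2L))
  pcfg <- if (!is.null(y$policy)) do.call(policy_config, y$policy) else NULL
  window <- if (!is.null(y$window)) context_window(unlist(y$window), grid) else NULL
  campaign_config(
    rounds = y$rounds %||% 3L,
    plates = y$plates %||% 8L,
    wells = y$wells %||% 6L,
    noise_variance = y$noise_variance %||% 0.0039,
    seed = y$seed %||% 1L,
    window = window,
    grid = grid,
    surrogate = scfg,
    policy = pcfg,
    mc_samples = y$mc_samples %||% 500L
  )
}

#' Write a campaign configuration to a YAML file
#'
#' @param cfg a [campaign_config()].
#' @param path output YAML path.
#' @return invisibly `path`.
#' @export
write_campaign_config <- function(cfg, path) {
  y <- list(
    rounds = cfg$rounds, plates = cfg$plates, wells = cfg$wells,
    noise_variance = cfg$noise_variance, seed = cfg$seed,
    window = as.numeric(unclass(cfg$window)),
    mc_samples = cfg$mc_samples,
    surrogate = list(noise_variance = cfg$surrogate$noise_variance,
                     restarts = cfg$surrogate$restarts,
                     seed = cfg$surrogate$seed),
    policy = list(plates = cfg$policy$plates, wells = cfg$policy$wells,
                  candidate_pool = cfg$policy$candidate_pool,
                  seed = cfg$policy$seed,
                  duplicate_mask = cfg$policy$duplicate_mask,
                  loop_order = cfg$policy$loop_order),
    grid = grid_to_config(cfg$grid)
  )
  yaml::write_yaml(y, path)
  invisible(path)
}
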