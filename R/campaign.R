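#' Campaign configuration
#'
#' Everything needed to run a multi-round closed-loop optimization campaign:
#' geometry, noise, seeds, the initial trypsin context window, and the
#' surrogate and policy settings. All randomness flows from `seed` via
#' deterministic per-round derived seeds.
#'
#' The policy default used inside campaigns samples 1,500 candidates per
#' context value with one hill-climb sweep — the simulation-study scale this
#' package documents; pass an explicit [policy_config()] to change it.
#'
#' @param rounds number of optimization rounds M.
#' @param plates,wells batch geometry (P x W conditions per round).
#' @param noise_variance observation-noise variance of the simulated assay.
#' @param seed campaign master seed.
#' @param window initial [context_window()]; default \{5, 8, 11, 14, 17, 20\} min.
#' @param grid a [search_grid()].
#' @param surrogate a [surrogate_config()].
#' @param policy a [policy_config()]; geometry fields are overridden by
#'   `plates`/`wells`.
#' @param mc_samples Monte-Carlo draws per context value for the context
#'   window decision.
#' @param initial_observations optional baseline observation data frame; when
#'   supplied, its top conditions are injected as round-1 controls (operator
#'   mode); in pure simulation round 1 has no controls.
#' @return an object of class `campaign_config`.
#' @export
campaign_config <- function(rounds = 3L, plates = 8L, wells = 6L,
                            noise_variance = 0.0039, seed = 1L,
                            window = NULL, grid = default_search_grid(),
                            surrogate = surrogate_config(),
                            policy = NULL, mc_samples = 500L,
                            initial_observations = NULL) {
  stopifnot(rounds >= 1)
  window <- window %||% context_window(seq(5, by = 3, length.out = wells), grid)
  policy <- policy %||% policy_config(candidate_pool = 1500L)
  policy$plates <- as.integer(plates)
  policy$wells <- as.integer(wells)
  if (length(unclass(window)) != wells) {
    stop_rpe("window length (%d) must equal wells (%d)", length(unclass(window)), wells)
  }
  structure(
    list(rounds = as.integer(rounds), plates = as.integer(plates),
         wells = as.integer(wells), noise_variance = noise_variance,
         seed = as.integer(seed), window = window, grid = grid,
         surrogate = surrogate, policy = policy,
         mc_samples = as.integer(mc_samples),
         initial_observations = initial_observations),
    class = "campaign_config"
  )
}

# Round-1 plan: uniform sampling with the context window assigned per well.
# sample_uniform() assigns window values cyclically, so sample i belongs to
# well slot ((i-1) %% wells) + 1.
uniform_plan <- function(grid, window, plates, wells, seed) {
  n <- plates * wells
  cond <- sample_uniform(grid, n, seed = seed, window = window)
  plan <- cbind(
    data.frame(plate = ((seq_len(n) - 1L) %/% wells) + 1L,
               well = ((seq_len(n) - 1L) %% wells) + 1L),
    cond,
    data.frame(provenance = "generated", stringsAsFactors = FALSE)
  )
  rownames(plan) <- NULL
  structure(plan, class = c("batch_plan", "data.frame"), window = window, seed = seed)
}

#' Run a closed-loop optimization campaign on a response oracle
#'
#' Round 1 queries are drawn by uniform sampling over the grid (with the
#' context window fixed per well); each later round fits the GP surrogate to
#' all data so far, builds the EI acquisition, generates the next batch with
#' the BCLP policy, injects the previous round's top-two conditions as
#' positive controls, observes all wells on the oracle, and finally decides
#' whether the trypsin context window stays or shifts for the following
#' round.
#'
#' @param cfg a [campaign_config()].
#' @param oracle a [toy_response()].
#' @return an object of class `campaign_history`: per-round list of `plan`,
#'   `observations`, `window`, `decision`, plus `observations` (all rounds
#'   pooled), `best_trajectory` (best-so-far after each round), and
#'   `final_best`.
#' @examples
#' \donttest{
#' cfg <- campaign_config(rounds = 2, plates = 2, wells = 3,
#'                        policy = policy_config(candidate_pool = 100),
#'                        mc_samples = 100, seed = 1)
#' hist <- run_campaign(cfg, toy_response(cfg$grid))
#' hist$best_trajectory
#' }
#' @export
run_campaign <- function(cfg, oracle = toy_response(cfg$grid)) {
  stopifnot(inherits(cfg, "campaign_config"), inherits(oracle, "toy_response"))
  grid <- cfg$grid
  window <- cfg$window
  D <- NULL
  s <- NULL
  rounds <- vector("list", cfg$rounds)
  best_trajectory <- numeric(cfg$rounds)

  for (t in seq_len(cfg$rounds)) {
    seed_t <- derive_seed(cfg$seed, t)
    plan <- tryCatch({
      if (is.null(s)) {
        p <- uniform_plan(grid, window, cfg$plates, cfg$wells, seed_t)
        if (!is.null(cfg$initial_observations)) {
          p <- inject_controls(p, cfg$initial_observations, grid)
        }
        p
      } else {
        pol <- cfg$policy
        pol$seed <- seed_t
        p <- generate_batch(s, grid, window, pol, D)
        inject_controls(p, rounds[[t - 1L]]$observations, grid)
      }
    }, error = function(e) {
      warn_rpe("round %d failed (%s); aborting with partial history", t,
               conditionMessage(e))
      NULL
    })
    if (is.null(plan)) {
      rounds <- rounds[seq_len(t - 1L)]
      best_trajectory <- best_trajectory[seq_len(t - 1L)]
      break
    }

    scores <- observe(oracle, plan[grid$codes], seed = derive_seed(seed_t, 555L),
                      noise_variance = cfg$noise_variance)
    obs <- observation_set(plan[grid$codes], scores, round = as.character(t),
                           plate = plan$plate, well = plan$well, grid = grid)
    D <- if (is.null(D)) obs else rbind(D, obs)
    best_trajectory[t] <- max(D$score, na.rm = TRUE)

    scfg <- cfg$surrogate
    scfg$seed <- derive_seed(seed_t, 31L)
    s <- fit_surrogate(D, grid, scfg)
    acq <- make_acquisition(s)
    decision <- adjust_context(acq, grid, window, mc_samples = cfg$mc_samples,
                               seed = derive_seed(seed_t, 777L))
    rounds[[t]] <- list(round = t, plan = plan, observations = obs,
                        window = window, decision = decision, seed = seed_t)
    window <- decision$next_window
  }

  structure(
    list(rounds = rounds, observations = D,
         best_trajectory = cummax(best_trajectory),
         final_best = max(D$score, na.rm = TRUE), config = cfg),
    class = "campaign_history"
  )
}

#' Uniform random-search baseline at equal budget
#'
#' Draws `n` conditions uniformly over the full grid (context value included)
#' and observes them under the same noise model. The comparison baseline for
#' the optimizer's efficacy.
#'
#' @param n evaluation budget.
#' @param oracle a [toy_response()].
#' @param seed integer seed.
#' @param noise_variance observation-noise variance.
#' @param grid a [search_grid()].
#' @return list with `best` (max observed score) and `observations`.
#' @export
run_random_search <- function(n, oracle, seed = 1L, noise_variance = 0.0039,
                              grid = oracle$grid) {
  cond <- sample_uniform(grid, n, seed = seed, window = NULL)
  scores <- observe(oracle, cond, seed = derive_seed(seed, 123L),
                    noise_variance = noise_variance)
  list(best = max(scores),
       observations = cbind(cond, data.frame(score = scores)))
}

#' @export
print.campaign_history <- function(x, ...) {
  cat(sprintf("<campaign_history> %d rounds, %d observations, best %.3f\n",
              length(x$rounds), nrow(x$observations), x$final_best))
  cat("  best-so-far:", paste(sprintf("%.3f", x$best_trajectory), collapse = " -> "), "\n")
  for (r in x$rounds) {
    cat(sprintf("  round %d: window {%s}, context %s\n", r$round,
                paste(unclass(r$window), collapse = ","), r$decision$action))
  }
  invisible(x)
}

#' Summarize a campaign history
#'
#' @param object a `campaign_history`.
#' @param ... unused.
#' @return data frame with one row per round: best score in round,
#'   best-so-far, context action, and window.
#' @export
summary.campaign_history <- function(object, ...) {
  data.frame(
    round = vapply(object$rounds, function(r) r$round, numeric(1)),
    best_in_round = vapply(object$rounds,
                           function(r) max(r$observations$score, na.rm = TRUE),
                           numeric(1)),
    best_so_far = object$best_trajectory,
    context_action = vapply(object$rounds, function(r) r$decision$action,
                            character(1)),
    window = vapply(object$rounds,
                    function(r) paste(unclass(r$window), collapse = ","),
                    character(1))
  )
}

#' Plan the next round from a results CSV (operator-in-the-loop mode)
#'
#' Reads an observation CSV covering the rounds executed so far, fits the
#' surrogate to the scored rows (unscored rows are dropped with a warning),
#' generates the next BCLP batch, injects the latest round's top-two
#' conditions as controls, decides the next context window, writes the plan
#' CSV (observation schema with empty scores plus a provenance column), and
#' appends the context decision to a JSON-lines log. Deterministic: the same
#' inputs and seed give a byte-identical plan file.
#'
#' @param results_csv path to the observation CSV.
#' @param out path for the plan CSV.
#' @param window current [context_window()].
#' @param cfg a [campaign_config()] (its `rounds` field is ignored here).
#' @param log optional path to a JSON-lines campaign log to append to.
#' @return invisibly, a list with the `plan`, the context `decision`, and
#'   the next round label.
#' @export
plan_next_round <- function(results_csv, out, window = NULL,
                            cfg = campaign_config(), log = NULL) {
  grid <- cfg$grid
  window <- window %||% cfg$window
  D <- read_observations(results_csv, grid)
  scored <- drop_unscored(D)
  if (nrow(scored) == 0L) stop_rpe("no scored observations in %s", results_csv)

  scfg <- cfg$surrogate
  scfg$seed <- derive_seed(cfg$seed, 31L)
  s <- fit_surrogate(scored, grid, scfg)

  pol <- cfg$policy
  pol$seed <- cfg$seed
  plan <- generate_batch(s, grid, window, pol, scored)

  round_nums <- suppressWarnings(as.numeric(D$round))
  latest <- if (all(is.na(round_nums))) {
    D[D$round == D$round[nrow(D)], , drop = FALSE]
  } else {
    D[round_nums == max(round_nums, na.rm = TRUE), , drop = FALSE]
  }
  plan <- inject_controls(plan, latest, grid)
  next_round <- if (all(is.na(round_nums))) "next" else
    as.character(max(round_nums, na.rm = TRUE) + 1)

  acq <- make_acquisition(s)
  decision <- adjust_context(acq, grid, window, mc_samples = cfg$mc_samples,
                             seed = derive_seed(cfg$seed, 777L))

  out_df <- observation_set(plan[grid$codes], NA_real_, round = next_round,
                            plate = plan$plate, well = plan$well, grid = grid)
  out_df$provenance <- plan$provenance
  write_observations(out_df, out, grid)

  if (!is.null(log)) {
    line <- jsonlite::toJSON(
      list(round = next_round, seed = cfg$seed,
           window = as.numeric(unclass(window)),
           V = decision$V, V_minus = decision$V_minus, V_plus = decision$V_plus,
           R_minus = decision$R_minus, R_plus = decision$R_plus,
           action = decision$action,
           next_window = as.numeric(unclass(decision$next_window))),
      auto_unbox = TRUE, digits = NA, na = "null")
    cat(line, "\n", sep = "", file = log, append = TRUE)
  }
  invisible(list(plan = plan, decision = decision, next_round = next_round,
                 out = out))
}
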