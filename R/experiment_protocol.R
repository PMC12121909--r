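# Orchestration of the full experimental paradigm for one simulated
# participant: 15 unperturbed baseline trials, a perturbed block until 60
# successes (or the trial budget runs out), one unannounced catch trial,
# five more perturbed trials, and 15 announced de-adaptation trials.

#' Protocol configuration
#'
#' @param n_baseline unperturbed baseline trials.
#' @param required_successes successful perturbed trials ending the block.
#' @param n_post_catch_perturbed perturbed trials after the catch trial.
#' @param n_deadaptation announced unperturbed trials at the end.
#' @param max_perturbed_trials trial budget of the perturbed block; a run
#'   that exhausts it is marked not completed.
#' @param normalization_target grid size for the normalized trial index.
#' @return an object of class `protocol_config`.
#' @export
protocol_config <- function(n_baseline = 15, required_successes = 60,
                            n_post_catch_perturbed = 5, n_deadaptation = 15,
                            max_perturbed_trials = 300,
                            normalization_target = 84) {
  stopifnot(n_baseline >= 1, required_successes >= 1,
            n_post_catch_perturbed >= 1, n_deadaptation >= 1,
            max_perturbed_trials >= 1, normalization_target >= 1)
  structure(list(n_baseline = n_baseline,
                 required_successes = required_successes,
                 n_post_catch_perturbed = n_post_catch_perturbed,
                 n_deadaptation = n_deadaptation,
                 max_perturbed_trials = max_perturbed_trials,
                 normalization_target = normalization_target),
            class = "protocol_config")
}

#' Normalized trial index
#'
#' Maps trial `trial_number` of a perturbed block with `n_perturbed` trials
#' onto the common grid: `(trial_number / n_perturbed) * target`.
#'
#' @param trial_number trial number within the block (1-based).
#' @param n_perturbed number of perturbed trials in the block.
#' @param target grid size (84 by default).
#' @return real-valued normalized index.
#' @export
normalize_trial_index <- function(trial_number, n_perturbed, target = 84) {
  if (any(n_perturbed <= 0)) {
    stop("normalize_trial_index: n_perturbed must be positive")
  }
  stopifnot(all(trial_number >= 1), all(trial_number <= n_perturbed))
  trial_number / n_perturbed * target
}

# one executed + scored trial; returns scalar record and updated learners
.run_one_trial <- function(block, index, policy, model, gains, eco, params,
                           rew_spec, keep, restore = "safe") {
  bias <- if (block %in% c("perturbed", "post_catch")) eco$safety_bias else 0
  plan <- sample_plan(policy, safety_bias = bias)
  trial <- simulate_trial(plan, model, gains, params)
  model <- trial$model
  s_cost <- safety_cost(trial, params)
  e_cost <- effort_cost(trial, params)
  reward <- compose_reward(trial$outcome, rew_spec, s_cost, e_cost)
  # a success achieved under the ecological safety bias is credited to the
  # bias, not the policy; failed trials let the policy absorb the biased
  # exploration, so plan learning happens during failures
  shift_credit <- if (trial$outcome == "success") bias * policy$forward_shift
                  else 0
  policy <- policy_update(policy, plan, reward, bias_shift = shift_credit)
  tr <- eco_transition(eco, trial$outcome, plan, policy, restore = restore,
                       cost = s_cost)
  eco <- tr$state
  policy <- tr$policy
  met <- compute_metrics(trial$trajectory,
                         rise = plan$end[2] - plan$start[2])
  rec <- list(index = index, block = block, outcome = trial$outcome,
              mode = rew_spec$active_cost, reward = reward,
              safety_cost = s_cost, effort_cost = e_cost,
              trajectory_area = met$trajectory_area,
              initial_trajectory_area = met$initial_trajectory_area,
              smoothness = met$smoothness,
              forward_peak = met$forward_peak,
              backward_peak = met$backward_peak,
              feedback_multiplier_mean = mean(trial$multiplier),
              plan_offsets = plan$via_offsets,
              plan = plan,
              trajectory = if (keep) trial$trajectory else NULL,
              commands = if (keep) trial$commands else NULL)
  list(rec = rec, policy = policy, model = model, eco = eco)
}

.records_df <- function(trials) {
  data.frame(index = vapply(trials, `[[`, 0, "index"),
             block = vapply(trials, `[[`, "", "block"),
             outcome = vapply(trials, `[[`, "", "outcome"),
             mode = vapply(trials, `[[`, "", "mode"),
             reward = vapply(trials, `[[`, 0, "reward"),
             trajectory_area = vapply(trials, `[[`, 0, "trajectory_area"),
             initial_trajectory_area =
               vapply(trials, `[[`, 0, "initial_trajectory_area"),
             smoothness = vapply(trials, `[[`, 0, "smoothness"),
             forward_peak = vapply(trials, `[[`, 0, "forward_peak"),
             backward_peak = vapply(trials, `[[`, 0, "backward_peak"),
             feedback_multiplier_mean =
               vapply(trials, `[[`, 0, "feedback_multiplier_mean"),
             plan_mid_offset =
               vapply(trials, function(r) r$plan_offsets[2], 0))
}

#' Run the full experimental paradigm for one simulated participant
#'
#' Executes baseline, perturbed, catch, post-catch and de-adaptation blocks
#' with all learning mechanisms active. The catch trial silently sets the
#' perturbation gain to zero; the de-adaptation block additionally resets
#' the motor plan to the memorized unperturbed plan and shifts the internal
#' model towards its unperturbed state by `rho`.
#'
#' @param config a configuration list as returned by [default_config()];
#'   `config$protocol` may be a [protocol_config()].
#' @param seed integer seed; all stochasticity of the run flows from it.
#' @param keep_trajectories retain full per-trial trajectories (memory
#'   heavy; population runs drop them).
#' @return an object of class `run_result`: `trials` (list of records),
#'   `trials_df` (per-trial scalars), `completed`, `n_failures`,
#'   `first_success_trial`, `n_perturbed`, `confidence_threshold`, `seed`.
#' @export
run_experiment <- function(config = default_config(), seed = 1,
                           keep_trajectories = FALSE) {
  set.seed(seed)
  proto <- config$protocol
  params <- config$body
  params0 <- params
  params0$perturbation_gain_K <- 0

  policy <- config$policy
  model <- config$model
  gains <- config$gains
  eco <- ecological_state(bias_decay_steps = config$eco$bias_decay_steps)
  rw <- config$eco

  spec_safe <- reward_spec(rw$success_bonus, rw$safety_weight,
                           rw$effort_weight, "safety")
  spec_eff <- reward_spec(rw$success_bonus, rw$safety_weight,
                          rw$effort_weight, "effort")

  trials <- list()
  idx <- 0

  # baseline: unperturbed, effort-driven; acquires the unperturbed memory
  for (i in seq_len(proto$n_baseline)) {
    idx <- idx + 1
    st <- .run_one_trial("baseline", idx, policy, model, gains, eco,
                         params0, spec_eff, keep_trajectories)
    policy <- st$policy; model <- st$model
    trials[[idx]] <- st$rec
    if (st$rec$outcome == "success") {
      eco$memory$unperturbed_plan <- st$rec$plan
    }
  }

  # perturbed block until the required successes or the budget runs out;
  # the reward baseline restarts with the new environment and cost context
  eco$mode <- "safe"; eco$success_count <- 0; eco$safety_bias <- 0
  policy$baseline <- NA_real_
  prev_mode <- "safe"
  n_perturbed <- 0
  first_success <- NA_integer_
  while (eco$success_count < proto$required_successes &&
         n_perturbed < proto$max_perturbed_trials) {
    idx <- idx + 1
    n_perturbed <- n_perturbed + 1
    if (eco$mode != prev_mode) {
      # the two costs live on different scales; the running-average reward
      # baseline restarts when the arbitration switches them
      policy$baseline <- NA_real_
      prev_mode <- eco$mode
    }
    spec <- if (eco$mode == "safe") spec_safe else spec_eff
    st <- .run_one_trial("perturbed", idx, policy, model, gains, eco,
                         params, spec, keep_trajectories)
    policy <- st$policy; model <- st$model; eco <- st$eco
    trials[[idx]] <- st$rec
    if (is.na(first_success) && st$rec$outcome == "success") {
      first_success <- n_perturbed
    }
  }
  completed <- eco$success_count >= proto$required_successes

  # unannounced catch trial: the pull is silently absent
  idx <- idx + 1
  spec <- if (eco$mode == "safe") spec_safe else spec_eff
  st <- .run_one_trial("catch", idx, policy, model, gains, eco, params0,
                       spec, TRUE)
  policy <- st$policy; model <- st$model; eco <- st$eco
  trials[[idx]] <- st$rec

  # five more perturbed trials
  for (i in seq_len(proto$n_post_catch_perturbed)) {
    idx <- idx + 1
    spec <- if (eco$mode == "safe") spec_safe else spec_eff
    st <- .run_one_trial("post_catch", idx, policy, model, gains, eco,
                         params, spec, keep_trajectories)
    policy <- st$policy; model <- st$model; eco <- st$eco
    trials[[idx]] <- st$rec
  }

  # announced de-adaptation: plan reset to the unperturbed memory, internal
  # model partially shifted back, and the feedback-gain state returned to
  # its unperturbed (near-zero) level -- the announcement restores trust in
  # the feed-forward pathway, so the residual internal model expresses
  # itself uncorrected in the first trial
  if (!is.null(eco$memory$unperturbed_plan)) {
    policy$mean <- eco$memory$unperturbed_plan$via_offsets
  }
  model <- shift_toward_unperturbed(model, config$model_rho)
  model$prediction_error_trace <- 0
  eco$safety_bias <- 0
  policy$baseline <- NA_real_
  for (i in seq_len(proto$n_deadaptation)) {
    idx <- idx + 1
    st <- .run_one_trial("deadaptation", idx, policy, model, gains, eco,
                         params0, spec_eff, keep_trajectories,
                         restore = "unperturbed")
    policy <- st$policy; model <- st$model; eco <- st$eco
    trials[[idx]] <- st$rec
  }

  df <- .records_df(trials)
  fail <- df$outcome != "success" & df$block %in% c("perturbed", "post_catch")
  structure(list(trials = trials, trials_df = df, completed = completed,
                 n_failures = sum(fail),
                 first_success_trial = first_success,
                 n_perturbed = n_perturbed,
                 confidence_threshold = eco$confidence_threshold,
                 policy = policy, model = model, seed = seed),
            class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat("<run_result> seed", x$seed, "-", nrow(x$trials_df), "trials,",
      x$n_failures, "failures, first success at perturbed trial",
      x$first_success_trial, "\n")
  cat("  completed:", x$completed, " confidence threshold:",
      x$confidence_threshold, "\n")
  invisible(x)
}

# per-run metric series on the normalized 1..target grid (perturbed block
# before the catch trial), gaps filled by linear interpolation
.binned_series <- function(run, metric, target = 84) {
  df <- run$trials_df[run$trials_df$block == "perturbed", ]
  n <- nrow(df)
  bins <- pmin(pmax(round(normalize_trial_index(seq_len(n), n, target)), 1),
               target)
  v <- tapply(df[[metric]], bins, mean)
  out <- rep(NA_real_, target)
  out[as.integer(names(v))] <- v
  if (anyNA(out)) {
    out <- approx(which(!is.na(out)), out[!is.na(out)],
                  xout = seq_len(target), rule = 2)$y
  }
  out
}

#' Metric series of a run on the normalized trial grid
#'
#' @param run a [run_experiment()] result.
#' @param metric column of `run$trials_df` (e.g. `"trajectory_area"`), or
#'   `"failure"` for the failure indicator.
#' @param target grid size.
#' @return numeric vector of length `target`.
#' @export
normalized_series <- function(run, metric = "trajectory_area", target = 84) {
  if (metric == "failure") {
    run$trials_df$failure <- as.numeric(run$trials_df$outcome != "success")
  }
  .binned_series(run, metric, target)
}

#' Run a population of independent simulated participants
#'
#' @param n_runs number of simulated participants.
#' @param base_seed integer; run `i` uses seed `base_seed + i`.
#' @param config configuration list, see [default_config()].
#' @return an object of class `population_result`: `runs` (list of
#'   [run_experiment()] results without trajectories) and `summary` with
#'   population statistics and per-trial-index metric averages.
#' @export
run_population <- function(n_runs, base_seed = 1,
                           config = default_config()) {
  stopifnot(n_runs >= 1)
  runs <- lapply(seq_len(n_runs), function(i) {
    run_experiment(config, seed = base_seed + i, keep_trajectories = FALSE)
  })
  target <- config$protocol$normalization_target
  series <- function(metric) {
    t(vapply(runs, normalized_series, numeric(target), metric = metric,
             target = target))
  }
  nf <- vapply(runs, `[[`, 0, "n_failures")
  fs <- vapply(runs, `[[`, 0, "first_success_trial")
  comp <- vapply(runs, `[[`, TRUE, "completed")
  summary <- list(
    n_runs = n_runs,
    completed = sum(comp),
    failures_mean = mean(nf[comp]), failures_sd = sd(nf[comp]),
    first_success_mean = mean(fs[comp], na.rm = TRUE),
    first_success_sd = sd(fs[comp], na.rm = TRUE),
    series = list(trajectory_area = series("trajectory_area"),
                  initial_trajectory_area =
                    series("initial_trajectory_area"),
                  smoothness = series("smoothness"),
                  feedback_multiplier_mean =
                    series("feedback_multiplier_mean"),
                  failure = series("failure")))
  structure(list(runs = runs, summary = summary, base_seed = base_seed),
            class = "population_result")
}

#' @export
print.population_result <- function(x, ...) {
  s <- x$summary
  cat("<population_result>", s$n_runs, "runs,", s$completed, "completed\n")
  cat(sprintf("  failures: %.2f +/- %.2f\n", s$failures_mean, s$failures_sd))
  cat(sprintf("  first success: %.2f +/- %.2f trials\n",
              s$first_success_mean, s$first_success_sd))
  invisible(x)
}
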