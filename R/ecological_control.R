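# Top-level arbitration: which cost the reinforcement learner optimizes.
# Failure switches learning to a conservative safe mode (restore a memorized
# safe plan, bias sampling forward); a run-specific count of successes
# ("confidence", drawn once from N(50, 50) truncated at 1) switches the
# active cost from safety to movement effort.

#' Ecological controller state
#'
#' @param confidence_threshold number of successes needed before the effort
#'   cost is engaged; when `NULL`, drawn once from Normal(50, 50) truncated
#'   below at 1.
#' @param mode `"safe"` or `"efficient"`.
#' @param success_count successes accumulated so far.
#' @param safety_bias current sampling bias towards safety in `[0, 1]`.
#' @param bias_decay_steps successful trials over which a full bias decays
#'   back to zero.
#' @return an object of class `ecological_state` with fields `mode`,
#'   `success_count`, `confidence_threshold`, `safety_bias`, and a `memory`
#'   holding `safe_plan` and `unperturbed_plan`.
#' @export
ecological_state <- function(confidence_threshold = NULL, mode = "safe",
                             success_count = 0, safety_bias = 0,
                             bias_decay_steps = 3) {
  if (is.null(confidence_threshold)) {
    confidence_threshold <- max(1, round(rnorm(1, 50, 50)))
  }
  stopifnot(confidence_threshold >= 1, mode %in% c("safe", "efficient"),
            success_count >= 0, safety_bias >= 0, safety_bias <= 1)
  structure(list(mode = mode, success_count = success_count,
                 confidence_threshold = confidence_threshold,
                 safety_bias = safety_bias,
                 bias_decay_steps = bias_decay_steps,
                 memory = list(safe_plan = NULL, safe_cost = NULL,
                               unperturbed_plan = NULL)),
            class = "ecological_state")
}

#' Reward specification for the composite reward
#'
#' @param success_bonus bonus granted on success.
#' @param safety_weight,effort_weight weights of the two costs.
#' @param active_cost `"safety"` or `"effort"`.
#' @return an object of class `reward_spec`.
#' @export
reward_spec <- function(success_bonus = 1, safety_weight = 0.5,
                        effort_weight = 0.5, active_cost = "safety") {
  stopifnot(safety_weight >= 0, effort_weight >= 0,
            active_cost %in% c("safety", "effort"))
  structure(list(success_bonus = success_bonus,
                 safety_weight = safety_weight,
                 effort_weight = effort_weight, active_cost = active_cost),
            class = "reward_spec")
}

#' Safety cost of a trial
#'
#' A decreasing function of the minimum forward zero-moment-point margin:
#' `(foot_support_front - min_t zmp_x) / support_length`, clipped below at
#' zero, plus the forward overshoot `(max_t zmp_x - foot_support_front)+ /
#' support_length`. It is 0 when the ZMP hugs the forward support bound
#' (maximal margin against the backward pull) and 1 when it sits at the
#' backward bound; over-leaning past the forward bound is unsafe too, so
#' the cost has its minimum at the support edge rather than rewarding
#' unbounded lean.
#'
#' @param trial a `trial_record` (or any list with a `trajectory` having a
#'   `zmp_x` column).
#' @param params a [body_params()].
#' @return non-negative dimensionless cost.
#' @export
safety_cost <- function(trial, params) {
  z <- trial$trajectory$zmp_x
  stopifnot(length(z) > 0)
  len <- params$foot_support_front - params$foot_support_back
  max(0, (params$foot_support_front - min(z)) / len) +
    3 * max(0, (max(z) - params$foot_support_front) / len)
}

#' Effort cost of a trial
#'
#' Time integral of the squared actuator commands, each normalized by the
#' gravity-support scale (`m g` for the prismatic force, `0.1 m g` m for the
#' ankle torque), over the trial.
#'
#' @param trial a `trial_record` with a `commands` data frame.
#' @param params a [body_params()].
#' @return non-negative dimensionless cost.
#' @export
effort_cost <- function(trial, params) {
  cmd <- trial$commands
  stopifnot(nrow(cmd) > 0)
  f0 <- params$mass * params$gravity
  tau0 <- 0.1 * params$mass * params$gravity
  v <- (cmd$force_prismatic / f0)^2 + (cmd$torque_ankle / tau0)^2
  n <- length(v)
  if (n < 2) return(0)
  sum((v[-1] + v[-n]) / 2) * params$dt
}

#' Composite switching reward
#'
#' `success_bonus * 1[success] - w_active * active_cost`; a failure forfeits
#' the bonus but still pays the active cost.
#'
#' @param outcome outcome string; `"success"` or a failure label.
#' @param spec a [reward_spec()].
#' @param safety safety cost of the trial.
#' @param effort effort cost of the trial.
#' @return scalar reward.
#' @export
compose_reward <- function(outcome, spec, safety, effort) {
  stopifnot(safety >= 0, effort >= 0)
  bonus <- if (identical(outcome, "success")) spec$success_bonus else 0
  cost <- if (spec$active_cost == "safety") {
    spec$safety_weight * safety
  } else {
    spec$effort_weight * effort
  }
  bonus - cost
}

#' Ecological state transition after a trial
#'
#' On success: increment the success ledger, memorize the executed plan as
#' the safe plan while in safe mode, decay the safety bias, and switch to
#' the efficient mode once the confidence threshold is reached. On failure:
#' revert to safe mode (confidence progress is retained), set the safety
#' bias high, and reset the policy mean to the memorized restore plan when
#' one exists (the safe plan during perturbed blocks; pass the unperturbed
#' memory via `restore` for announced perturbation-free blocks).
#'
#' @param state an [ecological_state()].
#' @param outcome outcome string of the executed trial.
#' @param executed_plan the executed [motor_plan()].
#' @param policy the current [policy_distribution()].
#' @param restore which memory to restore on failure: `"safe"` or
#'   `"unperturbed"`.
#' @param cost safety cost of the executed trial; the safe-plan memory only
#'   adopts a new successful plan when it was at least as safe as the
#'   remembered one, so the restore anchor does not drift onto marginal
#'   plans.
#' @return list with the updated `state` and `policy`.
#' @export
eco_transition <- function(state, outcome, executed_plan, policy,
                           restore = c("safe", "unperturbed"),
                           cost = NULL) {
  restore <- match.arg(restore)
  if (identical(outcome, "success")) {
    state$success_count <- state$success_count + 1
    if (state$mode == "safe") {
      old <- state$memory$safe_cost
      if (is.null(cost) || is.null(old) || cost <= old) {
        state$memory$safe_plan <- executed_plan
        state$memory$safe_cost <- cost
      }
    }
    state$safety_bias <- max(0, state$safety_bias - 1 / state$bias_decay_steps)
    if (state$success_count >= state$confidence_threshold) {
      state$mode <- "efficient"
    }
  } else {
    state$mode <- "safe"
    # bias towards safety only after a backward fall (in the direction of
    # the pull); after a forward fall more lean is not safer
    state$safety_bias <- if (identical(outcome, "failure_forward")) 0 else 1
    mem <- if (restore == "safe") state$memory$safe_plan else
      state$memory$unperturbed_plan
    if (!is.null(mem)) {
      policy$mean <- pmin(pmax(mem$via_offsets, policy$bounds[1]),
                          policy$bounds[2])
    }
  }
  list(state = state, policy = policy)
}
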