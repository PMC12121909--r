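# Motor plans are COM-space splines: the vertical profile is a rest-to-rest
# minimum-jerk rise and the horizontal profile is a clamped cubic spline
# through three via points anchored at 25/50/75 % of the movement time
# (about 10/50/90 % of the rise under the minimum-jerk vertical profile).
# Only the three horizontal via-point offsets are learned; the stand
# position inherits the final offset, so an adapted plan ends in a held
# forward lean. Anchoring the horizontal spline in time keeps the lean
# build-up slow while the body is low and the pull still weak; tying it to
# the vertical rise instead concentrates horizontal accelerations at peak
# vertical velocity, which no admissible plan survives.

# clamped cubic spline through (yk, xk) with zero end slopes; returns a
# function evaluating value and first/second derivative
.clamped_spline <- function(yk, xk, d0 = 0, dn = 0) {
  n <- length(yk)
  h <- diff(yk)
  A <- matrix(0, n, n)
  rhs <- numeric(n)
  A[1, 1] <- 2 * h[1]; A[1, 2] <- h[1]
  rhs[1] <- 6 * ((xk[2] - xk[1]) / h[1] - d0)
  for (i in 2:(n - 1)) {
    A[i, i - 1] <- h[i - 1]
    A[i, i] <- 2 * (h[i - 1] + h[i])
    A[i, i + 1] <- h[i]
    rhs[i] <- 6 * ((xk[i + 1] - xk[i]) / h[i] - (xk[i] - xk[i - 1]) / h[i - 1])
  }
  A[n, n - 1] <- h[n - 1]; A[n, n] <- 2 * h[n - 1]
  rhs[n] <- 6 * (dn - (xk[n] - xk[n - 1]) / h[n - 1])
  m <- solve(A, rhs)
  function(y, deriv = 0) {
    i <- pmin(pmax(findInterval(y, yk), 1L), n - 1L)
    hi <- h[i]; ya <- yk[i]; yb <- yk[i + 1]
    if (deriv == 0) {
      m[i] * (yb - y)^3 / (6 * hi) + m[i + 1] * (y - ya)^3 / (6 * hi) +
        (xk[i] / hi - m[i] * hi / 6) * (yb - y) +
        (xk[i + 1] / hi - m[i + 1] * hi / 6) * (y - ya)
    } else if (deriv == 1) {
      -m[i] * (yb - y)^2 / (2 * hi) + m[i + 1] * (y - ya)^2 / (2 * hi) +
        (xk[i + 1] - xk[i]) / hi - (m[i + 1] - m[i]) * hi / 6
    } else {
      m[i] * (yb - y) / hi + m[i + 1] * (y - ya) / hi
    }
  }
}

#' Three-via-point motor plan
#'
#' @param via_offsets numeric length-3, horizontal offsets (m) of the via
#'   points from the squat COM vertical, anchored at 25/50/75 % of the
#'   movement time. The stand position inherits the final offset
#'   (`end[1] = start[1] + via_offsets[3]`): an adapted plan ends in a held
#'   forward lean.
#' @param start COM position `(x, y)` (m) in squat.
#' @param end COM position in stand; the `x` entry is derived from
#'   `via_offsets[3]`, only the height is taken from this argument.
#' @param duration movement duration (s).
#' @return an object of class `motor_plan`.
#' @export
motor_plan <- function(via_offsets = c(0, 0, 0), start = c(0, 0.55),
                       end = c(0, 1.05), duration = 1.2) {
  stopifnot(length(via_offsets) == 3, duration > 0, start[2] < end[2])
  via_offsets <- as.numeric(via_offsets)
  structure(list(via_offsets = via_offsets, start = start,
                 end = c(start[1] + via_offsets[3], end[2]),
                 duration = duration,
                 via_t_frac = c(0.25, 0.5, 0.75)),
            class = "motor_plan")
}

#' Gaussian policy over via-point offsets
#'
#' The policy is a diagonal Gaussian over the three horizontal via-point
#' offsets, updated by plain REINFORCE with a running-average reward
#' baseline. The exploration standard deviation is held fixed.
#'
#' @param mean numeric length-3, mean via-point offsets (m).
#' @param stdev numeric length-3, exploration standard deviation (m).
#' @param learning_rate REINFORCE step size.
#' @param baseline running-average reward baseline; `NA` initializes it to
#'   the first observed reward.
#' @param bounds numeric length-2, admissible offset interval (m).
#' @param forward_shift forward bias (m, per via point) applied per unit
#'   safety bias when sampling; safety-biased samples lean further against
#'   the perturbation, with the later via points shifted more so the lean is
#'   built up gradually.
#' @param start,end,duration plan geometry, see [motor_plan()].
#' @return an object of class `policy_distribution`.
#' @export
policy_distribution <- function(mean = c(0, 0, 0), stdev = rep(0.005, 3),
                                learning_rate = 1e-4, baseline = NA_real_,
                                bounds = c(-0.05, 0.35),
                                forward_shift = c(0.003, 0.0075, 0.009),
                                start = c(0, 0.55),
                                end = c(0, 1.05), duration = 1.2) {
  stopifnot(all(stdev > 0), bounds[1] < bounds[2])
  structure(list(mean = as.numeric(mean), stdev = as.numeric(stdev),
                 learning_rate = learning_rate, baseline = baseline,
                 bounds = bounds, forward_shift = forward_shift,
                 start = start, end = end, duration = duration),
            class = "policy_distribution")
}

#' Sample a motor plan from the policy
#'
#' Via-point offsets are drawn from the Gaussian policy, shifted forward by
#' `safety_bias * forward_shift`, and clipped to the admissible bounds.
#'
#' @param policy a [policy_distribution()].
#' @param rng_seed optional integer seed for a reproducible draw; when `NULL`
#'   the current RNG stream is used.
#' @param safety_bias safety bias in `[0, 1]`.
#' @return a [motor_plan()].
#' @export
sample_plan <- function(policy, rng_seed = NULL, safety_bias = 0) {
  stopifnot(safety_bias >= 0, safety_bias <= 1)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  a <- rnorm(3, policy$mean + safety_bias * policy$forward_shift,
             policy$stdev)
  a <- pmin(pmax(a, policy$bounds[1]), policy$bounds[2])
  motor_plan(a, policy$start, policy$end, policy$duration)
}

#' Sample the desired COM trajectory of a plan
#'
#' The vertical profile is a rest-to-rest minimum-jerk rise; the horizontal
#' profile follows the clamped via-point spline, so positions and the
#' analytic first and second derivatives vanish appropriately at both ends.
#'
#' @param plan a [motor_plan()].
#' @param dt sampling step (s).
#' @return data frame with `t`, `x_des`, `y_des`, `xd_des`, `yd_des`,
#'   `xdd_des`, `ydd_des`.
#' @export
plan_to_reference <- function(plan, dt) {
  stopifnot(dt > 0)
  D <- plan$duration
  t <- seq(0, D, by = dt)
  tau <- t / D
  rise <- plan$end[2] - plan$start[2]
  y <- plan$start[2] + rise * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
  yd <- rise / D * (30 * tau^2 - 60 * tau^3 + 30 * tau^4)
  ydd <- rise / D^2 * (60 * tau - 180 * tau^2 + 120 * tau^3)
  tk <- c(0, plan$via_t_frac, 1) * D
  xk <- plan$start[1] + c(0, plan$via_offsets, plan$via_offsets[3])
  sp <- .clamped_spline(tk, xk)
  data.frame(t = t, x_des = sp(t), y_des = y,
             xd_des = sp(t, 1), yd_des = yd,
             xdd_des = sp(t, 2), ydd_des = ydd)
}

#' REINFORCE policy update
#'
#' `mean <- mean + alpha * (reward - baseline) * (a - mean) / stdev^2`,
#' clipped to the admissible bounds; the baseline is an exponential moving
#' average of the reward (factor 0.9). The exploration stdev is held fixed.
#'
#' @param policy a [policy_distribution()].
#' @param executed_plan the [motor_plan()] that was executed.
#' @param reward scalar reward of the executed trial.
#' @param bias_shift forward shift (m, per via point) that the ecological
#'   safety bias added when the plan was sampled. The update discounts it,
#'   so the policy learns from its own exploration and the transient bias
#'   does not ratchet the mean forward on every biased success.
#' @return the updated [policy_distribution()].
#' @export
policy_update <- function(policy, executed_plan, reward, bias_shift = 0) {
  stopifnot(is.finite(reward))
  a <- executed_plan$via_offsets - bias_shift
  if (is.na(policy$baseline)) policy$baseline <- reward
  adv <- reward - policy$baseline
  step <- policy$learning_rate * adv * (a - policy$mean) / policy$stdev^2
  # trust region of one sample distance: a large advantage shifts the mean
  # towards the newly discovered plan, never beyond (or further than) it
  towards <- a - policy$mean
  step <- sign(step) * pmin(abs(step), abs(towards))
  policy$mean <- policy$mean + step
  policy$mean <- pmin(pmax(policy$mean, policy$bounds[1]), policy$bounds[2])
  policy$baseline <- 0.9 * policy$baseline + 0.1 * reward
  policy
}

#' Serialize / restore a policy as JSON
#' @param policy a [policy_distribution()].
#' @param path file path.
#' @return `policy_from_json` returns a [policy_distribution()].
#' @export
policy_to_json <- function(policy, path) {
  jsonlite::write_json(unclass(policy), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname policy_to_json
#' @export
policy_from_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  baseline <- if (is.null(p$baseline)) NA_real_ else p$baseline
  policy_distribution(p$mean, p$stdev, p$learning_rate, baseline,
                      p$bounds, p$forward_shift, p$start, p$end, p$duration)
}
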