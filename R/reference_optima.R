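# Safety-optimal versus effort-optimal stand-up trajectories for the
# point-mass body under the velocity-proportional backward pull. The COM
# path is parameterized by the same via-point spline family as the motor
# plans (three horizontal offsets plus the movement duration); the exact
# tracking commands follow in closed form from the inverse dynamics, so the
# nonlinear program reduces to a smooth low-dimensional search solved with
# nlminb multi-starts.

#' Specification of a reference optimization
#'
#' @param objective `"max_safety"` (keep the centre of pressure as far
#'   forward as possible) or `"min_energy"` (minimize motion effort).
#' @param params a [body_params()].
#' @param duration_bounds admissible movement durations (s).
#' @param offset_bounds admissible via-point offsets (m).
#' @param n_starts nlminb multi-starts.
#' @return an object of class `optimization_spec`.
#' @export
optimization_spec <- function(objective = c("max_safety", "min_energy"),
                              params = body_params(),
                              duration_bounds = c(1.05, 1.45),
                              offset_bounds = c(-0.05, 0.35),
                              n_starts = 5) {
  structure(list(objective = match.arg(objective), params = params,
                 duration_bounds = duration_bounds,
                 offset_bounds = offset_bounds, n_starts = n_starts),
            class = "optimization_spec")
}

# path, commands and ZMP of an exactly tracked via-point plan
.optima_rollout <- function(offsets, duration, params, dt = 0.005) {
  plan <- motor_plan(offsets, c(0, params$leg_length_squat),
                     c(0, params$leg_length_stand), duration)
  ref <- plan_to_reference(plan, dt)
  m <- params$mass; g <- params$gravity
  r <- sqrt(ref$x_des^2 + ref$y_des^2)
  th <- atan2(ref$x_des, ref$y_des)
  rd <- (ref$x_des * ref$xd_des + ref$y_des * ref$yd_des) / r
  thd <- (ref$xd_des * ref$y_des - ref$x_des * ref$yd_des) / r^2
  fx <- -perturbation_force(ref$yd_des, m, params$perturbation_gain_K)
  s <- sin(th); c_ <- cos(th)
  u <- ref$xdd_des - (2 * rd * thd * c_ - r * thd^2 * s)
  v <- ref$ydd_des - (-2 * rd * thd * s - r * thd^2 * c_)
  rdd <- s * u + c_ * v
  thdd <- (c_ * u - s * v) / r
  f_base <- m * (rdd - r * thd^2 + g * c_)
  tau_base <- m * r^2 * thdd + 2 * m * r * rd * thd - m * g * r * s
  f_r <- f_base - fx * s
  tau <- tau_base - fx * r * c_
  zmp <- ref$x_des - ref$y_des * (ref$xdd_des - fx / m) / (ref$ydd_des + g)
  list(t = ref$t, x = ref$x_des, y = ref$y_des, zmp = zmp,
       xdd = ref$xdd_des, ydd = ref$ydd_des,
       force_prismatic = f_r, torque_ankle = tau, fx_pert = fx, dt = dt,
       plan = plan)
}

.optima_effort <- function(ro, params) {
  # point-mass energy: squared net force through the COM (the point mass
  # has no separate torque channel), normalized by body weight
  g <- params$gravity
  .trapz(ro$t, (ro$xdd^2 + (ro$ydd + g)^2) / g^2)
}

.optima_penalty <- function(ro, params) {
  over <- pmax(0, params$foot_support_back - ro$zmp)^2 +
    pmax(0, ro$zmp - params$foot_support_front)^2
  .trapz(ro$t, over)
}

#' Solve for a safety- or effort-optimal stand-up trajectory
#'
#' @param spec an [optimization_spec()].
#' @return list with `trajectory` (t, x, y, zmp, commands, perturbation
#'   force), `objective_value`, `via_offsets`, `duration`,
#'   `trajectory_area`, `initial_trajectory_area` (cm^2) and
#'   `peak_perturbation_force` (N).
#' @export
solve_optimal_trajectory <- function(spec) {
  params <- spec$params
  len <- params$foot_support_front - params$foot_support_back
  obj <- function(p) {
    ro <- .optima_rollout(p[1:3], p[4], params)
    eff <- .optima_effort(ro, params)
    pen <- .optima_penalty(ro, params)
    if (spec$objective == "max_safety") {
      # keep the COP as far forward as possible, within the support
      (params$foot_support_front - min(ro$zmp)) / len + 1e-3 * eff +
        200 * pen
    } else {
      # pure energy minimum, unconstrained by the support interval: its
      # balance infeasibility under the pull is the point of the contrast
      eff
    }
  }
  lb <- c(rep(spec$offset_bounds[1], 3), spec$duration_bounds[1])
  ub <- c(rep(spec$offset_bounds[2], 3), spec$duration_bounds[2])
  # deterministic start lattice; no global RNG use
  fr <- seq(0.15, 0.85, length.out = spec$n_starts)
  starts <- lapply(seq_len(spec$n_starts), function(i) {
    lb + c(fr[i], fr[i], fr[i], fr[spec$n_starts + 1 - i]) * (ub - lb)
  })
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(stats::nlminb(p0, obj, lower = lb, upper = ub),
                    error = function(e) NULL)
    if (!is.null(fit) &&
        (is.null(best) || fit$objective < best$objective)) {
      best <- fit
    }
  }
  stopifnot(!is.null(best))
  ro <- .optima_rollout(best$par[1:3], best$par[4], params)
  traj <- data.frame(t = ro$t, x = ro$x, y = ro$y, zmp_x = ro$zmp,
                     force_prismatic = ro$force_prismatic,
                     torque_ankle = ro$torque_ankle,
                     perturbation_force = -ro$fx_pert)
  nt <- normalize_trajectory(traj, rise = params$leg_length_stand -
                               params$leg_length_squat)
  list(trajectory = traj, objective_value = best$objective,
       via_offsets = best$par[1:3], duration = best$par[4],
       trajectory_area = trajectory_area(nt),
       initial_trajectory_area = initial_trajectory_area(nt),
       peak_perturbation_force = max(-ro$fx_pert))
}
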