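#' Body and perturbation parameters
#'
#' Parameters of the two degree-of-freedom inverted-pendulum body (a point
#' mass on a prismatic leg hinged at the ankle) and of the backward
#' perturbation, whose magnitude is proportional to the upward velocity of
#' the centre of mass (COM): `F = K * max(ydot, 0) * mass`, applied along -x.
#'
#' The default body matches a 77 kg adult with a COM rise of 0.5 m between
#' squat and stand, a movement duration of 1.2 s, and a foot support interval
#' of \[-0.10, +0.17\] m around the ankle.
#'
#' @param mass total body mass (kg).
#' @param leg_length_squat,leg_length_stand COM distance from the ankle in the
#'   squat and stand configurations (m).
#' @param foot_support_back,foot_support_front backward/forward bounds of the
#'   foot support interval for the zero-moment point (m; back < 0 < front).
#' @param gravity gravitational acceleration (m/s^2).
#' @param perturbation_gain_K perturbation gain (1/s); 0 disables the pull.
#' @param dt integrator step (s), fixed-step RK4.
#' @param duration trial duration (s).
#' @param f_max,tau_max actuator limits (N, N m).
#' @param grace sustained zero-moment-point excursion needed to call a
#'   balance failure (s); brief saturations are assumed recoverable without
#'   a corrective step.
#' @param stand_tol tolerance on the final COM height for a successful
#'   stand-up (m).
#' @return an object of class `body_params`.
#' @export
body_params <- function(mass = 77, leg_length_squat = 0.55,
                        leg_length_stand = 1.05, foot_support_back = -0.10,
                        foot_support_front = 0.17, gravity = 9.81,
                        perturbation_gain_K = 3, dt = 0.001, duration = 1.2,
                        f_max = 4000, tau_max = 400, grace = 0.08,
                        stand_tol = 0.05) {
  stopifnot(mass > 0, leg_length_squat > 0,
            leg_length_squat < leg_length_stand,
            foot_support_back < 0, foot_support_front > 0,
            gravity > 0, perturbation_gain_K >= 0, dt > 0, dt <= 0.005)
  structure(list(mass = mass, leg_length_squat = leg_length_squat,
                 leg_length_stand = leg_length_stand,
                 foot_support_back = foot_support_back,
                 foot_support_front = foot_support_front, gravity = gravity,
                 perturbation_gain_K = perturbation_gain_K, dt = dt,
                 duration = duration, f_max = f_max, tau_max = tau_max,
                 grace = grace, stand_tol = stand_tol),
            class = "body_params")
}

#' Pendulum configuration at one instant
#'
#' @param r leg extension (m); `theta` ankle angle from vertical, +forward
#'   (rad); `r_dot`, `theta_dot` their rates; `t` time (s).
#' @param theta,r_dot,theta_dot,t see `r`.
#' @return an object of class `body_state`.
#' @export
body_state <- function(r, theta = 0, r_dot = 0, theta_dot = 0, t = 0) {
  stopifnot(is.finite(c(r, theta, r_dot, theta_dot, t)), r > 0)
  structure(list(r = r, theta = theta, r_dot = r_dot, theta_dot = theta_dot,
                 t = t), class = "body_state")
}

#' COM position, velocity and vertical rate of a body state
#' @param state a [body_state()].
#' @return list with `x`, `y`, `x_dot`, `y_dot`.
#' @export
com_kinematics <- function(state) {
  s <- sin(state$theta); c <- cos(state$theta)
  list(x = state$r * s, y = state$r * c,
       x_dot = state$r_dot * s + state$r * state$theta_dot * c,
       y_dot = state$r_dot * c - state$r * state$theta_dot * s)
}

#' Velocity-proportional backward perturbation force
#'
#' Magnitude of the pull applied along -x at the COM: `K * max(y_dot, 0) *
#' mass`. The pull is clamped to upward COM motion; a descending COM draws
#' no force.
#'
#' @param y_dot vertical COM velocity (m/s).
#' @param mass body mass (kg).
#' @param K perturbation gain (1/s).
#' @return backward force magnitude (N, non-negative).
#' @export
perturbation_force <- function(y_dot, mass, K) {
  if (!all(is.finite(c(y_dot, mass, K)))) {
    stop("perturbation_force: inputs must be finite")
  }
  K * pmax(y_dot, 0) * mass
}

# generalized accelerations; fx is the signed external horizontal force
.gen_accel <- function(r, th, rd, thd, f_r, tau, fx, mass, g) {
  c(rdd = r * thd^2 - g * cos(th) + (f_r + fx * sin(th)) / mass,
    thdd = g * sin(th) / r - 2 * rd * thd / r +
      (tau + fx * r * cos(th)) / (mass * r^2))
}

.cart_accel <- function(r, th, rd, thd, rdd, thdd) {
  s <- sin(th); c <- cos(th)
  c(x_ddot = rdd * s + 2 * rd * thd * c + r * thdd * c - r * thd^2 * s,
    y_ddot = rdd * c - 2 * rd * thd * s - r * thdd * s - r * thd^2 * c)
}

.state_deriv <- function(st, f_r, tau, params) {
  yd <- st[3] * cos(st[2]) - st[1] * st[4] * sin(st[2])
  fx <- -perturbation_force(yd, params$mass, params$perturbation_gain_K)
  acc <- .gen_accel(st[1], st[2], st[3], st[4], f_r, tau, fx,
                    params$mass, params$gravity)
  c(st[3], st[4], acc[[1]], acc[[2]])
}

#' Advance the body by one RK4 step
#'
#' Integrates the pendulum equations of motion under the given actuator
#' commands, gravity, and the velocity-proportional perturbation.
#'
#' @param state a [body_state()].
#' @param command list with `force_prismatic` (N) and `torque_ankle` (N m).
#' @param params a [body_params()].
#' @param dt step size (s), at most 5 ms.
#' @return the advanced [body_state()].
#' @export
step_dynamics <- function(state, command, params, dt = params$dt) {
  stopifnot(dt > 0, dt <= 0.005)
  st <- c(state$r, state$theta, state$r_dot, state$theta_dot)
  f <- command$force_prismatic; tau <- command$torque_ankle
  k1 <- .state_deriv(st, f, tau, params)
  k2 <- .state_deriv(st + dt / 2 * k1, f, tau, params)
  k3 <- .state_deriv(st + dt / 2 * k2, f, tau, params)
  k4 <- .state_deriv(st + dt * k3, f, tau, params)
  st <- st + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  if (!all(is.finite(st))) {
    stop("step_dynamics: simulation diverged at t = ", state$t)
  }
  body_state(st[1], st[2], st[3], st[4], state$t + dt)
}

#' Zero-moment point of the point-mass body
#'
#' `x_zmp = x - y * x_ddot / (y_ddot + g)`. Undefined (ballistic phase) when
#' `y_ddot + g <= 0`.
#'
#' @param state a [body_state()].
#' @param accel numeric length-2, COM acceleration `(x_ddot, y_ddot)`.
#' @param params a [body_params()].
#' @return ZMP x-coordinate (m).
#' @export
zmp_point <- function(state, accel, params) {
  k <- com_kinematics(state)
  denom <- accel[2] + params$gravity
  if (denom <= 0) stop("zmp_point: ballistic phase, ZMP undefined")
  k$x - k$y * accel[1] / denom
}

#' Classify a trial outcome from its trajectory
#'
#' Success requires the final COM height to be within tolerance of the
#' standing height and the zero-moment point to remain inside the foot
#' support interval (excursions shorter than the grace time are forgiven).
#' Failure direction is the side of the deepest ZMP excursion beyond the
#' support interval; if neither side was crossed (the stand was simply not
#' reached), the sign of the final COM position decides.
#'
#' @param traj data frame with at least `t`, `x`, `y`, `zmp_x` columns.
#' @param params a [body_params()].
#' @param truncated logical; `TRUE` when the simulation was cut short.
#' @return one of `"success"`, `"failure_backward"`, `"failure_forward"`.
#' @export
classify_outcome <- function(traj, params, truncated = FALSE) {
  stopifnot(nrow(traj) > 0)
  dt <- if (nrow(traj) > 1) diff(traj$t[1:2]) else params$dt
  grace_n <- max(1L, ceiling(params$grace / dt))
  out_back <- traj$zmp_x < params$foot_support_back
  out_front <- traj$zmp_x > params$foot_support_front
  sustained_depth <- function(flag, depth) {
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    i <- which(r$values & r$lengths > grace_n)
    if (length(i) == 0) return(0)
    max(vapply(i, function(j) {
      max(depth[(ends[j] - r$lengths[j] + 1L):ends[j]])
    }, 0))
  }
  depth_back <- sustained_depth(out_back, params$foot_support_back -
                                  traj$zmp_x)
  depth_front <- sustained_depth(out_front, traj$zmp_x -
                                   params$foot_support_front)
  sustained <- depth_back > 0 || depth_front > 0
  reached <- !truncated &&
    abs(traj$y[nrow(traj)] - params$leg_length_stand) <= params$stand_tol
  if (reached && !sustained) return("success")
  if (sustained) {
    return(if (depth_back >= depth_front) "failure_backward"
           else "failure_forward")
  }
  # no sustained excursion but the stand was not reached
  if (traj$x[nrow(traj)] < 0) "failure_backward" else "failure_forward"
}

.traj_df <- function(m) {
  df <- as.data.frame(m)
  names(df) <- c("t", "x", "y", "x_dot", "y_dot", "x_ddot", "y_ddot", "zmp_x")
  df
}

#' Simulate one closed-loop trial
#'
#' Executes a motor plan with feed-forward commands from the internal model,
#' scaled PD feedback on the COM tracking error, online internal-model
#' learning at every control tick, and prediction-error-driven tuning of the
#' feedback gain multiplier. The body is integrated with fixed-step RK4.
#'
#' @param plan a [motor_plan()].
#' @param model an [internal_model()].
#' @param gains a [feedback_gains()].
#' @param params a [body_params()]; set `perturbation_gain_K = 0` for
#'   unperturbed trials.
#' @param learn logical; update the internal model during the trial.
#' @return a list (class `trial_record`) with `trajectory`, `commands`,
#'   `multiplier`, `outcome`, the updated `model`, and the executed `plan`.
#' @export
simulate_trial <- function(plan, model, gains, params, learn = TRUE) {
  ref <- plan_to_reference(plan, params$dt)
  state0 <- c(plan$start[2], 0, 0, 0)  # squat: COM above the ankle
  if (abs(plan$start[1]) > 1e-12) {
    r0 <- sqrt(sum(plan$start^2))
    state0 <- c(r0, atan2(plan$start[1], plan$start[2]), 0, 0)
  }
  par <- list(mass = params$mass, gravity = params$gravity,
              K = params$perturbation_gain_K, dt = params$dt,
              f_max = params$f_max, tau_max = params$tau_max,
              kp_x = gains$kp[1], kp_y = gains$kp[2],
              kd_x = gains$kd[1], kd_y = gains$kd[2],
              mult_cap = gains$multiplier_cap,
              mult_scale = gains$relation_scale_c,
              eta = model$learning_rate_eta, lambda = model$lambda,
              learn = learn)
  ref_m <- as.matrix(ref[, c("x_des", "y_des", "xd_des", "yd_des",
                             "xdd_des", "ydd_des")])
  out <- .sim_trial_cpp(ref_m, state0, model$delta_weights,
                        model$prediction_error_trace, par)
  traj <- .traj_df(out$traj)
  cmds <- as.data.frame(out$cmds)
  names(cmds) <- c("force_prismatic", "torque_ankle")
  model$delta_weights <- out$W
  model$prediction_error_trace <- out$err_trace
  structure(list(trajectory = traj, commands = cmds,
                 multiplier = as.numeric(out$mult),
                 outcome = classify_outcome(traj, params, out$truncated),
                 truncated = out$truncated, model = model, plan = plan),
            class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat("<trial_record>", x$outcome, "-", nrow(x$trajectory), "samples\n")
  invisible(x)
}
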