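# Inverse-dynamics internal model: the base term is the exact closed-form
# inverse dynamics of the unperturbed body; novel dynamics are absorbed by an
# additive term linear in a fixed feature basis, adapted online from the
# acceleration prediction error (normalized least-mean-squares per tick).

.id_features <- function(state) {
  k <- com_kinematics(state)
  c(1, state$r, state$theta, state$r_dot, state$theta_dot, k$y_dot,
    k$y_dot * sin(state$theta), k$y_dot * state$r * cos(state$theta))
}

# exact unperturbed inverse dynamics (generalized commands for a desired
# Cartesian COM acceleration at the given state)
.inv_dyn_base <- function(state, accel, params) {
  r <- state$r; th <- state$theta; rd <- state$r_dot; thd <- state$theta_dot
  s <- sin(th); c <- cos(th)
  u <- accel[1] - (2 * rd * thd * c - r * thd^2 * s)
  v <- accel[2] - (-2 * rd * thd * s - r * thd^2 * c)
  rdd <- s * u + c * v
  thdd <- (c * u - s * v) / r
  m <- params$mass
  c(force_prismatic = m * (rdd - r * thd^2 + params$gravity * c),
    torque_ankle = m * r^2 * thdd + 2 * m * r * rd * thd -
      m * params$gravity * r * s)
}

# unperturbed forward dynamics: Cartesian COM acceleration under commands
.fwd_dyn_base <- function(state, command, params) {
  acc <- .gen_accel(state$r, state$theta, state$r_dot, state$theta_dot,
                    command[1], command[2], 0, params$mass, params$gravity)
  .cart_accel(state$r, state$theta, state$r_dot, state$theta_dot,
              acc[[1]], acc[[2]])
}

#' Adaptive inverse-dynamics internal model
#'
#' @param delta_weights 2 x 8 matrix of additive-term coefficients (rows:
#'   prismatic force, ankle torque; columns: feature basis
#'   `(1, r, theta, r_dot, theta_dot, y_dot, y_dot*sin(theta),
#'   y_dot*r*cos(theta))`; the last two features carry the shapes of the
#'   pull's generalized forces, so a velocity-proportional horizontal force
#'   is exactly representable).
#' @param learning_rate_eta normalized LMS step per control tick.
#' @param lambda forgetting factor of the running prediction-error trace.
#' @param prediction_error_trace running RMS of the Cartesian acceleration
#'   prediction error (m/s^2).
#' @return an object of class `internal_model`.
#' @export
internal_model <- function(delta_weights = matrix(0, 2, 8),
                           learning_rate_eta = 0.0035, lambda = 0.9998,
                           prediction_error_trace = 0) {
  stopifnot(all(is.finite(delta_weights)), dim(delta_weights)[1] == 2,
            dim(delta_weights)[2] == 8, prediction_error_trace >= 0)
  structure(list(delta_weights = delta_weights,
                 learning_rate_eta = learning_rate_eta, lambda = lambda,
                 prediction_error_trace = prediction_error_trace),
            class = "internal_model")
}

#' Feed-forward command for a desired COM acceleration
#'
#' Base inverse dynamics of the unperturbed body plus the feature-weighted
#' additive term.
#'
#' @param model an [internal_model()].
#' @param state a [body_state()].
#' @param desired_accel numeric length-2 `(x_ddot, y_ddot)` (m/s^2).
#' @param params a [body_params()].
#' @return list with `force_prismatic` (N), `torque_ankle` (N m), `t` (s).
#' @export
feedforward_command <- function(model, state, desired_accel, params) {
  base <- .inv_dyn_base(state, desired_accel, params)
  add <- as.numeric(model$delta_weights %*% .id_features(state))
  list(force_prismatic = base[[1]] + add[1],
       torque_ankle = base[[2]] + add[2], t = state$t)
}

#' One prediction-error learning step
#'
#' Compares the observed COM acceleration with the model's prediction for
#' the net command, updates the additive-term weights by normalized LMS in
#' command space, and updates the running prediction-error trace.
#'
#' @param model an [internal_model()].
#' @param net_command list with `force_prismatic`, `torque_ankle`: the net
#'   command that was applied to the body.
#' @param state the [body_state()] at which the command was applied.
#' @param observed_accel numeric length-2, the resulting COM acceleration.
#' @param params a [body_params()].
#' @return the updated [internal_model()].
#' @export
observe_and_learn <- function(model, net_command, state, observed_accel,
                              params) {
  phi <- .id_features(state)
  add <- as.numeric(model$delta_weights %*% phi)
  u <- c(net_command$force_prismatic, net_command$torque_ankle)

  pred <- .fwd_dyn_base(state, u - add, params)
  err_a <- observed_accel - pred
  model$prediction_error_trace <- sqrt(
    model$lambda * model$prediction_error_trace^2 +
      (1 - model$lambda) * sum(err_a^2))

  base_obs <- .inv_dyn_base(state, observed_accel, params)
  err_u <- u - (as.numeric(base_obs) + add)
  gain <- model$learning_rate_eta / (1 + sum(phi^2))
  model$delta_weights <- model$delta_weights + gain * outer(err_u, phi)
  model
}

#' Shift the internal model towards its unperturbed state
#'
#' Scales the additive-term weights by `(1 - rho)`; `rho = 1` restores the
#' exact unperturbed model, `rho = 0` leaves the model unchanged.
#'
#' @param model an [internal_model()].
#' @param rho shift fraction in `[0, 1]`.
#' @return the shifted [internal_model()].
#' @export
shift_toward_unperturbed <- function(model, rho) {
  stopifnot(rho >= 0, rho <= 1)
  model$delta_weights <- (1 - rho) * model$delta_weights
  model
}

#' Serialize / restore an internal model as JSON
#' @param model an [internal_model()].
#' @param path file path.
#' @return `internal_model_from_json` returns an [internal_model()].
#' @export
internal_model_to_json <- function(model, path) {
  jsonlite::write_json(list(delta_weights = model$delta_weights,
                            learning_rate_eta = model$learning_rate_eta,
                            lambda = model$lambda,
                            prediction_error_trace =
                              model$prediction_error_trace),
                       path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname internal_model_to_json
#' @export
internal_model_from_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- p$delta_weights
  if (!is.matrix(W)) W <- matrix(as.numeric(W), 2, 8, byrow = TRUE)
  internal_model(W, p$learning_rate_eta, p$lambda,
                 p$prediction_error_trace)
}
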