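#' Scaled PD feedback gains
#'
#' Fixed proportional and derivative gains on the COM tracking error in
#' Cartesian space, multiplied by an adaptable scalar `multiplier_g`. The
#' multiplier is tied to the internal-model prediction-error trace through a
#' fixed relation ([tune_multiplier()]), so the feedback contribution is
#' inversely related to internal-model accuracy.
#'
#' @param kp numeric length-2, proportional gains `(x, y)` (N/m).
#' @param kd numeric length-2, derivative gains `(x, y)` (N s/m).
#' @param multiplier_g current scalar multiplier (dimensionless, >= 0).
#' @param relation_scale_c slope of the error-to-multiplier relation
#'   (per m/s^2 of prediction-error trace).
#' @param multiplier_cap saturation value of the multiplier.
#' @return an object of class `feedback_gains`.
#' @export
feedback_gains <- function(kp = c(3000, 3000), kd = c(500, 500),
                           multiplier_g = 0, relation_scale_c = 2,
                           multiplier_cap = 3) {
  stopifnot(all(kp >= 0), all(kd >= 0), multiplier_g >= 0,
            multiplier_g <= multiplier_cap, multiplier_cap > 0)
  structure(list(kp = kp, kd = kd, multiplier_g = multiplier_g,
                 relation_scale_c = relation_scale_c,
                 multiplier_cap = multiplier_cap),
            class = "feedback_gains")
}

#' PD feedback command on the COM tracking error
#'
#' Returns `multiplier_g * (kp * position_error + kd * velocity_error)` per
#' Cartesian channel. Mapping into actuator space (through the configuration
#' Jacobian transpose) is done by the trial simulator.
#'
#' @param gains a [feedback_gains()].
#' @param position_error,velocity_error numeric length-2 COM errors
#'   (desired minus actual), m and m/s.
#' @return numeric length-2 Cartesian feedback force (N).
#' @export
feedback_command <- function(gains, position_error, velocity_error) {
  stopifnot(all(is.finite(c(position_error, velocity_error))))
  gains$multiplier_g * (gains$kp * position_error + gains$kd * velocity_error)
}

#' Tune the feedback multiplier from the prediction-error trace
#'
#' `multiplier_g <- min(cap, c * trace)`: strictly increasing in the trace
#' and zero in the limit of a perfect internal model.
#'
#' @param gains a [feedback_gains()].
#' @param prediction_error_trace running RMS acceleration prediction error
#'   (m/s^2, >= 0).
#' @return the updated [feedback_gains()].
#' @export
tune_multiplier <- function(gains, prediction_error_trace) {
  stopifnot(prediction_error_trace >= 0)
  gains$multiplier_g <- min(gains$multiplier_cap,
                            gains$relation_scale_c * prediction_error_trace)
  gains
}
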