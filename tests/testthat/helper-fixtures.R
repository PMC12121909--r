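# shared small configurations and independent dynamics oracle

# coarser integrator step for unit tests; the dynamics are smooth enough
# that RK4 at 2 ms stays well within the tolerances asserted here
quick_params <- function(...) {
  body_params(dt = 0.002, ...)
}

# independent implementation of the pendulum equations of motion, written
# directly from the Lagrangian in polar coordinates; used as an oracle
# against the package integrator
oracle_deriv <- function(st, f_r, tau, params) {
  r <- st[1]; th <- st[2]; rd <- st[3]; thd <- st[4]
  m <- params$mass; g <- params$gravity
  y_dot <- rd * cos(th) - r * thd * sin(th)
  fx <- -params$perturbation_gain_K * max(y_dot, 0) * m
  rdd <- r * thd^2 - g * cos(th) + (f_r + fx * sin(th)) / m
  thdd <- g * sin(th) / r - 2 * rd * thd / r +
    (tau + fx * r * cos(th)) / (m * r^2)
  c(rd, thd, rdd, thdd)
}

# fixed-step explicit Euler on the oracle derivative
oracle_euler <- function(st, f_r, tau, params, dt, n) {
  for (i in seq_len(n)) {
    st <- st + dt * oracle_deriv(st, f_r, tau, params)
  }
  st
}

# a plan known to be balance-feasible for the default body once the
# internal model has converged
good_plan <- function() motor_plan(c(0.035, 0.098, 0.123))

# run n perturbed trials of a fixed plan, returning the final model
warmup_model <- function(n = 20, plan = good_plan(),
                         params = body_params()) {
  m <- internal_model()
  g <- feedback_gains()
  for (i in seq_len(n)) {
    tr <- simulate_trial(plan, m, g, params)
    m <- tr$model
  }
  m
}
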