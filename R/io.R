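#' Write / read a simulated trial trajectory as CSV
#'
#' Columns `t,x,y,x_dot,y_dot,x_ddot,y_ddot,zmp_x,force_prismatic,
#' torque_ankle`; one file per trial.
#'
#' @param trial a `trial_record` from [simulate_trial()].
#' @param path CSV file path.
#' @return `read_trial_csv` returns a list with `trajectory` and `commands`
#'   data frames.
#' @export
write_trial_csv <- function(trial, path) {
  df <- cbind(trial$trajectory, trial$commands)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  df <- read.csv(path)
  traj_cols <- c("t", "x", "y", "x_dot", "y_dot", "x_ddot", "y_ddot",
                 "zmp_x")
  list(trajectory = df[, intersect(traj_cols, names(df))],
       commands = df[, intersect(c("force_prismatic", "torque_ankle"),
                                 names(df)), drop = FALSE])
}

#' Per-trial metrics of a run as CSV
#'
#' @param run a [run_experiment()] result.
#' @param path CSV file path.
#' @return invisibly, the path.
#' @export
write_run_csv <- function(run, path) {
  write.csv(run$trials_df, path, row.names = FALSE)
  invisible(path)
}

#' Run-level JSON summary
#'
#' @param run a [run_experiment()] result.
#' @param path JSON file path.
#' @return invisibly, the path.
#' @export
write_run_summary_json <- function(run, path) {
  jsonlite::write_json(list(seed = run$seed, completed = run$completed,
                            n_failures = run$n_failures,
                            first_success_trial = run$first_success_trial,
                            n_perturbed = run$n_perturbed,
                            confidence_threshold = run$confidence_threshold),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
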