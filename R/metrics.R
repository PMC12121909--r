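# Adaptation measures computed from sagittal-plane COM trajectories and
# (for human-like data) a thigh antagonist EMG pair.

.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

#' Normalize a COM trajectory
#'
#' Translates the trajectory to start at the origin and scales it
#' isotropically so that the total vertical rise equals `rise_target`
#' (0.5 m). The reference rise defaults to the observed one; for failed
#' trials that never reach the top, pass the intended rise via `rise`.
#'
#' @param traj data frame with `x` and `y` columns (m); other columns are
#'   preserved.
#' @param rise reference rise (m) used for scaling; default
#'   `max(y) - y[1]`.
#' @param rise_target rise after scaling (m).
#' @return the normalized trajectory data frame.
#' @export
normalize_trajectory <- function(traj, rise = NULL, rise_target = 0.5) {
  if (is.null(rise)) rise <- max(traj$y) - traj$y[1]
  if (!is.finite(rise) || rise <= 0) {
    stop("normalize_trajectory: trajectory has no vertical rise")
  }
  s <- rise_target / rise
  out <- traj
  out$x <- (traj$x - traj$x[1]) * s
  out$y <- (traj$y - traj$y[1]) * s
  out
}

# x as a function of monotone y over the rising portion of the trajectory,
# up to the first attainment of the peak height
.x_of_rising_y <- function(traj) {
  i_peak <- which.max(traj$y)
  y <- traj$y[1:i_peak]
  x <- traj$x[1:i_peak]
  keep <- c(TRUE, diff(cummax(y)) > 0)
  list(y = cummax(y)[keep], x = x[keep])
}

#' Trajectory Area
#'
#' Signed integral of the horizontal deviation from the straight
#' squat-to-stand line, `A = int x dy`, from the start height to `y_end`,
#' over the rising portion of a normalized trajectory. Positive values mean
#' forward deviation (against a backward perturbation).
#'
#' @param traj a normalized trajectory ([normalize_trajectory()]).
#' @param y_end upper integration bound (m), at most the scaled rise.
#' @return signed area in cm^2.
#' @export
trajectory_area <- function(traj, y_end = 0.5) {
  stopifnot(y_end > 0)
  p <- .x_of_rising_y(traj)
  if (length(p$y) < 2) return(0)
  yl <- min(y_end, max(p$y))
  grid <- seq(p$y[1], yl, length.out = 512)
  xg <- approx(p$y, p$x, xout = grid, rule = 2)$y
  .trapz(grid, xg) * 1e4
}

#' Initial Trajectory Area
#'
#' [trajectory_area()] over the first 5 % of the scaled rise
#' (`y_end` = 2.5 cm): a proxy for the feed-forward motor plan before
#' feedback can act.
#'
#' @param traj a normalized trajectory.
#' @return signed area in cm^2.
#' @export
initial_trajectory_area <- function(traj) {
  trajectory_area(traj, y_end = 0.025)
}

#' Dimensionless squared jerk of a COM trajectory
#'
#' `SM = (int ||jerk||^2 dt) * D^3 / v_mean^2`, with the jerk obtained by
#' Savitzky-Golay smoothed triple differentiation of both position
#' components (window 11 samples, polynomial order 5) and `v_mean` the mean
#' speed (path length / duration). Lower values mean smoother movement.
#'
#' @param traj data frame with `t`, `x`, `y` columns.
#' @return non-negative dimensionless squared jerk.
#' @export
smoothness <- function(traj) {
  n <- nrow(traj)
  stopifnot(n >= 12)
  dt <- (traj$t[n] - traj$t[1]) / (n - 1)
  D <- traj$t[n] - traj$t[1]
  jx <- signal::sgolayfilt(traj$x, p = 5, n = 11, m = 3, ts = dt)
  jy <- signal::sgolayfilt(traj$y, p = 5, n = 11, m = 3, ts = dt)
  path <- sum(sqrt(diff(traj$x)^2 + diff(traj$y)^2))
  v_mean <- path / D
  stopifnot(v_mean > 0)
  .trapz(traj$t, jx^2 + jy^2) * D^3 / v_mean^2
}

#' Two-channel EMG recording
#'
#' @param vastus_medialis,biceps_femoris sampled signals (arbitrary units).
#' @param fs sampling rate (Hz).
#' @return an object of class `emg_channels`.
#' @export
emg_channels <- function(vastus_medialis, biceps_femoris, fs = 1000) {
  stopifnot(length(vastus_medialis) == length(biceps_femoris), fs > 0)
  structure(list(vastus_medialis = vastus_medialis,
                 biceps_femoris = biceps_femoris, fs = fs),
            class = "emg_channels")
}

# zero-phase 4th-order Butterworth band-pass 20-500 Hz; at fs = 1000 the
# upper edge coincides with Nyquist, so the filter reduces to a high-pass
.emg_filter <- function(x, fs, low = 20, high = 500) {
  nyq <- fs / 2
  bf <- if (high >= nyq) {
    signal::butter(4, low / nyq, type = "high")
  } else {
    signal::butter(4, c(low, high) / nyq, type = "pass")
  }
  signal::filtfilt(bf, x)
}

.rms_envelope <- function(x, fs, window = 0.05) {
  w <- max(1L, round(window * fs))
  if (w %% 2 == 0) w <- w + 1L
  pad <- (w - 1L) %/% 2L
  xp <- c(rep(x[1], pad), x, rep(x[length(x)], pad))
  sq <- stats::filter(xp^2, rep(1 / w, w), sides = 2)
  sqrt(as.numeric(sq[(pad + 1):(pad + length(x))]))
}

#' Co-contraction index of the thigh antagonist pair
#'
#' Each channel is band-pass filtered (zero-lag 4th-order Butterworth,
#' 20-500 Hz), full-wave rectified, enveloped by a moving 50 ms RMS window,
#' and integrated over the trial; the index is the quotient
#' `iEMG_vm / iEMG_bf`.
#'
#' @param emg an [emg_channels()].
#' @param window RMS envelope window (s).
#' @return positive dimensionless co-contraction index.
#' @export
co_contraction <- function(emg, window = 0.05) {
  stopifnot(inherits(emg, "emg_channels"))
  t <- seq_along(emg$vastus_medialis) / emg$fs
  env <- function(x) {
    .rms_envelope(abs(.emg_filter(x, emg$fs)), emg$fs, window)
  }
  i_vm <- .trapz(t, env(emg$vastus_medialis))
  i_bf <- .trapz(t, env(emg$biceps_femoris))
  if (i_bf <= .Machine$double.eps) {
    stop("co_contraction: degenerate biceps femoris signal")
  }
  i_vm / i_bf
}

#' Forward and backward peak COM displacement
#'
#' @param traj a normalized trajectory.
#' @return list with `forward` = max(x) and `backward` = min(x), in cm.
#' @export
peak_displacements <- function(traj) {
  list(forward = max(traj$x) * 100, backward = min(traj$x) * 100)
}

#' All trajectory metrics of one trial
#'
#' @param traj trajectory data frame (m units, un-normalized).
#' @param rise reference rise passed to [normalize_trajectory()].
#' @param emg optional [emg_channels()] for the co-contraction index.
#' @return list with `trajectory_area`, `initial_trajectory_area`,
#'   `smoothness`, `forward_peak`, `backward_peak`, `co_contraction`
#'   (cm^2, cm, dimensionless; `co_contraction` is `NA` without EMG).
#' @export
compute_metrics <- function(traj, rise = NULL, emg = NULL) {
  nt <- normalize_trajectory(traj, rise = rise)
  pk <- peak_displacements(nt)
  list(trajectory_area = trajectory_area(nt),
       initial_trajectory_area = initial_trajectory_area(nt),
       smoothness = if (nrow(nt) >= 12) smoothness(nt) else NA_real_,
       forward_peak = pk$forward, backward_peak = pk$backward,
       co_contraction = if (is.null(emg)) NA_real_ else co_contraction(emg))
}
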