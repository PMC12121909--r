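# Human-like synthetic trial series with controlled statistical structure:
# near-straight baselines, perturbation-bent adaptation trajectories whose
# bow amplitude follows an exponential trend, sporadic failures with
# backward excursions, and antagonist EMG bursts whose co-contraction is
# elevated on and after failures. They exercise the metrics and analysis
# stack independently of the simulator.

#' Specification of a synthetic trial series
#'
#' @param n_trials number of trials.
#' @param amp_a,amp_b,amp_c exponential bow-amplitude trend parameters (cm):
#'   amplitude of trial `i` is `amp_a * exp(-i / amp_b) + amp_c`.
#' @param failure_probability per-trial failure probabilities; a scalar is
#'   recycled, or a vector of length `n_trials`.
#' @param noise_sd trial-to-trial amplitude noise (cm).
#' @param emg_burst_amp base amplitude of the agonist EMG bursts.
#' @param emg_coc_base,emg_coc_failure co-contraction level of ordinary
#'   trials and of failure/post-failure trials.
#' @param fs_traj,fs_emg sampling rates (Hz).
#' @param duration trial duration (s).
#' @param rng_seed integer seed.
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_trials = 84, amp_a = -12, amp_b = 15, amp_c = 8,
                         failure_probability = 0.15, noise_sd = 0.5,
                         emg_burst_amp = 1, emg_coc_base = 1.2,
                         emg_coc_failure = 2.0, fs_traj = 200, fs_emg = 1000,
                         duration = 1.2, rng_seed = 1) {
  stopifnot(n_trials >= 1, amp_b > 0, noise_sd >= 0,
            all(failure_probability >= 0), all(failure_probability <= 1))
  if (length(failure_probability) == 1) {
    failure_probability <- rep(failure_probability, n_trials)
  }
  stopifnot(length(failure_probability) == n_trials)
  structure(list(n_trials = n_trials, amp_a = amp_a, amp_b = amp_b,
                 amp_c = amp_c, failure_probability = failure_probability,
                 noise_sd = noise_sd, emg_burst_amp = emg_burst_amp,
                 emg_coc_base = emg_coc_base,
                 emg_coc_failure = emg_coc_failure, fs_traj = fs_traj,
                 fs_emg = fs_emg, duration = duration, rng_seed = rng_seed),
            class = "fixture_spec")
}

# parabolic bow trajectory of given amplitude (cm) over a 0.5 m min-jerk rise
.fixture_traj <- function(amp_cm, fs, duration, backward_excursion = 0) {
  t <- seq(0, duration, by = 1 / fs)
  tau <- t / duration
  y <- 0.5 * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
  x <- (amp_cm / 100) * 4 * y * (0.5 - y) / 0.25
  if (backward_excursion > 0) {
    x <- x - backward_excursion * sin(pi * tau)^2
  }
  data.frame(t = t, x = x, y = 0.55 + y)
}

.fixture_emg <- function(coc, amp, fs, duration) {
  t <- seq(0, duration, by = 1 / fs)
  burst <- exp(-((t - duration / 2)^2) / (2 * (duration / 6)^2))
  carrier <- function() sin(2 * pi * 130 * t + runif(1, 0, 2 * pi)) +
    0.3 * sin(2 * pi * 270 * t + runif(1, 0, 2 * pi))
  emg_channels(vastus_medialis = coc * amp * burst * carrier(),
               biceps_femoris = amp * burst * carrier(), fs = fs)
}

#' Generate a human-like synthetic trial series
#'
#' @param spec a [fixture_spec()].
#' @return list of trial records, each with `index`, `outcome`,
#'   `trajectory`, `emg`, `amplitude`; the list carries the spec as an
#'   attribute.
#' @export
make_trial_series <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$rng_seed)
  amps <- spec$amp_a * exp(-seq_len(spec$n_trials) / spec$amp_b) +
    spec$amp_c + rnorm(spec$n_trials, 0, spec$noise_sd)
  fail <- runif(spec$n_trials) < spec$failure_probability
  prev_fail <- c(FALSE, fail[-spec$n_trials])
  trials <- lapply(seq_len(spec$n_trials), function(i) {
    exc <- if (fail[i]) 0.06 + 0.02 * runif(1) else 0
    traj <- .fixture_traj(amps[i], spec$fs_traj, spec$duration, exc)
    coc <- if (fail[i] || prev_fail[i]) spec$emg_coc_failure else
      spec$emg_coc_base
    list(index = i,
         outcome = if (fail[i]) "failure_backward" else "success",
         trajectory = traj,
         emg = .fixture_emg(coc, spec$emg_burst_amp, spec$fs_emg,
                            spec$duration),
         amplitude = amps[i])
  })
  attr(trials, "spec") <- spec
  trials
}

#' Metrics data frame of a synthetic trial series
#'
#' @param series a [make_trial_series()] result.
#' @return data frame with one row per trial (areas in cm^2).
#' @export
fixture_metrics <- function(series) {
  rows <- lapply(series, function(tr) {
    m <- compute_metrics(tr$trajectory, rise = 0.5, emg = tr$emg)
    data.frame(index = tr$index, outcome = tr$outcome,
               trajectory_area = m$trajectory_area,
               initial_trajectory_area = m$initial_trajectory_area,
               smoothness = m$smoothness,
               co_contraction = m$co_contraction)
  })
  do.call(rbind, rows)
}

#' Write / read a trial series as long-format CSV
#'
#' Columns `trial`, `outcome`, `t`, `x`, `y`; the same dialect as the
#' simulator trajectories with a trial index.
#'
#' @param series a [make_trial_series()] result.
#' @param path CSV file path.
#' @return `read_fixture_csv` returns a list of trial records with
#'   `index`, `outcome` and `trajectory` (no EMG round-trip).
#' @export
write_fixture_csv <- function(series, path) {
  rows <- lapply(series, function(tr) {
    cbind(trial = tr$index, outcome = tr$outcome, tr$trajectory)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trial = integer(), outcome = character(), t = numeric(),
               x = numeric(), y = numeric())
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fixture_csv
#' @export
read_fixture_csv <- function(path) {
  df <- read.csv(path)
  lapply(split(df, df$trial), function(d) {
    list(index = d$trial[1], outcome = d$outcome[1],
         trajectory = data.frame(t = d$t, x = d$x, y = d$y))
  })
}
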