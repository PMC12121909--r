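# analytic test paths
straight_traj <- function(n = 101, rise = 0.5) {
  t <- seq(0, 1.2, length.out = n)
  data.frame(t = t, x = rep(0, n), y = 0.55 + rise * t / 1.2)
}

offset_traj <- function(c_off, n = 101) {
  tr <- straight_traj(n)
  tr$x <- tr$x + c_off
  tr$x[1] <- 0  # rise from the origin, then constant offset
  tr
}

parabola_traj <- function(d, n = 2001) {
  t <- seq(0, 1.2, length.out = n)
  y <- 0.5 * t / 1.2
  data.frame(t = t, x = 4 * d * y * (0.5 - y) / 0.25, y = 0.55 + y)
}

test_that("trajectory normalization translates, scales isotropically, and is idempotent", {
  tr <- data.frame(t = 1:3, x = c(1, 1.2, 1.1), y = c(2, 2.5, 3))
  nt <- normalize_trajectory(tr)
  expect_equal(nt$x[1], 0)
  expect_equal(nt$y[1], 0)
  expect_equal(max(nt$y), 0.5)
  # isotropic: x scaled by the same factor as y (here 0.5 / 1.0)
  expect_equal(nt$x[2], (1.2 - 1) * 0.5)
  # already normalized input is unchanged
  expect_equal(normalize_trajectory(nt), nt)
  # straight line stays straight
  tr2 <- data.frame(t = 1:5, x = seq(0, 1, length.out = 5),
                    y = seq(0, 2, length.out = 5))
  nt2 <- normalize_trajectory(tr2)
  expect_equal(cor(nt2$x, nt2$y), 1)
  expect_error(normalize_trajectory(data.frame(t = 1:2, x = 0:1,
                                               y = c(1, 1))), "rise")
})

test_that("trajectory area matches closed forms on rectangle and parabola", {
  # straight vertical path: zero area
  expect_equal(trajectory_area(normalize_trajectory(straight_traj())), 0)
  # constant 2 cm offset: 0.02 * 0.5 m^2 = 100 cm^2
  nt <- normalize_trajectory(offset_traj(0.02))
  nt$x[1] <- 0.02  # ideal rectangle
  expect_equal(trajectory_area(nt), 100, tolerance = 1e-3)
  # parabolic bow, peak d = 2 cm: (2/3) * d * 0.5 = 66.67 cm^2
  nt2 <- normalize_trajectory(parabola_traj(0.02))
  expect_equal(trajectory_area(nt2), (2 / 3) * 0.02 * 0.5 * 1e4,
               tolerance = 66.67 * 1e-3)
  # sign flips under mirroring, scales linearly in x
  nt3 <- nt2; nt3$x <- -nt3$x
  expect_equal(trajectory_area(nt3), -trajectory_area(nt2),
               tolerance = 1e-9)
  nt4 <- nt2; nt4$x <- 2 * nt4$x
  expect_equal(trajectory_area(nt4), 2 * trajectory_area(nt2),
               tolerance = 1e-9)
})

test_that("initial trajectory area is the 2.5 cm truncation of the full area", {
  # constant 2 cm forward offset: 0.02 * 0.025 m^2 = 5 cm^2
  nt <- normalize_trajectory(offset_traj(0.02, n = 4001))
  nt$x[1] <- 0.02
  expect_equal(initial_trajectory_area(nt), 5, tolerance = 0.01)
  expect_equal(initial_trajectory_area(normalize_trajectory(straight_traj())),
               0)
  # ITA equals TA of the trajectory truncated at 2.5 cm height
  nt2 <- normalize_trajectory(parabola_traj(0.03, n = 8001))
  trunc <- nt2[seq_len(max(which(nt2$y <= 0.025)) + 1), ]
  expect_equal(initial_trajectory_area(nt2),
               trajectory_area(trunc, y_end = 0.025),
               tolerance = abs(initial_trajectory_area(nt2)) * 1e-3)
})

test_that("dimensionless jerk matches the analytic minimum-jerk value", {
  # 1-D minimum-jerk profile: jerk is (A/D^3)(60 - 360 tau + 360 tau^2),
  # whose squared integral over the unit interval is 720, and the
  # D^3 / v_mean^2 normalization cancels amplitude and duration exactly
  D <- 1.2; n <- 1201
  t <- seq(0, D, length.out = n); tau <- t / D
  x <- 0.3 * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
  tr <- data.frame(t = t, x = x, y = rep(1, n))
  expect_equal(smoothness(tr), 720, tolerance = 720 * 0.01)
  # invariant under time dilation (the D^3 / v_mean^2 normalization)
  t2 <- seq(0, 2 * D, length.out = n); tau2 <- t2 / (2 * D)
  x2 <- 0.3 * (10 * tau2^3 - 15 * tau2^4 + 6 * tau2^5)
  tr2 <- data.frame(t = t2, x = x2, y = rep(1, n))
  expect_equal(smoothness(tr2), smoothness(tr), tolerance = 720 * 0.01)
  # invariant under spatial translation
  tr3 <- tr; tr3$x <- tr3$x + 5; tr3$y <- tr3$y - 0.3
  expect_equal(smoothness(tr3), smoothness(tr), tolerance = 1e-6)
  # constant-velocity straight motion has zero jerk
  tr4 <- data.frame(t = t, x = t, y = rep(1, n))
  expect_lt(smoothness(tr4), 1e-12)
  # high-frequency noise strictly increases the squared jerk
  set.seed(3)
  tr5 <- tr; tr5$x <- tr5$x + rnorm(n, sd = 1e-4)
  expect_gt(smoothness(tr5), smoothness(tr))
})

test_that("co-contraction reproduces analytic envelope ratios", {
  fs <- 1000; t <- seq(0, 1.2, by = 1 / fs)
  carrier <- sin(2 * pi * 130 * t)
  env_a <- exp(-((t - 0.6)^2) / 0.05)
  emg <- emg_channels(env_a * carrier, env_a * carrier, fs)
  expect_equal(co_contraction(emg), 1, tolerance = 1e-6)
  emg2 <- emg_channels(2 * env_a * carrier, env_a * carrier, fs)
  expect_equal(co_contraction(emg2), 2, tolerance = 1e-6)
  # distinct analytic envelopes: ratio of envelope integrals
  env_b <- exp(-((t - 0.5)^2) / 0.02)
  emg3 <- emg_channels(env_a * carrier, env_b * sin(2 * pi * 170 * t), fs)
  exp_ratio <- sum(env_a) / sum(env_b)
  expect_equal(co_contraction(emg3), exp_ratio, tolerance = exp_ratio * 0.02)
  expect_error(co_contraction(emg_channels(carrier, 0 * carrier, fs)),
               "degenerate")
})

test_that("EMG filtering is zero-phase", {
  fs <- 1000
  x <- rep(0, 1001); x[501] <- 1  # centred impulse
  y <- ecomotor:::.emg_filter(x, fs)
  # symmetric impulse response about the impulse position
  expect_equal(y[501 + 1:100], y[501 - 1:100], tolerance = 1e-10)
})

test_that("peak displacements report the stored extrema in cm", {
  nt <- normalize_trajectory(parabola_traj(0.02))
  pk <- peak_displacements(nt)
  expect_equal(pk$forward, max(nt$x) * 100)
  expect_equal(pk$backward, min(nt$x) * 100)
  pk0 <- peak_displacements(normalize_trajectory(straight_traj()))
  expect_equal(pk0$forward, 0)
  expect_equal(pk0$backward, 0)
  # backward-then-forward bow keeps both signs
  nt2 <- normalize_trajectory(straight_traj(n = 201))
  nt2$x <- 0.01 * sin(4 * pi * nt2$y)
  pk2 <- peak_displacements(nt2)
  expect_gt(pk2$forward, 0)
  expect_lt(pk2$backward, 0)
})
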