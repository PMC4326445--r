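# The synthetic session generator: determinism, schedule structure,
# grip-force physics, trajectory band limits, serialization.

test_that("generators are pure functions of config and seed", {
  cfg <- tiny_config(seed = 3)
  expect_identical(generate_trajectory(cfg), generate_trajectory(cfg))
  expect_identical(generate_load_schedule(cfg), generate_load_schedule(cfg))
  cfg2 <- tiny_config(seed = 4)
  expect_false(identical(generate_trajectory(cfg)$hand,
                         generate_trajectory(cfg2)$hand))
})

test_that("trajectory is band-limited and confined to the workspace", {
  cfg <- reduced_profile(duration_s = 60, seed = 2,
                         trajectory_bandwidth_hz = 0.5, workspace_m = 0.8)
  traj <- generate_trajectory(cfg)
  expect_true(all(abs(traj$hand[1:3, ]) <= 0.8))
  expect_true(all(traj$hand[4:6, ] >= -180 & traj$hand[4:6, ] < 180))
  # power above 1 Hz (2x the bandwidth) is a trace fraction of the total
  sp <- stats::spec.pgram(traj$hand[1, ], plot = FALSE, taper = 0)
  f <- sp$freq * cfg$kin_rate_hz
  expect_lt(sum(sp$spec[f > 1]) / sum(sp$spec), 0.01)
  # shoulder barely moves
  expect_lt(max(abs(traj$shoulder)), 0.02)
})

test_that("load schedule tiles the session with alternating epochs", {
  cfg <- session_config(duration_s = 1920, seed = 5)
  sched <- generate_load_schedule(cfg)
  expect_equal(sched$start_s[1], 0)
  expect_equal(sched$end_s[nrow(sched)], 1920)
  expect_equal(sched$start_s[-1], sched$end_s[-nrow(sched)])
  # ~32 min with 2 min epochs: each of the four masses handled twice
  loaded <- sched$mass_g[sched$mass_g > 0]
  expect_length(loaded, 8)
  expect_equal(sort(unique(loaded)), c(100, 200, 500, 1000))
  expect_true(all(table(loaded) == 2))
  # loaded and unloaded epochs alternate
  expect_true(all(diff(sched$mass_g > 0) != 0))
})

test_that("degenerate schedules stay well-formed", {
  sched1 <- generate_load_schedule(session_config(duration_s = 120, seed = 1))
  expect_equal(sched1$start_s[1], 0)
  expect_equal(sched1$end_s[nrow(sched1)], 120)
  unl <- generate_load_schedule(session_config(duration_s = 300,
                                               load_masses_g = numeric(0)))
  expect_true(all(unl$mass_g == 0))
})

test_that("grip force follows load weight with inertial modulation", {
  # static hand: epoch-mean force inside a loaded epoch is m * g
  cfg <- reduced_profile(duration_s = 60, epoch_s = 15, seed = 9,
                         noise = list(force_n = 0))
  traj <- generate_trajectory(cfg)
  traj$hand[1:3, ] <- 0.2  # freeze the hand: no inertial force
  sched <- data.frame(start_s = c(0, 15, 30, 45), end_s = c(15, 30, 45, 60),
                      mass_g = c(0, 1000, 0, 500))
  force <- generate_grip_force(sched, traj, cfg)
  t_raw <- force$times_raw
  inner <- function(a, b) t_raw > a + 2 & t_raw < b - 2
  expect_equal(mean(force$raw[inner(15, 30)]), 1.0 * 9.80665, tolerance = 0.01)
  expect_lt(mean(force$raw[inner(0, 15)]), 0.05)
  # linearity: halving the mass halves the force
  expect_equal(mean(force$raw[inner(45, 60)]) * 2,
               mean(force$raw[inner(15, 30)]), tolerance = 0.02)
  expect_true(all(force$raw >= 0))
})

test_that("teacher activations are deterministic, bounded and force-sensitive", {
  cfg <- tiny_config(seed = 11)
  traj <- generate_trajectory(cfg)
  plant <- teacher_plant(cfg)
  n <- ncol(traj$hand)
  f0 <- rep(2, n)
  a0 <- teacher_activation(traj$hand, traj$shoulder, f0, plant)
  expect_identical(a0, teacher_activation(traj$hand, traj$shoulder, f0, plant))
  expect_true(all(a0 >= 0 & a0 <= 1))
  a1 <- teacher_activation(traj$hand, traj$shoulder, f0 + 2, plant)
  dd <- rowMeans(abs(a1 - a0))
  # distal muscles respond to force, proximal ones do not
  expect_gt(max(dd[7:12]), 0.01)
  expect_lt(max(dd[1:6]), 1e-12)
  # constant inputs give constant activations
  hc <- matrix(0.1, 6, 50); rownames(hc) <- rownames(traj$hand)
  sc <- matrix(0, 3, 50)
  ac <- teacher_activation(hc, sc, rep(1, 50), plant)
  expect_lt(max(apply(ac, 1, stats::sd)), 1e-12)
})

test_that("force-independent plant ignores the grip force entirely", {
  cfg <- tiny_config(seed = 12, force_dependent = FALSE)
  traj <- generate_trajectory(cfg)
  plant <- teacher_plant(cfg)
  n <- ncol(traj$hand)
  a0 <- teacher_activation(traj$hand, traj$shoulder, rep(0, n), plant)
  a1 <- teacher_activation(traj$hand, traj$shoulder, rep(8, n), plant)
  expect_equal(a0, a1, tolerance = 1e-12)
})

test_that("raw EMG is a band-limited carrier modulated by the activation", {
  cfg <- tiny_config(seed = 13)
  # constant activation: spectrum concentrates in the carrier band
  act <- matrix(0.8, 12, 60 * cfg$kin_rate_hz)
  rownames(act) <- rownames(tiny_session()$truth_activation)
  cfg2 <- cfg; cfg2$duration_s <- 60
  emg <- synthesize_raw_emg(act, cfg2)
  sp <- stats::spec.pgram(emg[1, ] - mean(emg[1, ]), plot = FALSE, taper = 0)
  f <- sp$freq * cfg$raw_rate_hz
  lo <- cfg$carrier_band_hz[1]; hi <- cfg$carrier_band_hz[2]
  expect_gt(sum(sp$spec[f >= lo & f <= hi]) / sum(sp$spec), 0.9)
  # zero activation: only offset + noise floor remains
  emg0 <- synthesize_raw_emg(act * 0, cfg2)
  expect_lt(stats::sd(emg0[1, ]), 2 * cfg$noise$emg)
  expect_lt(abs(mean(emg0[1, ]) - 0.02), 0.01)
})

test_that("sessions regenerate identically and round-trip through disk", {
  ses <- tiny_session()
  ses2 <- simulate_session(tiny_config())
  expect_identical(ses$raw_emg, ses2$raw_emg)
  expect_identical(ses$schedule, ses2$schedule)
  dir <- withr::local_tempdir()
  write_session(ses, dir)
  back <- read_session(dir)
  expect_equal(back$raw_emg, ses$raw_emg, tolerance = 1e-9)
  expect_equal(back$hand, ses$hand, tolerance = 1e-9)
  expect_equal(back$truth_activation, ses$truth_activation, tolerance = 1e-9)
  expect_equal(back$mvc_amplitude, ses$mvc_amplitude, tolerance = 1e-9)
  expect_equal(back$schedule$mass_g, ses$schedule$mass_g)
  expect_equal(back$config$raw_rate_hz, ses$config$raw_rate_hz)
})

test_that("unloaded sessions carry no grip force", {
  cfg <- tiny_config(seed = 14)
  cfg$load_masses_g <- numeric(0)
  ses <- simulate_session(cfg)
  expect_lt(mean(ses$grip_force), 0.1)
})
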