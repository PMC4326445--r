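# The teacher plant: the synthetic ground-truth mapping from kinematics and
# grip force to the 12 muscle activations.  Each muscle owns a small bank of
# tanh units reading the current and two-step-delayed feature vector — the
# same tapped-delay structure the predictor uses — so in the noiseless limit
# the mapping is exactly representable by a single-hidden-layer tanh network
# with at least 12 * teacher_units hidden units.

TEACHER_FORCE_SCALE <- 10  # newtons; nominal grip-force scale for the plant

#' Build a teacher plant
#'
#' @param config a [session_config()]; `force_dependent`, `mismatched_plant`
#'   and `teacher_units` shape the plant.
#' @param seed substream seed (defaults to the config's plant stream, so one
#'   base seed fixes the plant; pass the same plant seed with different
#'   trajectory seeds to emulate several sessions from one "subject").
#' @return a `teacher_plant` object.
#' @export
teacher_plant <- function(config, seed = substream_seed(config$seed, "plant")) {
  u <- config$teacher_units
  n_feat <- 7L            # x, y, z, pitch, roll, yaw, force (scaled)
  n_in <- 3L * n_feat     # current + two delayed copies
  force_cols <- c(7L, 14L, 21L)
  # reference session for gain calibration, drawn from the plant's own
  # substream with the generator itself, so calibrated modulation depths
  # carry over to real sessions
  cal_cfg <- config
  cal_cfg$duration_s <- 180
  cal_cfg$seed <- substream_seed(seed, "calibration")
  if (!length(cal_cfg$load_masses_g)) cal_cfg$load_masses_g <- c(100, 200, 500, 1000)
  traj_cal <- generate_trajectory(cal_cfg)
  force_cal <- generate_grip_force(generate_load_schedule(cal_cfg), traj_cal, cal_cfg)
  with_seed(seed, {
    U_cal <- embed3(rbind(
      (traj_cal$hand[1:3, ] - traj_cal$shoulder) / config$workspace_m,
      traj_cal$hand[4:6, ] / 180,
      force = force_cal$kin / TEACHER_FORCE_SCALE))
    W <- vector("list", 12); b <- vector("list", 12)
    cw <- vector("list", 12); c0 <- numeric(12)
    for (m in 1:12) {
      Wm <- matrix(stats::rnorm(u * n_in, 0, 2 / sqrt(n_in)), u, n_in)
      if (!(config$force_dependent && MUSCLES[m] %in% DISTAL)) {
        Wm[, force_cols] <- 0
      } else {
        # distal muscles: strengthen the force pathway so holding an object
        # visibly reshapes their activation
        Wm[, force_cols] <- Wm[, force_cols] * 2 +
          matrix(stats::rnorm(u * 3, 0, 0.35), u, 3)
      }
      bm <- stats::rnorm(u, 0, 0.5)
      cm <- stats::rnorm(u)
      # equalize unit contributions (a saturated unit otherwise freezes the
      # muscle), then calibrate the output gain to a 0.18 modulation SD,
      # capped so the output range stays inside [0, 1] without clipping
      h_cal <- tanh(Wm %*% U_cal + bm)
      cm <- cm / pmax(apply(h_cal, 1, stats::sd), 0.05)
      out_cal <- as.numeric(crossprod(cm, h_cal))
      out_cal <- out_cal - mean(out_cal)
      gain <- min(0.18 / max(stats::sd(out_cal), 1e-8),
                  0.40 / max(abs(out_cal)))
      cm <- cm * gain
      W[[m]] <- Wm; b[[m]] <- bm; cw[[m]] <- cm
      c0[m] <- 0.5 - sum(cm * rowMeans(tanh(Wm %*% U_cal + bm)))
    }
    vel_w <- if (config$mismatched_plant)
      matrix(stats::rnorm(12 * 3, 0, 0.05), 12, 3) else NULL
    structure(list(W = W, b = b, cw = cw, c0 = c0, units = u,
                   workspace_m = config$workspace_m,
                   orientation_range_deg = config$orientation_range_deg,
                   force_scale = TEACHER_FORCE_SCALE,
                   vel_w = vel_w, seed = seed),
              class = "teacher_plant")
  })
}

# scale raw kinematics + force into the plant's nondimensional feature space
teacher_features <- function(hand, shoulder, force_kin, plant) {
  pos <- (hand[1:3, , drop = FALSE] - shoulder) / plant$workspace_m
  ori <- hand[4:6, , drop = FALSE] / 180
  rbind(pos, ori, force = force_kin / plant$force_scale)
}

embed3 <- function(feat) {
  # [f(t), f(t-1), f(t-2)] with the first samples held (columns = time)
  n <- ncol(feat)
  i1 <- c(1, 1:(n - 1)); i2 <- c(1, 1, 1:(n - 2))
  rbind(feat, feat[, i1, drop = FALSE], feat[, i2, drop = FALSE])
}

#' Ground-truth muscle activations from the teacher plant
#'
#' Deterministic given the plant; optional zero-mean Gaussian noise (clipped
#' back into [0, 1]) models trial-to-trial motor variability and sets the
#' noise ceiling of any predictor.
#'
#' @param hand 6 x T hand kinematics (meters / degrees) at the kinematic rate.
#' @param shoulder 3 x T shoulder position, meters.
#' @param force_kin length-T grip force at the kinematic rate, newtons.
#' @param plant a [teacher_plant()].
#' @param noise_sd activation noise SD (0 = noiseless truth).  The noise is
#'   band-limited to 3 Hz — motor-command variability is slow — so it passes
#'   the envelope chain and sets a genuine prediction ceiling.
#' @param seed RNG seed for the noise draw.
#' @param rate_hz sampling rate of the activation traces (for the noise
#'   band limit).
#' @return 12 x T activation matrix in [0, 1], rownames = muscle names.
#' @export
teacher_activation <- function(hand, shoulder, force_kin, plant,
                               noise_sd = 0, seed = 1, rate_hz = 120) {
  U <- embed3(teacher_features(hand, shoulder, force_kin, plant))
  act <- matrix(0, 12, ncol(U), dimnames = list(MUSCLES, NULL))
  for (m in 1:12) {
    H <- tanh(plant$W[[m]] %*% U + plant$b[[m]])
    act[m, ] <- plant$c0[m] + as.numeric(crossprod(plant$cw[[m]], H))
  }
  if (!is.null(plant$vel_w)) {
    n <- ncol(hand)
    vel <- (hand[1:3, c(2:n, n), drop = FALSE] -
              hand[1:3, c(1, 1:(n - 1)), drop = FALSE]) / 2
    act <- act + plant$vel_w %*% tanh(vel * 50)
  }
  if (noise_sd > 0) {
    noise <- with_seed(seed, t(vapply(seq_len(nrow(act)), function(m) {
      n <- band_limited_noise(ncol(act), rate_hz, min(3, rate_hz / 4))
      n / stats::sd(n) * noise_sd
    }, numeric(ncol(act)))))
    act <- act + noise
  }
  pmin(pmax(act, 0), 1)
}

#' Synthesize raw EMG from activations
#'
#' Each channel is a band-limited Gaussian carrier (unit variance inside the
#' configured band, emulating the 100-475 Hz surface EMG passband)
#' amplitude-modulated by the activation upsampled to the raw rate, plus a
#' small DC offset and additive sensor noise.  Rectifying and 2 Hz-smoothing
#' the output recovers the activation up to a fixed scale.
#'
#' @param truth_activation 12 x T activation matrix at the kinematic rate.
#' @param config a [session_config()].
#' @param seed substream seed.
#' @return 12 x (duration * raw rate) EMG matrix, arbitrary units.
#' @export
synthesize_raw_emg <- function(truth_activation, config,
                               seed = substream_seed(config$seed, "carrier")) {
  n_raw <- round(config$duration_s * config$raw_rate_hz)
  t_raw <- seq(0, by = 1 / config$raw_rate_hz, length.out = n_raw)
  t_kin <- seq(0, by = 1 / config$kin_rate_hz, length.out = ncol(truth_activation))
  sos <- butter_sos(4, config$carrier_band_hz, config$raw_rate_hz, "pass")
  with_seed(seed, {
    emg <- matrix(0, nrow(truth_activation), n_raw,
                  dimnames = list(rownames(truth_activation), NULL))
    for (m in seq_len(nrow(truth_activation))) {
      act_raw <- stats::approx(t_kin, truth_activation[m, ], xout = t_raw, rule = 2)$y
      carrier <- sosfilt(sos, stats::rnorm(n_raw))
      carrier <- carrier / stats::sd(carrier)
      emg[m, ] <- act_raw * carrier + 0.02 +
        stats::rnorm(n_raw, 0, config$noise$emg)
    }
    emg
  })
}

#' Simulate a complete recording session
#'
#' Composes trajectory, load schedule, grip force, teacher activations, raw
#' EMG synthesis and an MVC reference (a 2 s full-activation burst per muscle
#' pushed through the same envelope chain; its maximum is the normalization
#' amplitude).  Every stage draws from a named substream of `config$seed`,
#' so regeneration is bit-identical.
#'
#' @param config a [session_config()].
#' @param plant optionally a fixed [teacher_plant()] shared across sessions
#'   (the "same subject" case); by default derived from `config$seed`.
#' @param realization replicate index for the noise substreams (activation
#'   noise, carriers, sensor noise).  Two sessions differing only in
#'   `realization` share trajectory, schedule and plant — correlating their
#'   processed envelopes estimates the noise ceiling.
#' @return an `emg_session` object.
#' @export
simulate_session <- function(config, plant = NULL, realization = 1L) {
  traj <- generate_trajectory(config)
  sched <- generate_load_schedule(config)
  force <- generate_grip_force(sched, traj, config,
                               seed = substream_seed(config$seed, "force", realization))
  if (is.null(plant)) plant <- teacher_plant(config)
  truth <- teacher_activation(traj$hand, traj$shoulder, force$kin, plant,
                              noise_sd = config$noise$activation,
                              seed = substream_seed(config$seed, "actnoise", realization),
                              rate_hz = config$kin_rate_hz)
  emg <- synthesize_raw_emg(truth, config,
                            seed = substream_seed(config$seed, "carrier", realization))
  mvc <- mvc_amplitudes(config, seed = substream_seed(config$seed, "mvc"))
  structure(list(
    raw_emg = emg, grip_force = force$raw,
    hand = traj$hand, shoulder = traj$shoulder,
    truth_activation = truth, mvc_amplitude = mvc,
    schedule = sched, grip_force_kin = force$kin,
    times_kin = traj$times, times_raw = force$times_raw,
    config = config, plant_seed = plant$seed
  ), class = "emg_session")
}

# MVC reference: per muscle, a 2 s maximal burst is synthesized with the
# session's carrier statistics and pushed through the standard envelope
# chain; the envelope maximum is the reference amplitude.
mvc_amplitudes <- function(config, seed) {
  dur <- 4  # seconds: 1 s rest, 2 s contraction, 1 s rest
  n_kin <- round(dur * config$kin_rate_hz)
  t_kin <- seq(0, by = 1 / config$kin_rate_hz, length.out = n_kin)
  burst <- as.numeric(t_kin >= 1 & t_kin < 3)
  cfg <- config; cfg$duration_s <- dur
  mvc <- numeric(12)
  for (m in 1:12) {
    raw <- synthesize_raw_emg(matrix(burst, 1), cfg,
                              seed = substream_seed(seed, "mvc_burst", m))
    env <- rectify_smooth(remove_dc(raw[1, ], cfg$raw_rate_hz), cfg$raw_rate_hz)
    mvc[m] <- max(env)
  }
  names(mvc) <- MUSCLES
  mvc
}

#' @export
print.emg_session <- function(x, ...) {
  loaded <- sum(x$schedule$mass_g > 0)
  cat(sprintf("Synthetic EMG session: %.0f s, %d loaded epochs\n",
              x$config$duration_s, loaded))
  cat(sprintf("  raw %g Hz (12 EMG + force), kinematics %g Hz\n",
              x$config$raw_rate_hz, x$config$kin_rate_hz))
  cat(sprintf("  masses: %s g\n",
              paste(unique(x$schedule$mass_g[x$schedule$mass_g > 0]), collapse = ", ")))
  invisible(x)
}
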