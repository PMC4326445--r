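# Synthetic recording sessions: free arm movements in peri-personal space,
# with alternating epochs of holding weighted objects.  Every generated
# signal has known ground truth (the teacher plant's muscle activations), so
# the whole prediction pipeline can be validated without subject recordings.

GRAVITY <- 9.80665  # m/s^2

MUSCLES <- c("SerrAnt", "AntDelt", "PostDelt", "PectMaj", "LatDors", "TeresMaj",
             "Biceps", "Brachialis", "BrachRad", "Triceps", "ECR", "FCR")
# forearm/elbow muscles respond to the handled load; shoulder girdle ones do not
DISTAL <- MUSCLES[7:12]

#' Configuration of a synthetic recording session
#'
#' Defaults mirror the experimental protocol being emulated: 12-channel EMG
#' sampled at 2500 Hz, kinematics at 120 Hz, ~2-minute epochs alternating
#' between free movement and moving one of four objects (100, 200, 500,
#' 1000 g), grip force proportional to load weight with inertial modulation.
#'
#' @param duration_s session length in seconds.
#' @param raw_rate_hz sampling rate of EMG and grip force.
#' @param kin_rate_hz sampling rate of kinematics (and of ground-truth
#'   activations).
#' @param load_masses_g object masses in grams; `numeric(0)` gives an
#'   unloaded session.
#' @param epoch_s nominal epoch length in seconds.
#' @param workspace_m half-width of the reachable workspace per axis, meters.
#' @param orientation_range_deg half-range of hand orientation excursions,
#'   kept below 180 so orientations never wrap.
#' @param trajectory_bandwidth_hz bandwidth of the random hand trajectory
#'   (white noise low-pass filtered at this cutoff).
#' @param grip_gain grip force per newton of load weight (dimensionless).
#' @param inertial_gain grip force per newton of inertial force.
#' @param carrier_band_hz EMG carrier band, Hz; must fit under the raw
#'   Nyquist frequency.
#' @param noise list of additive noise SDs: `position_m`, `orientation_deg`,
#'   `shoulder_m`, `force_n`, `activation`, `emg` (raw EMG channel units).
#' @param force_dependent logical; if `TRUE` the distal muscles of the
#'   teacher plant depend on grip force (the study's premise), if `FALSE` no
#'   muscle does (ablation).
#' @param mismatched_plant logical; add an unmodelled velocity dependence to
#'   the plant so the mapping is no longer exactly learnable.
#' @param wrap_stress logical; force orientation traces across the +/-180
#'   degree boundary to exercise unwrapping.
#' @param teacher_units tanh units per muscle in the teacher plant.
#' @param seed base seed; all stage substreams derive from it.
#' @return a `session_config` list.
#' @seealso [simulate_session()], [reduced_profile()]
#' @export
session_config <- function(duration_s = 1920,
                           raw_rate_hz = 2500,
                           kin_rate_hz = 120,
                           load_masses_g = c(100, 200, 500, 1000),
                           epoch_s = 120,
                           workspace_m = 0.8,
                           orientation_range_deg = 150,
                           trajectory_bandwidth_hz = 0.5,
                           grip_gain = 1,
                           inertial_gain = 1,
                           carrier_band_hz = c(100, 475),
                           noise = list(),
                           force_dependent = TRUE,
                           mismatched_plant = FALSE,
                           wrap_stress = FALSE,
                           teacher_units = 2,
                           seed = 1) {
  check_scalar(duration_s, "duration_s", positive = TRUE)
  check_scalar(raw_rate_hz, "raw_rate_hz", positive = TRUE)
  check_scalar(kin_rate_hz, "kin_rate_hz", positive = TRUE)
  check_scalar(epoch_s, "epoch_s", positive = TRUE)
  check_scalar(trajectory_bandwidth_hz, "trajectory_bandwidth_hz", positive = TRUE)
  if (length(load_masses_g) && any(load_masses_g < 0))
    stop_invalid("load masses must be >= 0")
  if (length(carrier_band_hz) != 2L || carrier_band_hz[2] >= raw_rate_hz / 2)
    stop_invalid("carrier band must lie below the raw Nyquist frequency")
  noise_def <- list(position_m = 0.001, orientation_deg = 0.5, shoulder_m = 0.002,
                    force_n = 0.05, activation = 0.05, emg = 0.05)
  noise_def[names(noise)] <- noise
  structure(list(
    duration_s = duration_s, raw_rate_hz = raw_rate_hz, kin_rate_hz = kin_rate_hz,
    load_masses_g = load_masses_g, epoch_s = epoch_s,
    workspace_m = workspace_m, orientation_range_deg = orientation_range_deg,
    trajectory_bandwidth_hz = trajectory_bandwidth_hz,
    grip_gain = grip_gain, inertial_gain = inertial_gain,
    carrier_band_hz = carrier_band_hz, noise = noise_def,
    force_dependent = force_dependent, mismatched_plant = mismatched_plant,
    wrap_stress = wrap_stress, teacher_units = teacher_units,
    seed = as.integer(seed)
  ), class = "session_config")
}

#' Reduced-scale session profile
#'
#' A scaled-down session for development and continuous testing: 6 minutes,
#' raw rate 1000 Hz (with the carrier band moved to 100-400 Hz so it fits
#' under the Nyquist frequency), 30 s epochs.  The statistical structure —
#' alternating load epochs, force/load proportionality, carrier-modulated
#' EMG — is unchanged.
#'
#' @param duration_s session length, seconds.
#' @param loaded logical; `FALSE` removes all load epochs.
#' @param epoch_s epoch length, seconds.
#' @param ... further overrides passed to [session_config()].
#' @export
reduced_profile <- function(duration_s = 360, loaded = TRUE, epoch_s = 30, ...) {
  session_config(duration_s = duration_s, raw_rate_hz = 1000,
                 load_masses_g = if (loaded) c(100, 200, 500, 1000) else numeric(0),
                 epoch_s = epoch_s, carrier_band_hz = c(100, 400), ...)
}

band_limited_noise <- function(n, rate_hz, bandwidth_hz) {
  # generate with burn-in/out margins so filter edge transients never reach
  # the returned track
  trim <- ceiling(3 * rate_hz / bandwidth_hz)
  w <- stats::rnorm(n + 2 * trim)
  butter_filtfilt(w, rate_hz, bandwidth_hz, order = 4, type = "low")[(trim + 1):(trim + n)]
}

#' Generate random hand and shoulder kinematics
#'
#' Hand position follows a band-limited Gaussian process (white noise
#' low-pass filtered at the trajectory bandwidth) rescaled into the
#' workspace; orientations follow the same process scaled to the requested
#' range and never wrap; the shoulder stays near the origin with millimeter
#' jitter.
#'
#' @param config a [session_config()].
#' @param seed substream seed (defaults to the config's trajectory stream).
#' @return list with `hand` (6 x T matrix: x, y, z in meters, pitch, roll,
#'   yaw in degrees), `shoulder` (3 x T, meters) and `times` (seconds).
#' @export
generate_trajectory <- function(config, seed = substream_seed(config$seed, "trajectory")) {
  n <- round(config$duration_s * config$kin_rate_hz)
  if (n < 8) stop_invalid("session too short for trajectory generation")
  with_seed(seed, {
    smooth_track <- function(half_range, margin = 0.9) {
      x <- band_limited_noise(n, config$kin_rate_hz, config$trajectory_bandwidth_hz)
      x <- x - mean(x)
      x * (margin * half_range / max(abs(x)))
    }
    pos <- t(vapply(1:3, function(i)
      smooth_track(config$workspace_m) + stats::rnorm(n, 0, config$noise$position_m),
      numeric(n)))
    ori <- t(vapply(1:3, function(i)
      smooth_track(config$orientation_range_deg) +
        stats::rnorm(n, 0, config$noise$orientation_deg), numeric(n)))
    if (config$wrap_stress) {
      # push yaw across the +/-180 boundary and wrap it, as a raw sensor would
      ori[3, ] <- ((ori[3, ] + 170 + seq(0, 40, length.out = n) + 180) %% 360) - 180
    }
    shoulder <- t(vapply(1:3, function(i)
      band_limited_noise(n, config$kin_rate_hz, 1) * config$noise$shoulder_m,
      numeric(n)))
    hand <- rbind(pos, ori)
    rownames(hand) <- c("x", "y", "z", "pitch", "roll", "yaw")
    rownames(shoulder) <- c("sx", "sy", "sz")
    list(hand = hand, shoulder = shoulder,
         times = seq(0, by = 1 / config$kin_rate_hz, length.out = n))
  })
}

#' Generate the alternating load schedule
#'
#' Epochs of ~`epoch_s` seconds tile the session, alternating between free
#' movement (mass 0) and moving an object.  Within each pass through the
#' object set, masses are drawn in random order without replacement; passes
#' repeat until the session ends, so a ~32 minute session with 2-minute
#' epochs handles each of the four objects twice.
#'
#' @inheritParams generate_trajectory
#' @return data frame with `start_s`, `end_s`, `mass_g`, one row per epoch.
#' @export
generate_load_schedule <- function(config, seed = substream_seed(config$seed, "schedule")) {
  d <- config$duration_s
  if (!length(config$load_masses_g))
    return(data.frame(start_s = 0, end_s = d, mass_g = 0))
  n_epochs <- max(1L, floor(d / config$epoch_s))
  starts <- seq(0, by = config$epoch_s, length.out = n_epochs)
  ends <- c(starts[-1], d)
  loaded <- seq_len(n_epochs) %% 2 == 0  # epochs 2, 4, ... carry an object
  n_loaded <- sum(loaded)
  masses <- with_seed(seed, {
    m <- unlist(lapply(seq_len(ceiling(n_loaded / length(config$load_masses_g))),
                       function(i) sample(config$load_masses_g)))
    m[seq_len(n_loaded)]
  })
  mass_g <- numeric(n_epochs)
  mass_g[loaded] <- masses
  data.frame(start_s = starts, end_s = ends, mass_g = mass_g)
}

#' Generate the thumb grip-force trace
#'
#' Within loaded epochs the normal force is proportional to the load weight
#' plus an inertial component proportional to the hand's acceleration
#' magnitude, with half-second ramps at epoch boundaries; outside them only
#' sensor noise remains.  The trace is clipped at zero (the sensor cannot
#' pull).
#'
#' @param schedule output of [generate_load_schedule()].
#' @param trajectory output of [generate_trajectory()].
#' @param config a [session_config()].
#' @param seed substream seed.
#' @return list with `raw` (noisy trace at the raw rate, newtons), `kin`
#'   (noise-free force at the kinematic rate, the plant's input) and
#'   `times_raw`.
#' @export
generate_grip_force <- function(schedule, trajectory, config,
                                seed = substream_seed(config$seed, "force")) {
  n_raw <- round(config$duration_s * config$raw_rate_hz)
  t_raw <- seq(0, by = 1 / config$raw_rate_hz, length.out = n_raw)
  t_kin <- trajectory$times
  if (abs(t_kin[length(t_kin)] - config$duration_s) > 1)
    stop_invalid("schedule and kinematics span different durations")

  acc <- hand_acceleration(trajectory$hand[1:3, , drop = FALSE], config$kin_rate_hz)
  acc_mag_kin <- sqrt(colSums(acc^2))

  # load + inertial force profile at kin rate, with raised-cosine ramps
  mass_kg <- numeric(length(t_kin))
  for (i in seq_len(nrow(schedule))) {
    idx <- t_kin >= schedule$start_s[i] & t_kin < schedule$end_s[i]
    mass_kg[idx] <- schedule$mass_g[i] / 1000
  }
  base_kin <- config$grip_gain * mass_kg * GRAVITY +
    config$inertial_gain * mass_kg * acc_mag_kin
  ramp <- ramp_envelope(mass_kg > 0, config$kin_rate_hz, ramp_s = 0.5)
  # grip modulation is neurally smooth: band-limit the commanded force
  # profile to 2.5 Hz (the rectified inertial term would otherwise carry
  # frequency-doubled content past the envelope band)
  base_kin <- pmax(butter_filtfilt(base_kin * ramp, config$kin_rate_hz, 2.5,
                                   order = 4, type = "low"), 0)

  base_raw <- stats::approx(t_kin, base_kin, xout = pmin(t_raw, t_kin[length(t_kin)]),
                            rule = 2)$y
  raw <- with_seed(seed, {
    noise <- butter_filtfilt(stats::rnorm(n_raw, 0, config$noise$force_n),
                             config$raw_rate_hz, min(20, config$raw_rate_hz / 4),
                             order = 2, type = "low")
    pmax(base_raw + noise, 0)
  })
  list(raw = raw, kin = base_kin, times_raw = t_raw)
}

# acceleration by twice-applied central differences on the (already smooth)
# position tracks
hand_acceleration <- function(pos, rate_hz) {
  diff1 <- function(x) {
    n <- length(x)
    c(x[2] - x[1], (x[3:n] - x[1:(n - 2)]) / 2, x[n] - x[n - 1]) * rate_hz
  }
  t(apply(t(apply(pos, 1, diff1)), 1, diff1))
}

# smooth 0->1 transitions of a logical mask over ramp_s seconds
ramp_envelope <- function(active, rate_hz, ramp_s = 0.5) {
  k <- max(1L, round(ramp_s * rate_hz))
  env <- as.numeric(active)
  # moving-average of the mask with a cosine window yields smooth ramps
  w <- 0.5 * (1 - cos(2 * pi * seq_len(2 * k + 1) / (2 * k + 2)))
  w <- w / sum(w)
  pad <- c(rep(env[1], k), env, rep(env[length(env)], k))
  as.numeric(stats::filter(pad, w, sides = 2))[(k + 1):(k + length(env))]
}
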