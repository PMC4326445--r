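# The conditioning chain: EMG -> DC removal (0.1 Hz high-pass), full-wave
# rectification, 2 Hz low-pass envelope, downsampling to the 120 Hz
# kinematic grid, MVC normalization; kinematics -> shoulder-relative,
# displacement-normalized, 6 Hz low-pass.  All filters are 6th-order
# zero-phase Butterworth in second-order sections.

#' Remove the DC offset of raw EMG
#'
#' 0.1 Hz sixth-order zero-phase Butterworth high-pass.
#'
#' @param x raw EMG vector (or matrix, channels in rows).
#' @param rate_hz sampling rate.
#' @export
remove_dc <- function(x, rate_hz) {
  butter_filtfilt(x, rate_hz, 0.1, order = 6, type = "high")
}

#' Full-wave rectify and smooth to the EMG envelope
#'
#' Absolute value followed by a 2 Hz sixth-order zero-phase Butterworth
#' low-pass; small negative filter ringing is clipped to zero.
#'
#' @inheritParams remove_dc
#' @export
rectify_smooth <- function(x, rate_hz) {
  pmax(butter_filtfilt(abs(x), rate_hz, 2, order = 6, type = "low"), 0)
}

#' Resample a raw-rate series onto the kinematic time grid
#'
#' Linear interpolation; legitimate only because the envelope chain has
#' already band-limited the series far below the target Nyquist frequency.
#'
#' @param x series at the raw rate (vector or channels-in-rows matrix).
#' @param raw_rate_hz its sampling rate.
#' @param kin_times target timestamps, seconds (first raw sample = time 0).
#' @export
resample_to_kin_grid <- function(x, raw_rate_hz, kin_times) {
  resample1 <- function(v) {
    t_raw <- seq(0, by = 1 / raw_rate_hz, length.out = length(v))
    if (min(kin_times) < t_raw[1] - 1e-9 ||
        max(kin_times) > t_raw[length(t_raw)] + 1e-9)
      stop_invalid("kinematic times extend beyond the raw series (%.3f..%.3f s)",
                   t_raw[1], t_raw[length(t_raw)])
    stats::approx(t_raw, v, xout = kin_times, rule = 2)$y
  }
  if (is.matrix(x)) t(apply(x, 1, resample1)) else resample1(x)
}

#' Normalize EMG envelopes by MVC amplitude
#'
#' @param envelope 12 x T envelope matrix at the kinematic rate.
#' @param mvc_amplitude per-muscle reference amplitudes (> 0).
#' @return matrix of MVC-normalized envelopes (unitless, ~[0, 1]; values may
#'   exceed 1 if a session burst exceeds the MVC reference).
#' @export
normalize_emg <- function(envelope, mvc_amplitude) {
  if (length(mvc_amplitude) != nrow(envelope))
    stop_invalid("need one MVC amplitude per channel")
  bad <- which(!is.finite(mvc_amplitude) | mvc_amplitude <= 0)
  if (length(bad)) {
    nm <- if (!is.null(names(mvc_amplitude))) names(mvc_amplitude)[bad] else bad
    stop_invalid("nonpositive MVC amplitude for muscle(s): %s",
                 paste(nm, collapse = ", "))
  }
  envelope / mvc_amplitude
}

# unwrap angle traces (degrees) so sensor wrap events at +/-180 do not ring
# through the low-pass filter
unwrap_deg <- function(x) {
  d <- diff(x)
  corr <- cumsum(ifelse(d > 180, -360, ifelse(d < -180, 360, 0)))
  x + c(0, corr)
}

#' Normalize hand kinematics
#'
#' Positions are expressed relative to the shoulder and divided by the
#' session's maximal absolute shoulder-relative displacement (one scalar
#' across axes, so geometry is preserved); orientations are unwrapped and
#' divided by 180 degrees.  All six channels are then low-pass filtered at
#' 6 Hz (sixth-order zero-phase Butterworth).
#'
#' @param hand 6 x T matrix (x, y, z meters; pitch, roll, yaw degrees).
#' @param shoulder 3 x T shoulder position, meters.
#' @param rate_hz kinematic sampling rate.
#' @param per_axis if `TRUE`, normalize each position axis by its own
#'   maximum instead of the shared scalar.
#' @return list with `features` (6 x T normalized matrix) and `scale`
#'   (the displacement normalizer, meters).
#' @export
normalize_kinematics <- function(hand, shoulder, rate_hz, per_axis = FALSE) {
  rel <- hand[1:3, , drop = FALSE] - shoulder
  if (per_axis) {
    scale <- apply(abs(rel), 1, max)
    if (any(scale <= 0)) stop_invalid("zero hand displacement; cannot normalize")
    pos <- rel / scale
  } else {
    scale <- max(abs(rel))
    if (scale <= 0) stop_invalid("zero hand displacement; cannot normalize")
    pos <- rel / scale
  }
  ori <- t(apply(hand[4:6, , drop = FALSE], 1, unwrap_deg)) / 180
  feats <- butter_filtfilt(rbind(pos, ori), rate_hz, 6, order = 6, type = "low")
  rownames(feats) <- c("x", "y", "z", "pitch", "roll", "yaw")
  list(features = feats, scale = scale)
}

#' Run the full conditioning chain on a session
#'
#' Produces the time-aligned 120 Hz dataset the predictor consumes: six
#' normalized kinematic features plus the (6 Hz low-passed, resampled) grip
#' force as inputs, and twelve MVC-normalized EMG envelopes as targets.  The
#' session's ground-truth activations are carried along for evaluation.
#'
#' @param session an `emg_session` from [simulate_session()] or
#'   [read_session()].
#' @return an `emg_dataset` object.
#' @export
preprocess_session <- function(session) {
  cfg <- session$config
  kin <- normalize_kinematics(session$hand, session$shoulder, cfg$kin_rate_hz)
  force_f <- butter_filtfilt(session$grip_force, cfg$raw_rate_hz, 6,
                             order = 6, type = "low")
  force_kin <- resample_to_kin_grid(force_f, cfg$raw_rate_hz, session$times_kin)
  env <- rectify_smooth(remove_dc(session$raw_emg, cfg$raw_rate_hz), cfg$raw_rate_hz)
  env_kin <- resample_to_kin_grid(env, cfg$raw_rate_hz, session$times_kin)
  targets <- normalize_emg(env_kin, session$mvc_amplitude)
  features <- rbind(kin$features, force = force_kin)
  structure(list(
    times = session$times_kin,
    features = features,          # 7 x T: x y z pitch roll yaw force
    targets = targets,            # 12 x T, MVC-normalized
    truth_activation = session$truth_activation,
    schedule = session$schedule,
    mvc_amplitude = session$mvc_amplitude,
    norm_scale = kin$scale,
    config = cfg
  ), class = "emg_dataset")
}

#' @export
print.emg_dataset <- function(x, ...) {
  cat(sprintf("Processed EMG dataset: %d samples at %g Hz (%.0f s)\n",
              length(x$times), x$config$kin_rate_hz, x$config$duration_s))
  cat(sprintf("  features: %s\n", paste(rownames(x$features), collapse = ", ")))
  cat(sprintf("  targets: 12 MVC-normalized EMG envelopes\n"))
  invisible(x)
}
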