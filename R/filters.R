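# Butterworth design in zero-pole-gain form, realized as a cascade of
# second-order sections (SOS).  The conditioning chain needs a 6th-order
# filter with cutoffs as low as 0.1 Hz on 2500 Hz data; expanding such a
# design to a single transfer function is numerically unstable (the
# denominator roots cluster at z = 1), so the SOS realization is mandatory
# here, not an optimization.

butter_prototype_poles <- function(order) {
  k <- seq_len(order)
  exp(1i * pi * (2 * k + order - 1) / (2 * order))
}

#' Design a digital Butterworth filter as second-order sections
#'
#' @param order filter order (of the analog prototype; a bandpass design has
#'   twice this many poles).
#' @param cutoff_hz scalar cutoff for `"low"`/`"high"`, length-2 band edges
#'   for `"pass"`.
#' @param rate_hz sampling rate of the signal the filter will be applied to.
#' @param type `"low"`, `"high"` or `"pass"`.
#' @return a `butter_sos` object: a matrix with one row per biquad section,
#'   columns `b0 b1 b2 a0 a1 a2` (`a0` always 1).
#' @examples
#' sos <- butter_sos(6, 2, rate_hz = 120, type = "low")
#' @export
butter_sos <- function(order, cutoff_hz, rate_hz, type = c("low", "high", "pass")) {
  type <- match.arg(type)
  check_scalar(rate_hz, "rate_hz", positive = TRUE)
  if (!is.numeric(order) || length(order) != 1L || order != round(order) || order < 1)
    stop_invalid("'order' must be a positive integer")
  nyq <- rate_hz / 2
  if (any(!is.finite(cutoff_hz)) || any(cutoff_hz <= 0) || any(cutoff_hz >= nyq))
    stop_invalid("cutoff (%s Hz) must lie strictly inside (0, Nyquist = %g Hz)",
                 paste(cutoff_hz, collapse = ", "), nyq)

  fs2 <- 2 * rate_hz
  warp <- function(f) fs2 * tan(pi * f / rate_hz)
  p <- butter_prototype_poles(order)

  if (type == "low") {
    wc <- warp(cutoff_hz)
    zs <- complex(0); ps <- wc * p; ks <- wc^order
  } else if (type == "high") {
    wc <- warp(cutoff_hz)
    zs <- rep(0 + 0i, order); ps <- wc / p; ks <- 1
  } else {
    if (length(cutoff_hz) != 2L || cutoff_hz[1] >= cutoff_hz[2])
      stop_invalid("bandpass requires increasing band edges")
    w1 <- warp(cutoff_hz[1]); w2 <- warp(cutoff_hz[2])
    bw <- w2 - w1; w0 <- sqrt(w1 * w2)
    phalf <- p * bw / 2
    ps <- c(phalf + sqrt(phalf^2 - w0^2), phalf - sqrt(phalf^2 - w0^2))
    zs <- rep(0 + 0i, order); ks <- bw^order
  }

  # bilinear transform
  zd <- (fs2 + zs) / (fs2 - zs)
  pd <- (fs2 + ps) / (fs2 - ps)
  kd <- ks * Re(prod(fs2 - zs) / prod(fs2 - ps))
  zd <- c(zd, rep(-1 + 0i, length(pd) - length(zd)))  # zeros at Nyquist fill the degree

  sos <- zpk_to_sos(zd, pd, kd)
  structure(sos, class = "butter_sos", rate_hz = rate_hz, type = type,
            cutoff_hz = cutoff_hz, order = order)
}

# Pair conjugate poles/zeros into biquads.  Butterworth poles arrive in exact
# conjugate pairs (plus one real pole for odd orders); digital zeros sit at
# +/-1.  Sections are ordered with the poles farthest from the unit circle
# first, pushing the most resonant biquad to the end of the cascade.
zpk_to_sos <- function(z, p, k) {
  pair_up <- function(v) {
    out <- list()
    v <- v[order(Im(v), Re(v))]
    while (length(v)) {
      if (abs(Im(v[1])) > 1e-12) {
        j <- which.min(abs(v - Conj(v[1]))[-1]) + 1L
        out[[length(out) + 1L]] <- c(v[1], v[j]); v <- v[-c(1L, j)]
      } else {
        j <- which(abs(Im(v[-1])) <= 1e-12)
        if (length(j)) {
          out[[length(out) + 1L]] <- c(v[1], v[j[1] + 1L]); v <- v[-c(1L, j[1] + 1L)]
        } else {
          out[[length(out) + 1L]] <- v[1]; v <- v[-1L]
        }
      }
    }
    out
  }
  zp <- pair_up(z); pp <- pair_up(p)
  n_sec <- max(length(zp), length(pp))
  while (length(zp) < n_sec) zp[[length(zp) + 1L]] <- complex(0)
  while (length(pp) < n_sec) pp[[length(pp) + 1L]] <- complex(0)
  ord <- order(vapply(pp, function(q) max(c(0, abs(abs(q) - 1))), 0), decreasing = TRUE)
  zp <- zp[ord]; pp <- pp[ord]
  sos <- matrix(0, n_sec, 6)
  colnames(sos) <- c("b0", "b1", "b2", "a0", "a1", "a2")
  for (i in seq_len(n_sec)) {
    b <- Re(poly_from_roots(zp[[i]]))
    a <- Re(poly_from_roots(pp[[i]]))
    sos[i, ] <- c(pad3(b), pad3(a))
  }
  sos[1, 1:3] <- sos[1, 1:3] * k
  sos
}

poly_from_roots <- function(r) {
  coef <- 1 + 0i
  for (ri in r) coef <- c(coef, 0) - c(0, coef * ri)
  coef
}
pad3 <- function(x) c(x, rep(0, 3 - length(x)))

# One biquad, direct form, with "constant history" initialization: the state
# is initialized as if the input had been frozen at its first sample forever,
# which suppresses the start-up step transient (critical for the 0.1 Hz
# high-pass, whose transient outlives any reasonable padding).
biquad_filter <- function(b, a, x) {
  x0 <- x[1]
  dc <- sum(b) / sum(c(1, a))
  u <- x - x0
  n <- length(u)
  y <- b[1] * u
  if (n > 1) y[2:n] <- y[2:n] + b[2] * u[1:(n - 1)]
  if (n > 2) y[3:n] <- y[3:n] + b[3] * u[1:(n - 2)]
  y <- stats::filter(y, -a, method = "recursive")
  as.numeric(y) + dc * x0
}

#' Apply a second-order-sections filter in one direction
#' @param sos a `butter_sos` matrix.
#' @param x numeric vector.
#' @return filtered vector, same length as `x`.
#' @export
sosfilt <- function(sos, x) {
  for (i in seq_len(nrow(sos))) x <- biquad_filter(sos[i, 1:3], sos[i, 5:6], x)
  x
}

#' Zero-phase (forward-backward) second-order-sections filtering
#'
#' The signal is extended at both ends by odd reflection before the forward
#' pass, filtered, reversed, filtered again and re-reversed, so the net
#' magnitude response is the squared one-pass response and the phase response
#' is identically zero.
#'
#' @inheritParams sosfilt
#' @export
sosfiltfilt <- function(sos, x) {
  n <- length(x)
  if (any(!is.finite(x))) stop_invalid("input signal contains non-finite values")
  # pad to roughly 6 time constants of the slowest pole
  rho <- max(vapply(seq_len(nrow(sos)), function(i) {
    a <- sos[i, 4:6]
    if (abs(a[3]) < 1e-300 && abs(a[2]) < 1e-300) return(0)
    max(Mod(polyroot(rev(a))))
  }, 0))
  settle <- if (rho >= 1) n - 1L else ceiling(6 / max(1 - rho, 1e-6))
  npad <- min(n - 1L, max(9L * nrow(sos) + 3L, settle), 50000L)
  if (npad > 0) {
    front <- 2 * x[1] - x[(npad + 1):2]
    back <- 2 * x[n] - x[(n - 1):(n - npad)]
    xe <- c(front, x, back)
  } else xe <- x
  y <- sosfilt(sos, xe)
  y <- rev(sosfilt(sos, rev(y)))
  if (npad > 0) y <- y[(npad + 1):(npad + n)]
  y
}

#' Zero-phase Butterworth filtering of one or more channels
#'
#' Designs the requested Butterworth filter and applies it forward-backward.
#' Per common practice the stated order is the design order of each pass, so
#' the magnitude response of the zero-phase result is that order squared; use
#' half the order if a net magnitude of the stated order is wanted.
#'
#' @param x numeric vector, or a matrix with one channel per row.
#' @param rate_hz sampling rate in Hz.
#' @param cutoff_hz cutoff (scalar, or band edges for `type = "pass"`).
#' @param order design order (default 6, the conditioning chain's standard).
#' @param type `"low"`, `"high"` or `"pass"`.
#' @return filtered data with the shape of `x`.
#' @examples
#' t <- seq(0, 5, by = 1 / 120)
#' x <- sin(2 * pi * 1 * t) + sin(2 * pi * 30 * t)
#' y <- butter_filtfilt(x, 120, cutoff_hz = 6)
#' @export
butter_filtfilt <- function(x, rate_hz, cutoff_hz, order = 6, type = c("low", "high", "pass")) {
  type <- match.arg(type)
  sos <- butter_sos(order, cutoff_hz, rate_hz, type)
  if (is.matrix(x)) t(apply(x, 1, function(ch) sosfiltfilt(sos, ch))) else sosfiltfilt(sos, x)
}
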