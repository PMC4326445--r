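# Butterworth design and zero-phase filtering: checked against closed-form
# magnitude responses and phase properties, not against another library.

test_that("design rejects invalid specs and bad input", {
  expect_error(butter_sos(6, 70, 120, "low"), "Nyquist")
  expect_error(butter_sos(6, 0, 120, "low"), "Nyquist")
  expect_error(butter_sos(0, 2, 120, "low"), "positive integer")
  expect_error(butter_sos(4, c(10, 5), 120, "pass"), "increasing")
  expect_error(sosfiltfilt(butter_sos(2, 2, 120, "low"), c(1, NA, 3)), "non-finite")
})

test_that("low-pass has unit DC gain: constants pass through unchanged", {
  sos <- butter_sos(6, 2, 2500, "low")
  x <- rep(3.7, 2000)
  expect_lt(max(abs(sosfiltfilt(sos, x) - 3.7)), 1e-9)
})

test_that("bidirectional pass attenuates the cutoff sinusoid to one half", {
  # |H|^2 at the cutoff of a Butterworth is exactly 1/2 regardless of order
  for (spec in list(c(2, 120), c(6, 120), c(6, 2500))) {
    fs <- spec[2]; fc <- 2
    t <- seq(0, 40, by = 1 / fs)
    y <- butter_filtfilt(sin(2 * pi * fc * t), fs, fc, order = spec[1])
    mid <- seq(round(length(t) * 0.3), round(length(t) * 0.7))
    expect_equal(max(abs(y[mid])), 0.5, tolerance = 0.01)
  }
})

test_that("zero-phase: cross-correlation with the input peaks at lag 0", {
  fs <- 120
  t <- seq(0, 60, by = 1 / fs)
  x <- sin(2 * pi * 1 * t) + 0.5 * sin(2 * pi * 3 * t)
  y <- butter_filtfilt(x, fs, 6, order = 6)
  cc <- stats::ccf(x, y, lag.max = 20, plot = FALSE)
  expect_identical(cc$lag[which.max(cc$acf)], 0)
  # and a one-directional pass does lag, confirming the check has power
  y1 <- sosfilt(butter_sos(6, 6, fs, "low"), x)
  cc1 <- stats::ccf(x, y1, lag.max = 20, plot = FALSE)
  expect_gt(abs(cc1$lag[which.max(cc1$acf)]), 0)
})

test_that("high-pass removes offsets without touching the passband", {
  fs <- 2500
  set.seed(4)
  x <- stats::rnorm(fs * 60)
  y <- remove_dc(x + 0.5, fs)
  # residual mean reflects genuine sub-0.1 Hz noise power, not the offset
  expect_lt(abs(mean(y)), 0.01 * stats::sd(x))
  # passband content (>> 0.2 Hz) is preserved sample-for-sample
  t <- seq(0, 20, by = 1 / fs)
  s <- sin(2 * pi * 5 * t)
  ys <- remove_dc(s + 2, fs)
  mid <- seq(round(length(t) * 0.3), round(length(t) * 0.7))
  expect_lt(max(abs(ys[mid] - s[mid])), 0.01)
})

test_that("band-pass concentrates energy inside the band", {
  fs <- 1000
  set.seed(5)
  sos <- butter_sos(4, c(100, 400), fs, "pass")
  y <- sosfilt(sos, stats::rnorm(fs * 30))
  sp <- stats::spec.pgram(y, plot = FALSE, taper = 0)
  f <- sp$freq * fs
  inband <- sum(sp$spec[f >= 100 & f <= 400]) / sum(sp$spec)
  expect_gt(inband, 0.95)
})

test_that("envelope extraction tracks an amplitude modulator", {
  fs <- 1000
  t <- seq(0, 60, by = 1 / fs)
  modulator <- 1 + 0.8 * sin(2 * pi * 0.25 * t)
  set.seed(6)
  carrier <- sosfilt(butter_sos(4, c(100, 400), fs, "pass"), stats::rnorm(length(t)))
  carrier <- carrier / stats::sd(carrier)
  env <- rectify_smooth(modulator * carrier, fs)
  expect_true(all(env >= 0))
  expect_gt(stats::cor(env, modulator), 0.95)
})

test_that("rectified constant-amplitude carrier gives the half-normal mean", {
  # E|N(0, A^2)| = A * sqrt(2/pi); the 2 Hz envelope of an unmodulated
  # carrier must sit at that level
  fs <- 1000
  set.seed(7)
  carrier <- sosfilt(butter_sos(4, c(100, 400), fs, "pass"), stats::rnorm(fs * 60))
  A <- 2.5
  env <- rectify_smooth(A * carrier / stats::sd(carrier), fs)
  mid <- seq(round(fs * 10), round(fs * 50))
  expect_equal(mean(env[mid]), A * sqrt(2 / pi), tolerance = 0.03)
})

test_that("scaling commutes with linear filtering", {
  fs <- 120
  set.seed(8)
  x <- stats::rnorm(3000)
  a <- butter_filtfilt(5 * x, fs, 6)
  b <- 5 * butter_filtfilt(x, fs, 6)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("resampling onto the kinematic grid is faithful for band-limited series", {
  fs <- 1000
  t_raw <- seq(0, 20, by = 1 / fs)
  kin_t <- seq(0.5, 19.5, by = 1 / 120)
  x <- sin(2 * pi * 1 * t_raw)
  y <- resample_to_kin_grid(x, fs, kin_t)
  expect_equal(length(y), length(kin_t))
  expect_lt(max(abs(y - sin(2 * pi * 1 * kin_t))), 1e-3)
  expect_equal(resample_to_kin_grid(rep(2, length(t_raw)), fs, kin_t),
               rep(2, length(kin_t)))
  expect_error(resample_to_kin_grid(x, fs, c(kin_t, 30)), "beyond")
})
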