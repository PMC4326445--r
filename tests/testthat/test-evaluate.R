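# Scoring: the correlation-based coefficient of determination and the
# per-muscle evaluation wrapper.

test_that("r_squared matches the Pearson definition and its edge cases", {
  a <- c(1, 2, 3, 4); p <- c(1.1, 2.0, 2.9, 4.2)
  # hand-computed squared Pearson correlation
  byhand <- (sum((a - mean(a)) * (p - mean(p))) /
               sqrt(sum((a - mean(a))^2) * sum((p - mean(p))^2)))^2
  expect_equal(r_squared(a, p), byhand, tolerance = 1e-12)
  expect_equal(r_squared(a, a), 1)
  # sign-invariance is a documented consequence of the definition
  expect_equal(r_squared(a, -a), 1)
  # affine invariance likewise
  expect_equal(r_squared(a, 3 * p + 7), r_squared(a, p), tolerance = 1e-12)
  expect_error(r_squared(rep(1, 4), p), "zero variance")
  expect_warning(expect_equal(r_squared(a, rep(2, 4)), 0), "zero variance")
  expect_error(r_squared(a, p[1:3]), "lengths differ")
  # the variance-explained alternative penalizes bias, unlike the default
  expect_lt(r_squared(a, p + 10, method = "variance_explained"), 0)
  expect_equal(r_squared(a, p + 10), byhand, tolerance = 1e-12)
})

test_that("evaluate_model scores each muscle and aggregates", {
  set.seed(20)
  d <- structure(list(
    X = matrix(stats::rnorm(300), 100, 3),
    Y = matrix(stats::rnorm(200), 100, 2,
               dimnames = list(NULL, c("AntDelt", "FCR")))),
    class = "delay_design")
  # an oracle model that emits the targets scores 1 everywhere
  oracle <- structure(list(net = NULL, scaler = NULL), class = "tdmlp")
  res <- with_mocked_bindings(
    evaluate_model(oracle, d),
    predict.tdmlp = function(object, newdata, ...) d$Y
  )
  expect_equal(unname(res$r2), c(1, 1))
  expect_named(res$r2, c("AntDelt", "FCR"))
})

test_that("independent noise predictions score near zero", {
  set.seed(21)
  n <- 2e4
  actual <- stats::rnorm(n)
  noise <- stats::rnorm(n)
  expect_lt(r_squared(actual, noise), 0.05)
})

test_that("noise ceiling is bounded and sensitive to the noise level", {
  quiet <- reduced_profile(duration_s = 45, epoch_s = 15, seed = 31,
                           noise = list(activation = 0.01))
  noisy <- reduced_profile(duration_s = 45, epoch_s = 15, seed = 31,
                           noise = list(activation = 0.15))
  c_quiet <- estimate_noise_ceiling(quiet, n_pairs = 1)
  c_noisy <- estimate_noise_ceiling(noisy, n_pairs = 1)
  expect_true(all(c_quiet >= 0 & c_quiet <= 1))
  expect_gt(mean(c_quiet), mean(c_noisy))
})

test_that("across-session transfer degrades gracefully with plant mismatch", {
  cfg_a <- reduced_profile(duration_s = 120, epoch_s = 15, seed = 41)
  ses_a <- simulate_session(cfg_a)
  # same plant, new movements: the "same subject, second session" case
  cfg_b <- cfg_a; cfg_b$seed <- 52
  ses_b <- simulate_session(cfg_b, plant = teacher_plant(cfg_a))
  # a genuinely different subject: different plant
  cfg_c <- reduced_profile(duration_s = 120, epoch_s = 15, seed = 63)
  ses_c <- simulate_session(cfg_c)
  within  <- across_session_transfer(ses_a, ses_a, hidden = 30, epochs = 80,
                                     learning_rate = 0.3, train_duration_s = 80)
  shared  <- across_session_transfer(ses_a, ses_b, hidden = 30, epochs = 80,
                                     learning_rate = 0.3, train_duration_s = 80)
  foreign <- across_session_transfer(ses_a, ses_c, hidden = 30, epochs = 80,
                                     learning_rate = 0.3, train_duration_s = 80)
  # same-plant transfer approaches within-session performance
  expect_gt(shared$mean, within$mean - 0.25)
  # and clearly beats transfer to a different plant
  expect_gt(shared$mean, foreign$mean)
})
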