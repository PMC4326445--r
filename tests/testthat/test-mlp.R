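# The MLP engine: initialization, forward pass, gradient correctness
# against finite differences, and the training loop's update rule.

test_that("initialization is seeded, bounded, and has the right parameter count", {
  net <- mlp_init(21, 30, 12, seed = 5)
  expect_identical(net, mlp_init(21, 30, 12, seed = 5))
  expect_false(identical(net$W, mlp_init(21, 30, 12, seed = 6)$W))
  # 21*30+30 weights+biases into the hidden layer, 30*12+12 out
  expect_equal(sum(lengths(net$W)) + sum(lengths(net$b)), 1032)
  expect_true(all(abs(net$W[[1]]) <= 1 / sqrt(21)))
  expect_true(all(abs(net$W[[2]]) <= 1 / sqrt(30)))
  expect_error(mlp_init(5, c(4, 0), 2), "positive integers")
})

test_that("forward pass matches a hand-computed tanh composition", {
  net <- mlp_init(2, 1, 1, seed = 1)
  net$W[[1]][] <- c(0.3, -0.2); net$b[[1]][] <- 0.1
  net$W[[2]][] <- 2; net$b[[2]][] <- -0.5
  x <- rbind(c(0.7, 0.4))
  expect_equal(mlp_forward(net, x)[1, 1],
               2 * tanh(0.3 * 0.7 - 0.2 * 0.4 + 0.1) - 0.5, tolerance = 1e-12)
  # zero weights give zero outputs
  net0 <- mlp_init(3, c(4, 2), 2, seed = 2)
  for (l in seq_along(net0$W)) { net0$W[[l]][] <- 0; net0$b[[l]][] <- 0 }
  expect_true(all(mlp_forward(net0, matrix(stats::rnorm(30), 10)) == 0))
  # row-wise independence: permuting rows permutes outputs
  net2 <- mlp_init(3, 5, 2, seed = 3)
  X <- matrix(stats::rnorm(30), 10)
  p <- sample(10)
  expect_equal(mlp_forward(net2, X[p, ]), mlp_forward(net2, X)[p, ])
  expect_error(mlp_forward(net2, X[, 1:2]), "expects")
})

test_that("analytic gradients agree with finite differences across architectures", {
  # scale-relative deviation; entrywise h = 1e-6 comparisons are limited by
  # cancellation noise where the true entry vanishes
  archs <- list(3, 8, c(4, 4), c(20, 9, 9, 20), 30)
  for (i in seq_along(archs)) {
    expect_lt(gradient_rel_err(archs[[i]], seed = i), 1e-7)
  }
})

test_that("gradients vanish at a perfect fit and respect mean-loss scaling", {
  net <- mlp_init(3, 4, 2, seed = 9)
  X <- matrix(stats::rnorm(60), 20)
  Y <- mlp_forward(net, X)
  g <- mlp_gradients(net, X, Y)
  expect_lt(max(abs(unlist(g$gW))), 1e-14)
  # duplicating the dataset leaves the mean-loss gradient unchanged
  Y2 <- Y + stats::rnorm(40)
  g1 <- mlp_gradients(net, X, Y2)
  g2 <- mlp_gradients(net, rbind(X, X), rbind(Y2, Y2))
  expect_equal(g1$gW, g2$gW, tolerance = 1e-12)
})

test_that("training implements momentum gradient descent exactly", {
  set.seed(10)
  X <- matrix(stats::rnorm(60), 20)
  Y <- matrix(stats::rnorm(40), 20)
  # learning rate 0: nothing moves
  f0 <- mlp_fit(X, Y, hidden = 4, epochs = 5, learning_rate = 0, seed = 3,
                scale_inputs = FALSE)
  expect_equal(coef(f0), unclass(mlp_init(3, 4, 2, seed = 3))[c("W", "b")],
               tolerance = 1e-15, ignore_attr = TRUE)
  expect_equal(stats::var(f0$trace), 0)
  # momentum 0, one epoch: theta - lr * grad, verbatim
  net0 <- mlp_init(3, 4, 2, seed = 3)
  g <- mlp_gradients(net0, X, Y)
  f1 <- mlp_fit(X, Y, hidden = 4, epochs = 1, learning_rate = 0.1,
                momentum = 0, seed = 3, scale_inputs = FALSE)
  expect_equal(coef(f1)$W[[1]], net0$W[[1]] - 0.1 * g$gW[[1]], tolerance = 1e-14)
  expect_equal(coef(f1)$b[[2]], net0$b[[2]] - 0.1 * g$gb[[2]], tolerance = 1e-14)
})

test_that("training reduces the loss on a learnable linear problem", {
  set.seed(11)
  X <- matrix(stats::rnorm(600), 200)
  Y <- X %*% matrix(c(1, -1, 0.5, 0.2, 0, -0.3), 3) + 0.5
  fit <- mlp_fit(X, Y, hidden = 5, epochs = 100, learning_rate = 0.05, seed = 4)
  expect_lt(fit$final_mse, fit$trace[1] / 5)
})

test_that("divergence raises a named error instead of returning garbage", {
  set.seed(12)
  X <- matrix(stats::rnorm(100) * 50, 50)
  Y <- matrix(stats::rnorm(100) * 50, 50)
  expect_error(
    mlp_fit(X, Y, hidden = 10, epochs = 200, learning_rate = 1e4,
            scale_inputs = FALSE),
    "diverged at epoch")
})

test_that("predict applies the stored scaler and stays finite off-range", {
  set.seed(13)
  X <- matrix(stats::runif(300, 0, 10), 100)
  Y <- cbind(sin(X[, 1]), X[, 2] * 0.1)
  fit <- mlp_fit(X, Y, hidden = 8, epochs = 50, learning_rate = 0.05, seed = 5)
  # constant inputs give constant outputs
  p <- predict(fit, matrix(5, 4, 3))
  expect_equal(max(apply(p, 2, stats::sd)), 0)
  # inputs 10% beyond the training range stay finite
  expect_true(all(is.finite(predict(fit, matrix(11, 4, 3)))))
  # clipping flag
  expect_true(all(predict(fit, matrix(-50, 4, 3), clip = TRUE) >= 0))
})

test_that("model methods print, summarize and plot without error", {
  set.seed(14)
  X <- matrix(stats::rnorm(90), 30)
  fit <- mlp_fit(X, X[, 1, drop = FALSE], hidden = c(4, 3), epochs = 20,
                 learning_rate = 0.05)
  expect_output(print(fit), "Time-delay MLP")
  expect_output(print(summary(fit)), "hidden neurons")
  expect_length(residuals(fit, structure(list(X = X, Y = X[, 1, drop = FALSE]),
                                         class = "delay_design")), 30)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
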