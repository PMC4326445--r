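# From-scratch multilayer perceptron regression: tanh hidden layers, linear
# outputs, full-batch gradient descent with momentum on mean squared error.
# This is the modelling core of the package; everything else feeds it.

#' Initialize a multilayer perceptron
#'
#' Weights and biases are drawn Uniform(-1/sqrt(fan_in), +1/sqrt(fan_in)),
#' deterministically per seed.
#'
#' @param n_inputs number of input columns.
#' @param hidden integer vector of hidden layer sizes, e.g. `30` or
#'   `c(20, 9, 9, 20)`.
#' @param n_outputs number of output channels.
#' @param seed RNG seed.
#' @return an `mlp_net`: lists `W` (out x in matrices) and `b` per layer.
#' @export
mlp_init <- function(n_inputs, hidden, n_outputs, seed = 1) {
  if (any(hidden < 1) || any(hidden != round(hidden)))
    stop_invalid("hidden layer sizes must be positive integers")
  sizes <- c(n_inputs, hidden, n_outputs)
  with_seed(seed, {
    W <- vector("list", length(sizes) - 1)
    b <- vector("list", length(sizes) - 1)
    for (l in seq_along(W)) {
      fan_in <- sizes[l]
      lim <- 1 / sqrt(fan_in)
      W[[l]] <- matrix(stats::runif(sizes[l + 1] * fan_in, -lim, lim),
                       sizes[l + 1], fan_in)
      b[[l]] <- stats::runif(sizes[l + 1], -lim, lim)
    }
    structure(list(W = W, b = b, sizes = sizes, seed = seed), class = "mlp_net")
  })
}

n_parameters <- function(net) {
  sum(vapply(net$W, length, 0L)) + sum(vapply(net$b, length, 0L))
}

#' Forward pass
#'
#' Hidden layers apply tanh; the output layer is linear.
#'
#' @param net an `mlp_net`.
#' @param X N x n_inputs matrix.
#' @param keep_hidden return per-layer activations (for backpropagation).
#' @return N x n_outputs prediction matrix (or a list with `A` when
#'   `keep_hidden`).
#' @export
mlp_forward <- function(net, X, keep_hidden = FALSE) {
  if (ncol(X) != net$sizes[1])
    stop_invalid("input has %d columns; network expects %d", ncol(X), net$sizes[1])
  L <- length(net$W)
  A <- vector("list", L + 1)
  A[[1]] <- X
  for (l in seq_len(L - 1))
    A[[l + 1]] <- tanh(sweep(A[[l]] %*% t(net$W[[l]]), 2, net$b[[l]], "+"))
  A[[L + 1]] <- sweep(A[[L]] %*% t(net$W[[L]]), 2, net$b[[L]], "+")
  if (keep_hidden) list(Yhat = A[[L + 1]], A = A) else A[[L + 1]]
}

#' Analytic gradients of the mean-squared error
#'
#' Exact backpropagated gradient of `mean((Y - Yhat)^2)` (the mean running
#' over all N x q entries) with respect to every weight and bias.
#'
#' @param net an `mlp_net`.
#' @param X inputs, N x n_inputs.
#' @param Y targets, N x n_outputs.
#' @return list with `gW`, `gb` (shapes matching the net) and `mse`.
#' @export
mlp_gradients <- function(net, X, Y) {
  fw <- mlp_forward(net, X, keep_hidden = TRUE)
  A <- fw$A
  L <- length(net$W)
  N <- nrow(X); q <- ncol(Y)
  err <- fw$Yhat - Y
  mse <- mean(err^2)
  delta <- 2 * err / (N * q)
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in L:1) {
    gW[[l]] <- crossprod(delta, A[[l]])
    gb[[l]] <- colSums(delta)
    if (l > 1) delta <- (delta %*% net$W[[l]]) * (1 - A[[l]]^2)
  }
  list(gW = gW, gb = gb, mse = mse)
}

#' Fit a time-delay multilayer perceptron
#'
#' The package's central fitting function: full-batch gradient descent with
#' momentum (update v <- momentum * v - lr * grad; theta <- theta + v) on
#' the mean squared error, for exactly `epochs` epochs — no early stopping,
#' no validation split, no regularization, matching the training protocol it
#' reimplements.  Inputs are affinely scaled to [-1, 1] using extremes of
#' the training data (the scaler is stored and re-applied by
#' [predict.tdmlp()]); targets are used as given (MVC-normalized envelopes
#' already live near [0, 1]).
#'
#' @param X training inputs: an N x p matrix or a `delay_design`.
#' @param Y training targets, N x q (taken from the design if omitted).
#' @param hidden hidden layer sizes; `30` is the best-performing single
#'   hidden layer, `c(20, 9, 9, 20)` the four-hidden-layer variant.
#' @param epochs full-batch epochs (protocol default 100).
#' @param learning_rate gradient step size.
#' @param momentum momentum coefficient in [0, 1).
#' @param seed initialization seed.
#' @param scale_inputs fit and apply the [-1, 1] input scaler (disable only
#'   if `X` is already scaled).
#' @param trace_every record training MSE every so many epochs (1 = all).
#' @return a `tdmlp` object with `print`, `summary`, `coef`, `predict`,
#'   `fitted`, `residuals` and `plot` methods.
#' @examples
#' set.seed(1)
#' X <- matrix(runif(600, -1, 1), 200, 3)
#' Y <- cbind(tanh(X %*% c(1, -2, 0.5)), X %*% c(0.3, 0, -0.1))
#' fit <- mlp_fit(X, Y, hidden = 5, epochs = 200, learning_rate = 0.05)
#' fit
#' @export
mlp_fit <- function(X, Y = NULL, hidden = 30, epochs = 100,
                    learning_rate = 0.01, momentum = 0.9, seed = 1,
                    scale_inputs = TRUE, trace_every = 1) {
  if (inherits(X, "delay_design")) {
    if (is.null(Y)) Y <- X$Y
    X <- X$X
  }
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop_invalid("X and Y row counts differ")
  check_scalar(epochs, "epochs", positive = TRUE)
  check_scalar(learning_rate, "learning_rate", nonnegative = TRUE)
  if (momentum < 0 || momentum >= 1) stop_invalid("momentum must be in [0, 1)")

  scaler <- if (scale_inputs) fit_scaler(X) else NULL
  Xs <- if (scale_inputs) apply_scaler(scaler, X) else X
  net <- mlp_init(ncol(Xs), hidden, ncol(Y), seed = seed)

  vW <- lapply(net$W, function(w) w * 0)
  vb <- lapply(net$b, function(b) b * 0)
  trace <- numeric(0)
  for (e in seq_len(epochs)) {
    g <- mlp_gradients(net, Xs, Y)
    if (!is.finite(g$mse))
      stop_invalid(paste0("training diverged at epoch %d (MSE is not finite); ",
                          "reduce the learning rate"), e)
    for (l in seq_along(net$W)) {
      vW[[l]] <- momentum * vW[[l]] - learning_rate * g$gW[[l]]
      vb[[l]] <- momentum * vb[[l]] - learning_rate * g$gb[[l]]
      net$W[[l]] <- net$W[[l]] + vW[[l]]
      net$b[[l]] <- net$b[[l]] + vb[[l]]
    }
    if (e %% trace_every == 0 || e == epochs) trace[length(trace) + 1] <- g$mse
  }
  final_mse <- mean((mlp_forward(net, Xs) - Y)^2)
  structure(list(
    net = net, scaler = scaler, hidden = hidden,
    epochs = epochs, learning_rate = learning_rate, momentum = momentum,
    seed = seed, trace = trace, final_mse = final_mse,
    n_inputs = ncol(Xs), n_outputs = ncol(Y),
    target_names = colnames(Y)
  ), class = "tdmlp")
}

#' Predict EMG envelopes from a fitted time-delay MLP
#'
#' Applies the stored input scaler, then the forward pass.  Predictions are
#' on the MVC-normalized scale and are not clipped by default (scores are
#' computed on the raw network output); `clip = TRUE` clips at zero for
#' downstream use as stimulation templates.
#'
#' @param object a `tdmlp`.
#' @param newdata matrix of unscaled inputs or a `delay_design`.
#' @param clip clip negative predictions to zero.
#' @param ... unused.
#' @return N x q prediction matrix.
#' @export
predict.tdmlp <- function(object, newdata, clip = FALSE, ...) {
  if (inherits(newdata, "delay_design")) newdata <- newdata$X
  newdata <- as.matrix(newdata)
  Xs <- if (!is.null(object$scaler)) apply_scaler(object$scaler, newdata) else newdata
  Yhat <- mlp_forward(object$net, Xs)
  colnames(Yhat) <- object$target_names
  if (clip) Yhat <- pmax(Yhat, 0)
  Yhat
}

#' @export
print.tdmlp <- function(x, ...) {
  cat(sprintf("Time-delay MLP: %s\n",
              paste(x$net$sizes, collapse = " - ")))
  cat(sprintf("  %d parameters; tanh hidden units, linear outputs\n",
              n_parameters(x$net)))
  cat(sprintf("  trained %d full-batch epochs (lr %g, momentum %g); final train MSE %.4g\n",
              x$epochs, x$learning_rate, x$momentum, x$final_mse))
  invisible(x)
}

#' @export
summary.tdmlp <- function(object, ...) {
  s <- list(sizes = object$net$sizes, n_parameters = n_parameters(object$net),
            hidden_neurons = sum(object$hidden),
            epochs = object$epochs, learning_rate = object$learning_rate,
            momentum = object$momentum, final_mse = object$final_mse,
            initial_mse = object$trace[1], scaled = !is.null(object$scaler))
  class(s) <- "summary.tdmlp"
  s
}

#' @export
print.summary.tdmlp <- function(x, ...) {
  cat(sprintf("Time-delay MLP %s (%d hidden neurons, %d parameters)\n",
              paste(x$sizes, collapse = "-"), x$hidden_neurons, x$n_parameters))
  cat(sprintf("Training: %d epochs, lr %g, momentum %g\n",
              x$epochs, x$learning_rate, x$momentum))
  cat(sprintf("MSE: %.4g -> %.4g%s\n", x$initial_mse, x$final_mse,
              if (x$scaled) " (inputs scaled to [-1, 1])" else ""))
  invisible(x)
}

#' @export
coef.tdmlp <- function(object, ...) {
  list(W = object$net$W, b = object$net$b)
}

#' @export
fitted.tdmlp <- function(object, X, ...) predict(object, X)

#' Residuals of a fitted time-delay MLP on a design
#' @param object a `tdmlp`.
#' @param design a `delay_design` with targets.
#' @param ... unused.
#' @export
residuals.tdmlp <- function(object, design, ...) {
  design$Y - predict(object, design)
}

#' Plot the training MSE trace
#' @param x a `tdmlp`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.tdmlp <- function(x, ...) {
  graphics::plot(seq_along(x$trace), x$trace, type = "l", log = "y",
                 xlab = "epoch", ylab = "training MSE",
                 main = sprintf("MLP %s", paste(x$hidden, collapse = "-")), ...)
  invisible(x)
}
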