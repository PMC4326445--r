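# Delay embedding, temporal train/test split, and input scaling: turning a
# processed session into the supervised regression problem.

#' Delay-embed features against targets
#'
#' Row i of the design matrix concatenates the feature vector at time t_i
#' with its copies from the `n_delays` preceding samples (the tapped delay
#' line that lets a static network express temporal dependence); the first
#' `n_delays` samples are dropped.
#'
#' @param features T x p feature matrix (rows = time) or the p x T matrix of
#'   an `emg_dataset` (auto-transposed when column names look like times).
#' @param targets T x q target matrix.
#' @param times length-T timestamps, seconds.
#' @param n_delays number of delayed copies (default 2).
#' @return a `delay_design` list: `X` ((T - n_delays) x p(n_delays+1)),
#'   `Y`, `times`, `feature_names`, `n_delays`.
#' @export
embed_delays <- function(features, targets, times = NULL, n_delays = 2) {
  features <- as.matrix(features); targets <- as.matrix(targets)
  T_n <- nrow(features)
  if (nrow(targets) != T_n) stop_invalid("features and targets are not aligned")
  if (T_n <= n_delays) stop_invalid("need more than n_delays = %d samples", n_delays)
  if (is.null(times)) times <- seq_len(T_n)
  p <- ncol(features)
  fn <- colnames(features); if (is.null(fn)) fn <- paste0("f", seq_len(p))
  idx <- (n_delays + 1):T_n
  X <- do.call(cbind, lapply(0:n_delays, function(d) features[idx - d, , drop = FALSE]))
  colnames(X) <- unlist(lapply(0:n_delays, function(d) paste0(fn, "_t", -d)))
  structure(list(X = X, Y = targets[idx, , drop = FALSE], times = times[idx],
                 feature_names = fn, n_delays = n_delays),
            class = "delay_design")
}

#' Build the delay design of a processed session
#'
#' @param dataset an `emg_dataset` from [preprocess_session()].
#' @param include_force include the grip-force feature (the loaded-movement
#'   input set: 7 features x 3 time steps = 21 inputs).  With `FALSE` the
#'   unloaded input set (18 inputs) is built.
#' @param n_delays number of delayed copies.
#' @return a `delay_design`.
#' @export
session_design <- function(dataset, include_force = TRUE, n_delays = 2) {
  feats <- dataset$features
  if (!include_force) feats <- feats[rownames(feats) != "force", , drop = FALSE]
  embed_delays(t(feats), t(dataset$targets), dataset$times, n_delays)
}

#' Split a delay design into contiguous train and test partitions
#'
#' The first `train_duration_s` seconds train; the remainder tests.  The
#' embedding rows whose delay window straddles the boundary are assigned to
#' neither partition, so no information leaks across the split.
#'
#' @param design a `delay_design`.
#' @param train_duration_s training duration in seconds (default 1000, the
#'   protocol's split).
#' @return list with `train` and `test` delay designs.
#' @export
split_train_test <- function(design, train_duration_s = 1000) {
  if (train_duration_s <= 0) stop_invalid("train duration must be positive")
  dt <- stats::median(diff(design$times))
  t0 <- design$times[1] - design$n_delays * dt  # session start, pre-embedding
  boundary <- t0 + train_duration_s
  if (boundary >= design$times[length(design$times)])
    stop_invalid("session (%.0f s) too short for a %.0f s training split",
                 design$times[length(design$times)] - t0, train_duration_s)
  tr <- design$times < boundary
  te <- design$times >= boundary + design$n_delays * dt
  take <- function(keep) {
    structure(list(X = design$X[keep, , drop = FALSE],
                   Y = design$Y[keep, , drop = FALSE],
                   times = design$times[keep],
                   feature_names = design$feature_names,
                   n_delays = design$n_delays), class = "delay_design")
  }
  list(train = take(tr), test = take(te))
}

#' Fit a [-1, 1] input scaler on a training design
#'
#' Column-wise affine map of the training extremes onto [-1, 1]; columns
#' with (near-)zero range are flagged constant and merely centered.  Test
#' data mapped with the same transform may exceed [-1, 1].
#'
#' @param X training input matrix (or a `delay_design`).
#' @return an `input_scaler`.
#' @export
fit_scaler <- function(X) {
  if (inherits(X, "delay_design")) X <- X$X
  if (!nrow(X)) stop_invalid("cannot fit a scaler on an empty matrix")
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  constant <- (hi - lo) < 1e-12
  structure(list(min = lo, max = hi, constant = constant,
                 n_cols = ncol(X), col_names = colnames(X)),
            class = "input_scaler")
}

#' Apply (or invert) an input scaler
#' @param scaler an `input_scaler`.
#' @param X matrix with the scaler's columns.
#' @export
apply_scaler <- function(scaler, X) {
  if (inherits(X, "delay_design")) X <- X$X
  if (ncol(X) != scaler$n_cols)
    stop_invalid("scaler expects %d columns, got %d", scaler$n_cols, ncol(X))
  rng <- scaler$max - scaler$min
  out <- X
  for (j in seq_len(ncol(X))) {
    out[, j] <- if (scaler$constant[j]) X[, j] - scaler$min[j]
                else 2 * (X[, j] - scaler$min[j]) / rng[j] - 1
  }
  out
}

#' @rdname apply_scaler
#' @export
invert_scaler <- function(scaler, X) {
  rng <- scaler$max - scaler$min
  out <- X
  for (j in seq_len(ncol(X))) {
    out[, j] <- if (scaler$constant[j]) X[, j] + scaler$min[j]
                else (X[, j] + 1) / 2 * rng[j] + scaler$min[j]
  }
  out
}
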