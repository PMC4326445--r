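# Scoring and the two experiment designs: the loaded/unloaded cross-training
# condition matrix and the network-capacity grid.

#' Coefficient of determination based on the correlation
#'
#' The squared Pearson correlation between actual and predicted series —
#' the scoring rule of the protocol this package reimplements.  Note the
#' consequences: the value is invariant to affine rescaling (and to sign
#' flips) of the predictions, and it ignores prediction bias.  The
#' complementary `1 - SS_res/SS_tot` definition is available via `method`;
#' the two diverge when predictions are biased.
#'
#' @param actual,predicted numeric vectors of equal length >= 3.
#' @param method `"correlation"` (default) or `"variance_explained"`.
#' @return a scalar; in [0, 1] for `"correlation"`.
#' @export
r_squared <- function(actual, predicted, method = c("correlation", "variance_explained")) {
  method <- match.arg(method)
  if (length(actual) != length(predicted)) stop_invalid("series lengths differ")
  if (length(actual) < 3) stop_invalid("need at least 3 samples")
  if (stats::sd(actual) == 0)
    stop_invalid("actual series has zero variance; R^2 is undefined")
  if (method == "variance_explained")
    return(1 - sum((actual - predicted)^2) / sum((actual - mean(actual))^2))
  if (stats::sd(predicted) == 0) {
    warning("predicted series has zero variance; returning R^2 = 0")
    return(0)
  }
  stats::cor(actual, predicted)^2
}

#' Score a fitted model on a test design, per muscle
#'
#' @param model a `tdmlp`.
#' @param design a `delay_design` holding the test inputs and actual
#'   envelopes.
#' @param verbose also compute the variance-explained definition.
#' @return a `prediction_result`: named per-muscle `r2`, `mean`, `sd`.
#' @export
evaluate_model <- function(model, design, verbose = FALSE) {
  Yhat <- predict(model, design)
  nm <- colnames(design$Y)
  if (is.null(nm)) nm <- paste0("ch", seq_len(ncol(design$Y)))
  r2 <- vapply(seq_len(ncol(design$Y)), function(j)
    r_squared(design$Y[, j], Yhat[, j]), 0)
  names(r2) <- nm
  out <- list(r2 = r2, mean = mean(r2), sd = stats::sd(r2),
              n_test = nrow(design$Y))
  if (verbose)
    out$r2_variance_explained <- vapply(seq_len(ncol(design$Y)), function(j)
      r_squared(design$Y[, j], Yhat[, j], method = "variance_explained"), 0)
  structure(out, class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("Per-muscle R^2 (n = %d test samples): mean %.3f +/- %.3f\n",
              x$n_test, x$mean, x$sd))
  print(round(x$r2, 3))
  invisible(x)
}

#' Estimate the per-muscle noise ceiling of a session configuration
#'
#' The maximum R^2 any predictor can reach against the processed envelopes
#' is limited by activation noise, carrier demodulation noise and sensor
#' noise.  It is estimated by brute force: sessions sharing trajectory,
#' schedule and plant but with independent noise realizations are processed,
#' and the correlation between the envelope pairs of the same muscle is the
#' ceiling (for envelopes e_i = m + d_i with independent d_i,
#' cor(e_1, e_2) = var(m) / (var(m) + var(d)), exactly the best achievable
#' squared correlation with the common signal m).
#'
#' @param config a [session_config()].
#' @param n_pairs number of independent realization pairs to average.
#' @return named per-muscle ceiling vector (values in [0, 1]).
#' @export
estimate_noise_ceiling <- function(config, n_pairs = 2) {
  plant <- teacher_plant(config)
  ceil <- matrix(0, n_pairs, 12)
  for (i in seq_len(n_pairs)) {
    s1 <- simulate_session(config, plant = plant, realization = 2L * i)
    s2 <- simulate_session(config, plant = plant, realization = 2L * i + 1L)
    e1 <- preprocess_session(s1)$targets
    e2 <- preprocess_session(s2)$targets
    ceil[i, ] <- vapply(1:12, function(m) stats::cor(e1[m, ], e2[m, ]), 0)
  }
  out <- colMeans(ceil)
  names(out) <- MUSCLES
  pmin(pmax(out, 0), 1)
}

train_and_score <- function(train_design, test_design, hidden, epochs,
                            learning_rate, momentum, seed) {
  fit <- mlp_fit(train_design, hidden = hidden, epochs = epochs,
                 learning_rate = learning_rate, momentum = momentum, seed = seed)
  list(fit = fit, result = evaluate_model(fit, test_design))
}

#' Loaded/unloaded cross-training condition matrix
#'
#' For each replicate seed, one unloaded and one loaded session are
#' generated (sharing the teacher plant, i.e. the same "subject"),
#' processed, and split.  A network is trained on each session's training
#' partition — kinematics only for the unloaded session, kinematics + grip
#' force for the loaded one — and evaluated on both test partitions, giving
#' the four train/test combinations.  When a network trained without force
#' predicts loaded movements it has no access to the load, which is the
#' degradation the experiment quantifies.
#'
#' @param config a loaded [session_config()] (the unloaded twin is derived
#'   by dropping the masses).
#' @param hidden hidden layer sizes for every cell's network.
#' @param epochs,learning_rate,momentum training protocol.
#' @param train_duration_s temporal split point, seconds.
#' @param n_seeds replicate count (each replicate re-draws trajectory,
#'   noise and initialization).
#' @return a `condition_matrix` report: per-cell mean +/- SD of R^2 across
#'   muscles and replicates, plus per-seed cell means.
#' @export
run_condition_matrix <- function(config, hidden = 30, epochs = 100,
                                 learning_rate = 0.01, momentum = 0.9,
                                 train_duration_s = NULL, n_seeds = 5) {
  if (is.null(train_duration_s))
    train_duration_s <- default_split_s(config$duration_s)
  cells <- c("unloaded->unloaded", "loaded->loaded",
             "unloaded->loaded", "loaded->unloaded")
  per_seed <- matrix(NA_real_, n_seeds, 4, dimnames = list(NULL, cells))
  per_muscle <- array(NA_real_, c(n_seeds, 4, 12),
                      dimnames = list(NULL, cells, MUSCLES))
  for (s in seq_len(n_seeds)) {
    seed_s <- substream_seed(config$seed, "replicate", s)
    cfg_l <- config; cfg_l$seed <- seed_s
    cfg_u <- cfg_l
    cfg_u$load_masses_g <- numeric(0)
    cfg_u$seed <- substream_seed(seed_s, "unloaded_session")  # distinct movements
    plant <- teacher_plant(cfg_l)  # shared plant: same "subject", two sessions
    ses_l <- simulate_session(cfg_l, plant = plant)
    ses_u <- simulate_session(cfg_u, plant = plant)
    ds_l <- preprocess_session(ses_l)
    ds_u <- preprocess_session(ses_u)
    # unloaded-trained networks use kinematics only (no force channel was
    # informative); loaded-trained networks use kinematics + force
    sp_l_kin <- split_train_test(session_design(ds_l, include_force = FALSE),
                                 train_duration_s)
    sp_l_all <- split_train_test(session_design(ds_l, include_force = TRUE),
                                 train_duration_s)
    sp_u <- split_train_test(session_design(ds_u, include_force = FALSE),
                             train_duration_s)
    init_seed <- substream_seed(seed_s, "init")
    fit_u <- mlp_fit(sp_u$train, hidden = hidden, epochs = epochs,
                     learning_rate = learning_rate, momentum = momentum,
                     seed = init_seed)
    fit_l <- mlp_fit(sp_l_all$train, hidden = hidden, epochs = epochs,
                     learning_rate = learning_rate, momentum = momentum,
                     seed = init_seed)
    # loaded-trained network scored on unloaded movements: force inputs are
    # rebuilt from the unloaded session (a near-zero trace), as in protocol
    sp_u_all <- split_train_test(session_design(ds_u, include_force = TRUE),
                                 train_duration_s)
    res <- list(
      evaluate_model(fit_u, sp_u$test),
      evaluate_model(fit_l, sp_l_all$test),
      evaluate_model(fit_u, sp_l_kin$test),
      evaluate_model(fit_l, sp_u_all$test)
    )
    per_seed[s, ] <- vapply(res, function(r) r$mean, 0)
    for (k in 1:4) per_muscle[s, k, ] <- res[[k]]$r2
  }
  pooled <- apply(per_muscle, 2, identity)  # (seeds*muscles) x 4
  structure(list(
    mean = colMeans(pooled), sd = apply(pooled, 2, stats::sd),
    per_seed = per_seed, per_muscle = per_muscle,
    n_seeds = n_seeds, hidden = hidden, epochs = epochs,
    force_dependent = config$force_dependent
  ), class = "condition_matrix")
}

#' @export
print.condition_matrix <- function(x, ...) {
  cat(sprintf("Condition matrix (%d replicates, MLP %s, %d epochs)\n",
              x$n_seeds, paste(x$hidden, collapse = "-"), x$epochs))
  tab <- data.frame(mean_R2 = round(x$mean, 3), sd_R2 = round(x$sd, 3))
  print(tab)
  invisible(x)
}

#' Network-capacity comparison grid
#'
#' Trains every requested architecture on the loaded-movement training
#' partition for each replicate seed and scores it on the loaded test
#' partition, reporting mean +/- SD of R^2 across muscles and replicates,
#' sorted by total hidden-neuron count.
#'
#' @param config a loaded [session_config()].
#' @param architectures list of hidden-layer-size vectors, e.g.
#'   `list(1, 2, 5, 10, 30, c(20, 9, 9, 20))`.
#' @inheritParams run_condition_matrix
#' @return an `architecture_grid` report.
#' @export
run_architecture_grid <- function(config, architectures = list(1, 2, 5, 10, 30, c(20, 9, 9, 20)),
                                  epochs = 100, learning_rate = 0.01,
                                  momentum = 0.9, train_duration_s = NULL,
                                  n_seeds = 5) {
  if (is.null(train_duration_s))
    train_duration_s <- default_split_s(config$duration_s)
  labels <- vapply(architectures, function(h) paste0("MLP", paste(h, collapse = "_")), "")
  neurons <- vapply(architectures, sum, 0)
  per <- matrix(NA_real_, n_seeds, length(architectures),
                dimnames = list(NULL, labels))
  per_pool <- vector("list", length(architectures))
  for (s in seq_len(n_seeds)) {
    seed_s <- substream_seed(config$seed, "replicate", s)
    cfg <- config; cfg$seed <- seed_s
    ds <- preprocess_session(simulate_session(cfg))
    sp <- split_train_test(session_design(ds, include_force = TRUE), train_duration_s)
    for (a in seq_along(architectures)) {
      fit <- mlp_fit(sp$train, hidden = architectures[[a]], epochs = epochs,
                     learning_rate = learning_rate, momentum = momentum,
                     seed = substream_seed(seed_s, "init", a))
      r <- evaluate_model(fit, sp$test)
      per[s, a] <- r$mean
      per_pool[[a]] <- c(per_pool[[a]], r$r2)
    }
  }
  ord <- order(neurons)
  structure(list(
    label = labels[ord], neurons = neurons[ord],
    mean = vapply(per_pool, mean, 0)[ord],
    sd = vapply(per_pool, stats::sd, 0)[ord],
    per_seed = per[, ord, drop = FALSE],
    n_seeds = n_seeds, epochs = epochs
  ), class = "architecture_grid")
}

#' @export
print.architecture_grid <- function(x, ...) {
  cat(sprintf("Architecture grid (%d replicates, %d epochs)\n", x$n_seeds, x$epochs))
  print(data.frame(network = x$label, hidden_neurons = x$neurons,
                   mean_R2 = round(x$mean, 3), sd_R2 = round(x$sd, 3)))
  invisible(x)
}

#' Across-session transfer
#'
#' Trains on session A's training partition (scaler included) and scores on
#' session B's test partition — the synthetic analogue of training on one
#' subject and predicting another.
#'
#' @param session_a,session_b `emg_session` objects sharing feature
#'   conventions.
#' @inheritParams run_condition_matrix
#' @param include_force use the grip-force input.
#' @return a `prediction_result`.
#' @export
across_session_transfer <- function(session_a, session_b, hidden = 30,
                                    epochs = 100, learning_rate = 0.01,
                                    momentum = 0.9, train_duration_s = NULL,
                                    include_force = TRUE) {
  if (is.null(train_duration_s))
    train_duration_s <- default_split_s(session_a$config$duration_s)
  ds_a <- preprocess_session(session_a)
  ds_b <- preprocess_session(session_b)
  sp_a <- split_train_test(session_design(ds_a, include_force), train_duration_s)
  sp_b <- split_train_test(session_design(ds_b, include_force), train_duration_s)
  fit <- mlp_fit(sp_a$train, hidden = hidden, epochs = epochs,
                 learning_rate = learning_rate, momentum = momentum,
                 seed = substream_seed(session_a$config$seed, "init"))
  evaluate_model(fit, sp_b$test)
}

# protocol split: 1000 s of a full-length session; two thirds of a shorter one
default_split_s <- function(duration_s) {
  if (duration_s > 1500) 1000 else round(duration_s * 2 / 3)
}
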