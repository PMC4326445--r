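# Small fixtures shared across test files.  Sessions are generated once per
# test run and cached, since several files probe the same objects.

tiny_config <- function(seed = 7, duration_s = 60, ...) {
  reduced_profile(duration_s = duration_s, epoch_s = 15, seed = seed, ...)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

tiny_session <- function() cached("tiny_session", simulate_session(tiny_config()))
tiny_dataset <- function() cached("tiny_dataset", preprocess_session(tiny_session()))

# teacher-student problem on exact plant inputs (no signal chain): the
# setting where the mapping is representable without error by the student
teacher_problem <- function(seed, duration_s = 240, kin_rate_hz = 60,
                            epoch_s = 10) {
  cfg <- reduced_profile(duration_s = duration_s, seed = seed,
                         noise = list(activation = 0), epoch_s = epoch_s,
                         kin_rate_hz = kin_rate_hz)
  traj <- generate_trajectory(cfg)
  sched <- generate_load_schedule(cfg)
  force <- generate_grip_force(sched, traj, cfg)
  plant <- teacher_plant(cfg)
  act <- teacher_activation(traj$hand, traj$shoulder, force$kin, plant)
  feats <- rbind((traj$hand[1:3, ] - traj$shoulder) / cfg$workspace_m,
                 traj$hand[4:6, ] / 180, force = force$kin / 10)
  design <- embed_delays(t(feats), t(act), n_delays = 2)
  nr <- nrow(design$X)
  cut <- round(nr * 2 / 3)
  take <- function(i) structure(
    list(X = design$X[i, , drop = FALSE], Y = design$Y[i, , drop = FALSE],
         times = design$times[i], feature_names = design$feature_names,
         n_delays = 2), class = "delay_design")
  list(train = take(seq_len(cut)), test = take((cut + 3):nr), plant = plant)
}

# finite-difference gradient of the training MSE, the independent oracle for
# backpropagation; h chosen per call
fd_gradient <- function(net, X, Y, h = 1e-6) {
  loss <- function(n) mean((mlp_forward(n, X) - Y)^2)
  gW <- lapply(net$W, function(w) w * 0)
  gb <- lapply(net$b, function(b) b * 0)
  for (l in seq_along(net$W)) {
    for (k in seq_along(net$W[[l]])) {
      np <- net; np$W[[l]][k] <- np$W[[l]][k] + h
      nm <- net; nm$W[[l]][k] <- nm$W[[l]][k] - h
      gW[[l]][k] <- (loss(np) - loss(nm)) / (2 * h)
    }
    for (k in seq_along(net$b[[l]])) {
      np <- net; np$b[[l]][k] <- np$b[[l]][k] + h
      nm <- net; nm$b[[l]][k] <- nm$b[[l]][k] - h
      gb[[l]][k] <- (loss(np) - loss(nm)) / (2 * h)
    }
  }
  list(gW = gW, gb = gb)
}

# max deviation between analytic and finite-difference gradients, relative
# to the gradient's largest magnitude (entrywise relative error at h = 1e-6
# is dominated by cancellation noise ~1e-10 wherever the true entry
# vanishes, so the scale-relative form is the numerically meaningful one)
gradient_rel_err <- function(hidden, n = 30, p = 7, q = 4, seed = 1, h = 1e-6) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * p), n)
  Y <- matrix(stats::rnorm(n * q), n)
  net <- mlp_init(p, hidden, q, seed = seed)
  an <- mlp_gradients(net, X, Y)
  fd <- fd_gradient(net, X, Y, h = h)
  num <- max(mapply(function(a, b) max(abs(a - b)), an$gW, fd$gW),
             mapply(function(a, b) max(abs(a - b)), an$gb, fd$gb))
  den <- max(mapply(function(a) max(abs(a)), fd$gW),
             mapply(function(a) max(abs(a)), fd$gb))
  num / den
}
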