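# Experiment orchestration: a declarative config drives the whole pipeline
# (simulate -> preprocess -> dataset -> train -> report) into a
# deterministic directory tree.

#' Default experiment configuration
#'
#' @param profile `"reduced"` (6-minute sessions at raw 1000 Hz — the
#'   development and testing scale) or `"paper"` (full-length sessions at
#'   2500 Hz, the replication preset).
#' @return an `experiment_config` list, serializable to JSON losslessly.
#' @export
default_experiment_config <- function(profile = c("reduced", "paper")) {
  profile <- match.arg(profile)
  if (profile == "reduced") {
    session <- list(duration_s = 360, raw_rate_hz = 1000, kin_rate_hz = 120,
                    load_masses_g = c(100, 200, 500, 1000), epoch_s = 30,
                    carrier_band_hz = c(100, 400), seed = 1)
    train <- list(epochs = 60, learning_rate = 0.02, momentum = 0.9)
    split <- list(train_duration_s = 240)
    n_seeds <- 1
  } else {
    session <- list(duration_s = 1920, raw_rate_hz = 2500, kin_rate_hz = 120,
                    load_masses_g = c(100, 200, 500, 1000), epoch_s = 120,
                    carrier_band_hz = c(100, 475), seed = 1)
    train <- list(epochs = 100, learning_rate = 0.01, momentum = 0.9)
    split <- list(train_duration_s = 1000)
    n_seeds <- 5
  }
  structure(list(profile = profile, session = session, train = train,
                 split = split, architectures = list(1, 30),
                 condition_matrix = TRUE, n_seeds = n_seeds),
            class = "experiment_config")
}

#' Validate an experiment configuration
#'
#' @param config an `experiment_config` list, or the path of a JSON file
#'   holding one.
#' @return character vector of problems; empty when the config is valid.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_invalid("config file '%s' not found", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
    if (is.data.frame(config$architectures))
      config$architectures <- as.list(config$architectures)
  }
  problems <- character(0)
  need <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)
  s <- config$session
  need(is.list(s), "session: missing section")
  if (is.list(s)) {
    need(is.numeric(s$duration_s) && s$duration_s > 0,
         "session.duration_s: must be > 0")
    need(is.numeric(s$raw_rate_hz) && s$raw_rate_hz > 0,
         "session.raw_rate_hz: must be > 0")
    if (!is.null(s$carrier_band_hz) && is.numeric(s$raw_rate_hz))
      need(max(s$carrier_band_hz) < s$raw_rate_hz / 2,
           "session.carrier_band_hz: must lie below the raw Nyquist frequency")
    if (!is.null(s$load_masses_g))
      need(all(s$load_masses_g >= 0), "session.load_masses_g: masses must be >= 0")
  }
  tr <- config$train
  need(is.list(tr), "train: missing section")
  if (is.list(tr)) {
    need(is.numeric(tr$learning_rate) && tr$learning_rate > 0,
         "train.learning_rate: must be > 0")
    need(is.numeric(tr$epochs) && tr$epochs >= 1, "train.epochs: must be >= 1")
    need(is.numeric(tr$momentum) && tr$momentum >= 0 && tr$momentum < 1,
         "train.momentum: must be in [0, 1)")
  }
  need(length(config$architectures) >= 1, "architectures: list must be nonempty")
  for (a in config$architectures) {
    ok <- is.numeric(unlist(a)) && all(unlist(a) >= 1) &&
      all(unlist(a) == round(unlist(a)))
    need(ok, sprintf("architectures: invalid token '%s'",
                     paste(unlist(a), collapse = ",")))
  }
  if (is.list(config$split) && is.list(s) && is.numeric(s$duration_s))
    need(is.numeric(config$split$train_duration_s) &&
           config$split$train_duration_s > 0 &&
           config$split$train_duration_s < s$duration_s,
         "split.train_duration_s: must be in (0, session.duration_s)")
  problems
}

config_to_session <- function(config) {
  s <- config$session
  do.call(session_config, s[names(s) %in% names(formals(session_config))])
}

#' Run a full experiment from a configuration
#'
#' Stages: simulate the loaded (and, for the condition matrix, unloaded)
#' sessions; preprocess; build delay datasets; train the configured
#' architectures; write JSON reports.  The output tree
#' (`sessions/`, `reports/`, `provenance.json`, `log.txt`) is a pure
#' function of the config, so identical configs give identical reports.
#'
#' @param config an `experiment_config` (or JSON path).
#' @param out_dir output directory root.
#' @param dry_run print the stage plan and write nothing.
#' @param write_sessions also persist the simulated sessions as text (off by
#'   default; they are large and reproducible from the config).
#' @return list with the reports (invisibly unless `dry_run`).
#' @export
run_experiment <- function(config, out_dir, dry_run = FALSE, write_sessions = FALSE) {
  if (is.character(config)) {
    problems <- validate_config(config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
    if (is.data.frame(config$architectures))
      config$architectures <- as.list(config$architectures)
  } else problems <- validate_config(config)
  if (length(problems))
    stop_invalid("invalid experiment config:\n  %s", paste(problems, collapse = "\n  "))

  stages <- c("simulate", "preprocess", "make-dataset",
              if (isTRUE(config$condition_matrix)) "condition-matrix",
              "arch-grid", "report")
  if (dry_run) {
    cat("stage plan:", paste(stages, collapse = " -> "), "\n")
    return(invisible(stages))
  }
  dir.create(file.path(out_dir, "reports"), recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "log.txt")
  log_line <- function(...) cat(sprintf(...), "\n", file = logf, append = TRUE)
  cat("", file = logf)

  scfg <- config_to_session(config)
  t0 <- proc.time()["elapsed"]
  stage <- function(name, expr) {
    s0 <- proc.time()["elapsed"]
    out <- tryCatch(expr, error = function(e)
      stop_invalid("stage '%s' failed: %s", name, conditionMessage(e)))
    log_line("stage %-16s %8.1f s", name, proc.time()["elapsed"] - s0)
    out
  }

  reports <- list()
  if (write_sessions)
    stage("simulate", write_session(simulate_session(scfg),
                                    file.path(out_dir, "sessions", "loaded")))
  if (isTRUE(config$condition_matrix)) {
    cm <- stage("condition-matrix", run_condition_matrix(
      scfg, hidden = 30, epochs = config$train$epochs,
      learning_rate = config$train$learning_rate,
      momentum = config$train$momentum,
      train_duration_s = config$split$train_duration_s,
      n_seeds = config$n_seeds))
    reports$condition_matrix <- list(mean = as.list(cm$mean), sd = as.list(cm$sd),
                                     per_seed = cm$per_seed)
  }
  ag <- stage("arch-grid", run_architecture_grid(
    scfg, architectures = config$architectures,
    epochs = config$train$epochs,
    learning_rate = config$train$learning_rate,
    momentum = config$train$momentum,
    train_duration_s = config$split$train_duration_s,
    n_seeds = config$n_seeds))
  reports$architecture_grid <- list(network = ag$label, hidden_neurons = ag$neurons,
                                    mean = ag$mean, sd = ag$sd)

  stage("report", {
    jsonlite::write_json(reports, file.path(out_dir, "reports", "reports.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    prov <- list(config = unclass(config),
                 config_hash = config_hash(config),
                 package_version = as.character(utils::packageVersion("emgmlp")))
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  log_line("total %8.1f s", proc.time()["elapsed"] - t0)
  invisible(reports)
}

# order-stable hash of the config (djb2 over its canonical JSON)
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", h)
}
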