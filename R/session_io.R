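# Session serialization: one delimited text file per rate group plus a JSON
# metadata sidecar, so sessions survive as plain text.

#' Write a session to a directory
#'
#' Layout: `raw.tsv` (12 EMG channels + grip force at the raw rate),
#' `kin.tsv` (6 hand DOF + 3 shoulder + 12 ground-truth activations at the
#' kinematic rate) and `meta.json` (rates, schedule, MVC amplitudes, config
#' echo, seeds).
#'
#' @param session an `emg_session`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  raw <- data.table::as.data.table(t(session$raw_emg))
  data.table::setnames(raw, paste0("emg_", rownames(session$raw_emg)))
  raw[, force := session$grip_force]
  data.table::fwrite(raw, file.path(dir, "raw.tsv"), sep = "\t")
  kin <- data.table::as.data.table(cbind(t(session$hand), t(session$shoulder),
                                         t(session$truth_activation)))
  data.table::setnames(kin, c(rownames(session$hand), rownames(session$shoulder),
                              paste0("truth_", rownames(session$truth_activation))))
  data.table::fwrite(kin, file.path(dir, "kin.tsv"), sep = "\t")
  meta <- list(
    raw_rate_hz = session$config$raw_rate_hz,
    kin_rate_hz = session$config$kin_rate_hz,
    mvc_amplitude = as.list(session$mvc_amplitude),
    schedule = session$schedule,
    plant_seed = session$plant_seed,
    config = unclass(session$config)
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a session written by [write_session()]
#'
#' @param dir session directory.
#' @return an `emg_session`.
#' @export
read_session <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  raw <- data.table::fread(file.path(dir, "raw.tsv"))
  kin <- data.table::fread(file.path(dir, "kin.tsv"))
  cfg <- meta$config
  cfg$noise <- as.list(cfg$noise)
  config <- do.call(session_config, cfg[names(cfg) %in% names(formals(session_config))])
  emg_cols <- grep("^emg_", names(raw), value = TRUE)
  truth_cols <- grep("^truth_", names(kin), value = TRUE)
  hand <- t(as.matrix(kin[, c("x", "y", "z", "pitch", "roll", "yaw"), with = FALSE]))
  shoulder <- t(as.matrix(kin[, c("sx", "sy", "sz"), with = FALSE]))
  truth <- t(as.matrix(kin[, truth_cols, with = FALSE]))
  rownames(truth) <- sub("^truth_", "", truth_cols)
  emg <- t(as.matrix(raw[, emg_cols, with = FALSE]))
  rownames(emg) <- sub("^emg_", "", emg_cols)
  n_kin <- ncol(hand); n_raw <- ncol(emg)
  structure(list(
    raw_emg = emg, grip_force = raw$force,
    hand = hand, shoulder = shoulder,
    truth_activation = truth,
    mvc_amplitude = unlist(meta$mvc_amplitude),
    schedule = as.data.frame(meta$schedule),
    grip_force_kin = NULL,
    times_kin = seq(0, by = 1 / config$kin_rate_hz, length.out = n_kin),
    times_raw = seq(0, by = 1 / config$raw_rate_hz, length.out = n_raw),
    config = config, plant_seed = meta$plant_seed
  ), class = "emg_session")
}
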