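# Plain-text session serialization: recordings as TSV (samples x channels),
# events as TSV, ground truth and configuration as JSON sidecars.

#' Write a session to a directory
#'
#' Writes `recording.tsv` (one column per channel, header row of channel
#' labels), `meta.json` (sampling rate, labels), `events.tsv`, `truth.json`
#' and `config.json`.
#'
#' @param session a `ts_session` from [simulate_session()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "ts_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_recording(session$recording, dir)
  write_events(session$events, file.path(dir, "events.tsv"))
  truth <- session$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(unclass(truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(unclass(session$truth$config),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

write_recording <- function(recording, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- t(recording$data)
  colnames(m) <- recording$channel_labels
  utils::write.table(format(m, digits = 7, trim = TRUE, scientific = FALSE),
                     file.path(dir, "recording.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(sampling_rate_hz = recording$sampling_rate_hz,
                            channel_labels = recording$channel_labels),
                       file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

read_recording <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  m <- utils::read.delim(file.path(dir, "recording.tsv"),
                         check.names = FALSE)
  new_recording(t(as.matrix(m)), meta$sampling_rate_hz, meta$channel_labels)
}

#' Write / read the per-trial event table
#'
#' Tab-separated values with a header row; columns are the event tibble's
#' columns (`trial`, `letter1..3`, `onset1_s..onset3_s`, `probe_onset_s`,
#' `probe_letter`, `rt_s`, `correct`).
#'
#' @param events event tibble.
#' @param path file path.
#' @return `path` (write) or the event tibble (read).
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  df$correct <- as.logical(df$correct)
  for (col in c("letter1", "letter2", "letter3", "probe_letter")) {
    df[[col]] <- as.character(df[[col]])
  }
  tibble::as_tibble(df)
}

#' Read a session directory written by [write_session()]
#'
#' @param dir session directory.
#' @return A `ts_session` (ground truth restored from JSON).
#' @export
read_session <- function(dir) {
  recording <- read_recording(dir)
  events <- read_events(file.path(dir, "events.tsv"))
  tr <- jsonlite::read_json(file.path(dir, "truth.json"),
                            simplifyVector = TRUE)
  truth <- structure(list(
    config = validate_config(tr$config),
    channels = tibble::as_tibble(tr$channels),
    tuned_positions = tibble::as_tibble(tr$tuned_positions),
    bursts = tibble::as_tibble(tr$bursts),
    artifacts = tibble::as_tibble(tr$artifacts),
    position_phase_centers_rad = tr$position_phase_centers_rad,
    phase_code_planted = tr$phase_code_planted), class = "ts_truth")
  structure(list(recording = recording, events = events, truth = truth),
            class = "ts_session")
}
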