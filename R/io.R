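# Plain-text exchange formats: long-format CSV for recordings with a JSON
# sidecar for metadata, CSV truth tables, and CSV envelope export.

#' Write a recording to CSV with a JSON sidecar
#'
#' The data go to `<path>.csv` in long format (`trial, channel,
#' sample_index, value`); sampling rate, channel names, condition, baseline
#' length, the stimulus envelope and (for simulated recordings) the
#' generating parameters go to `<path>.json`.
#'
#' @param rec a `simulated_recording` (or compatible list).
#' @param path output path without extension.
#' @return the two file paths, invisibly.
#' @export
write_recording <- function(rec, path) {
  d <- dim(rec$data)
  long <- data.frame(
    trial = rep(seq_len(d[1]), each = d[2] * d[3]),
    channel = rep(rep(rec$channel_names, each = d[3]), times = d[1]),
    sample_index = rep(seq_len(d[3]), times = d[1] * d[2]),
    value = as.vector(aperm(rec$data, c(3, 2, 1))))
  csv <- paste0(path, ".csv"); js <- paste0(path, ".json")
  write.csv(long, csv, row.names = FALSE)
  truth <- rec$truth
  meta <- list(
    fs_hz = rec$fs_hz, channel_names = rec$channel_names,
    condition = rec$condition, baseline_s = rec$baseline_s,
    rate_hz = rec$stimulus$rate_hz,
    envelope_rec = rec$envelope_rec,
    truth = if (!is.null(truth)) list(
      g_td = truth$g_td, c_frontal = truth$c_frontal,
      frontal_lag_s = truth$frontal_lag_s, noise_amp = truth$noise_amp,
      w_left = truth$w_left, seed = truth$seed,
      right_osc = unclass(truth$right_osc),
      left_osc = unclass(truth$left_osc)))
  jsonlite::write_json(meta, js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, json = js))
}

#' Read a recording written by [write_recording()]
#'
#' Also accepts user-supplied data in the same schema: a long CSV with
#' columns `trial, channel, sample_index, value` plus a JSON sidecar
#' carrying at least `fs_hz` and `channel_names`.
#'
#' @param path path without extension (reads `<path>.csv`, `<path>.json`).
#' @return a list of class `simulated_recording` (truth is NULL for
#'   user-supplied data without it).
#' @export
read_recording <- function(path) {
  long <- read.csv(paste0(path, ".csv"))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  chans <- meta$channel_names
  trials <- sort(unique(long$trial))
  ns <- max(long$sample_index)
  data <- array(NA_real_, dim = c(length(trials), length(chans), ns),
                dimnames = list(NULL, chans, NULL))
  for (j in seq_along(trials)) for (ch in chans) {
    sel <- long$trial == trials[j] & long$channel == ch
    data[j, ch, long$sample_index[sel]] <- long$value[sel]
  }
  if (anyNA(data)) stop("recording CSV has missing (trial, channel, sample) cells")
  structure(list(data = data, channel_names = chans, fs_hz = meta$fs_hz,
                 stimulus = list(rate_hz = meta$rate_hz,
                                 envelope = NULL, fs_hz = meta$fs_hz),
                 envelope_rec = meta$envelope_rec,
                 condition = meta$condition,
                 baseline_s = meta$baseline_s %||% 0,
                 truth = meta$truth),
            class = "simulated_recording")
}

#' Write a cohort truth table to CSV
#'
#' @param truth data.frame as returned in the `truth` attribute of
#'   [sample_subject_params()].
#' @param path output CSV path.
#' @export
write_truth_table <- function(truth, path) {
  write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' Export an envelope series as CSV
#'
#' Two columns, `time_s` and `value`; filter provenance goes to a JSON
#' sidecar when the envelope carries a `params` block.
#'
#' @param env an `envelope_series` (or list with `values`, `fs_hz`).
#' @param path output CSV path.
#' @export
write_envelope_csv <- function(env, path) {
  df <- data.frame(time_s = (seq_along(env$values) - 1) / env$fs_hz,
                   value = env$values)
  write.csv(df, path, row.names = FALSE)
  if (!is.null(env$params))
    jsonlite::write_json(env$params, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}
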