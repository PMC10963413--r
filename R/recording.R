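#' Multichannel recording container
#'
#' A `wl_recording` holds one modality's multichannel time series: a numeric
#' samples matrix (time in rows, channels in columns), the sampling rate, the
#' modality label, channel labels, and the clock offset `t0_s`. Dense raw
#' signals (e.g. 32-channel EEG at 500 Hz) are kept as a matrix rather than a
#' long data frame; `as_tibble()` converts when a tabular view is wanted.
#'
#' @param samples numeric matrix or vector; time in rows, one column per
#'   channel. `NaN`/`NA` entries are explicit dropout markers (e.g. blinks).
#' @param sample_rate_hz sampling rate in Hz, positive scalar.
#' @param modality one of `"fnirs_730"`, `"fnirs_850"`, `"eeg"`, `"ecg"`,
#'   `"ppg"`, `"eog_h"`, `"eog_v"`, `"gaze_x"`, `"gaze_y"`, `"pupil"`, or
#'   `"gaze"` for a two-column x/y gaze recording.
#' @param channel_labels character vector, one per column. Defaults to
#'   `ch01, ch02, ...`.
#' @param t0_s clock time of the first sample, seconds.
#' @return an object of class `wl_recording`.
#' @examples
#' rec <- wl_recording(sin(2 * pi * 10 * seq(0, 1, by = 1 / 500)),
#'                     sample_rate_hz = 500, modality = "eeg")
#' n_samples(rec)
#' @export
wl_recording <- function(samples, sample_rate_hz, modality,
                         channel_labels = NULL, t0_s = 0) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  if (!is.matrix(samples) || !is.numeric(samples)) {
    abort("`samples` must be a numeric matrix (time x channels).")
  }
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1 ||
      sample_rate_hz <= 0) {
    abort("`sample_rate_hz` must be a positive scalar.")
  }
  if (is.null(channel_labels)) {
    channel_labels <- sprintf("ch%02d", seq_len(ncol(samples)))
  }
  if (length(channel_labels) != ncol(samples)) {
    abort("`channel_labels` length must match the number of channels.")
  }
  colnames(samples) <- channel_labels
  structure(
    list(samples = samples, sample_rate_hz = sample_rate_hz,
         modality = modality, channel_labels = channel_labels, t0_s = t0_s),
    class = "wl_recording"
  )
}

#' @export
print.wl_recording <- function(x, ...) {
  cat(sprintf("<wl_recording: %s>  %d ch x %d samples @ %g Hz, t0 = %g s\n",
              x$modality, ncol(x$samples), nrow(x$samples),
              x$sample_rate_hz, x$t0_s))
  invisible(x)
}

#' @rdname wl_recording
#' @param rec a `wl_recording`.
#' @export
n_samples <- function(rec) nrow(rec$samples)

#' @rdname wl_recording
#' @export
rec_times <- function(rec) {
  rec$t0_s + (seq_len(nrow(rec$samples)) - 1L) / rec$sample_rate_hz
}

#' @rdname wl_recording
#' @param x a `wl_recording`.
#' @param ... unused.
#' @export
as_tibble.wl_recording <- function(x, ...) {
  out <- as_tibble(as.data.frame(x$samples))
  dplyr::bind_cols(tibble(time_s = rec_times(x)), out)
}

# index range of samples whose timestamps fall in [t_start, t_end)
interval_index <- function(rec, t_start, t_end) {
  t <- rec_times(rec)
  which(t >= t_start & t < t_end)
}

#' Read and write recordings as CSV with a JSON sidecar
#'
#' The on-disk interchange is one CSV per recording (first column `time_s`,
#' one column per channel) plus a JSON sidecar holding `modality`,
#' `sample_rate_hz`, `channel_labels`, and `t0_s`.
#'
#' @param rec a `wl_recording`.
#' @param path CSV path; the sidecar is written at `<path>.json`.
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns a `wl_recording`.
#' @export
write_recording <- function(rec, path) {
  readr::write_csv(as_tibble(rec), path)
  meta <- list(modality = rec$modality, sample_rate_hz = rec$sample_rate_hz,
               channel_labels = as.list(rec$channel_labels), t0_s = rec$t0_s)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  samples <- as.matrix(df[, setdiff(names(df), "time_s"), drop = FALSE])
  wl_recording(samples, meta$sample_rate_hz, meta$modality,
               channel_labels = unlist(meta$channel_labels), t0_s = meta$t0_s)
}
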