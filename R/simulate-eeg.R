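#' Simulate multichannel EEG with block-scaled band powers
#'
#' Each channel is a sum over the five classical bands of band-limited
#' Gaussian noise whose variance is scaled block-wise by the ground-truth
#' `scale_<band>` factors, plus a 1/f background, an optional 60 Hz line
#' component, and optional template blink artifacts.
#'
#' @param truth ground-truth tibble for one recording.
#' @param n_channels,sample_rate_hz montage size and rate (32 ch at 500 Hz).
#' @param band_amp_uV baseline RMS amplitude per band (uV), named by band.
#' @param pink_amp_uV RMS of the 1/f background (uV).
#' @param line_amp_uV amplitude of the 60 Hz line component (uV); 0 disables.
#' @param blink_times_s optional vector of blink onsets; a 400 ms template
#'   deflection is added to frontal channels (first quarter of the montage).
#' @param duration_s recording length; defaults to 30 s past the last block.
#' @param seed integer seed.
#' @return a `wl_recording` of modality `"eeg"`.
#' @export
simulate_eeg <- function(truth, n_channels = 32, sample_rate_hz = 500,
                         band_amp_uV = c(delta = 4, theta = 4, alpha = 6,
                                         beta = 3, gamma = 1.5),
                         pink_amp_uV = 2, line_amp_uV = 20,
                         blink_times_s = NULL, duration_s = NULL, seed = 1) {
  if (nrow(truth) == 0) abort("`truth` must contain at least one block.")
  bands <- eeg_bands()
  scale_cols <- paste0("scale_", bands$band)
  if (!all(scale_cols %in% names(truth))) {
    abort("`truth` must carry scale_<band> columns for all five bands.")
  }
  duration_s <- duration_s %||% (max(truth$t_end_s) + 30)
  n <- round(duration_s * sample_rate_hz)
  t <- (seq_len(n) - 1) / sample_rate_hz

  # per-sample amplitude scale: sqrt of the containing (or preceding)
  # block's band-power factor; the lead-in inherits the first block's level
  block_scale <- function(col) {
    i <- findInterval(t, truth$t_start_s)
    sqrt(truth[[col]][pmax(1, i)])
  }
  scales <- map(scale_cols, block_scale)
  names(scales) <- bands$band

  with_seed(seed, {
    samples <- matrix(0, n, n_channels)
    for (ch in seq_len(n_channels)) {
      x <- numeric(n)
      for (i in seq_len(nrow(bands))) {
        bn <- band_noise(n, sample_rate_hz, bands$lo_hz[i], bands$hi_hz[i])
        x <- x + band_amp_uV[[bands$band[i]]] * scales[[bands$band[i]]] * bn
      }
      if (pink_amp_uV > 0) x <- x + pink_amp_uV * pink_noise(n)
      if (line_amp_uV > 0) {
        x <- x + line_amp_uV * sin(2 * pi * 60 * t + runif(1, 0, 2 * pi))
      }
      samples[, ch] <- x
    }
    if (!is.null(blink_times_s) && length(blink_times_s) > 0) {
      tmpl_t <- seq(0, 0.4, by = 1 / sample_rate_hz)
      tmpl <- 100 * sin(pi * tmpl_t / 0.4)^2  # 100 uV blink deflection
      frontal <- seq_len(max(1, n_channels %/% 4))
      for (bt in blink_times_s) {
        i0 <- round(bt * sample_rate_hz) + 1
        idx <- i0:min(i0 + length(tmpl) - 1, n)
        if (length(idx) < 2) next
        for (ch in frontal) {
          samples[idx, ch] <- samples[idx, ch] + tmpl[seq_along(idx)]
        }
      }
    }
    wl_recording(samples, sample_rate_hz, "eeg",
                 channel_labels = sprintf("E%02d", seq_len(n_channels)))
  })
}
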