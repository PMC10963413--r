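#' Classical EEG frequency bands
#'
#' Delta 1-4, theta 4-8, alpha 8-13, beta 13-30, gamma 30-59 Hz (the gamma
#' band is bounded above by the band-pass edge). Bands are half-open
#' `[lo, hi)` and non-overlapping.
#' @return tibble with columns `band`, `lo_hz`, `hi_hz`.
#' @export
eeg_bands <- function() {
  tibble(band = c("delta", "theta", "alpha", "beta", "gamma"),
         lo_hz = c(1, 4, 8, 13, 30),
         hi_hz = c(4, 8, 13, 30, 59))
}

#' Notch filter for power-line interference
#'
#' Zero-phase (forward-backward) order-8 Butterworth band-stop centred on the
#' line frequency (default stop band 58-62 Hz).
#'
#' @param rec a `wl_recording`.
#' @param freq_hz line frequency.
#' @param order Butterworth order.
#' @param width_hz half-width handling: the stop band is
#'   `freq_hz +/- width_hz`.
#' @return a filtered `wl_recording`.
#' @export
notch_filter <- function(rec, freq_hz = 60, order = 8, width_hz = 2) {
  fs <- rec$sample_rate_hz
  if (freq_hz + width_hz >= fs / 2) {
    abort("notch band must lie below Nyquist.")
  }
  out <- rec
  # the order-8 band-stop is realised as two cascaded order-4 sections: the
  # single 16-pole transfer function is numerically unstable in double
  # precision at this rate, the cascade is exact in response and stable
  half <- order %/% 2
  band <- c(freq_hz - width_hz, freq_hz + width_hz)
  x <- butter_filtfilt(rec$samples, fs, half, band, "stop")
  out$samples <- butter_filtfilt(x, fs, order - half, band, "stop")
  out
}

#' Broadband band-pass filter
#'
#' Zero-phase order-7 Butterworth band-pass (default 1-59 Hz), removing slow
#' drift and everything above the line-noise notch.
#'
#' @param rec a `wl_recording`.
#' @param lo_hz,hi_hz band edges.
#' @param order Butterworth order.
#' @return a filtered `wl_recording`.
#' @export
bandpass_filter <- function(rec, lo_hz = 1, hi_hz = 59, order = 7) {
  fs <- rec$sample_rate_hz
  if (hi_hz >= fs / 2) abort("`hi_hz` must be below Nyquist.")
  out <- rec
  # realised as cascaded order-7 high-pass and low-pass sections (second-
  # order-section form): the wide band-pass as one transfer function is
  # numerically unstable
  x <- sos_filtfilt(rec$samples, fs, order, lo_hz, "high")
  out$samples <- sos_filtfilt(x, fs, order, hi_hz, "low")
  out
}

#' Remove ocular artifacts using a synchronized EOG reference
#'
#' Two selectable routes. `"regression"` (the default, appropriate for short
#' recordings) subtracts the least-squares projection of both EOG channels
#' from every EEG channel. `"component"` computes a linear (principal
#' component) decomposition of the EEG and zeroes components whose absolute
#' correlation with either EOG channel exceeds `threshold` before
#' reconstruction.
#'
#' @param rec EEG `wl_recording`.
#' @param eog_h,eog_v EOG `wl_recording`s resampled/synchronized to the EEG
#'   clock (same number of samples).
#' @param method `"regression"` or `"component"`.
#' @param threshold component-EOG absolute correlation above which a
#'   component is removed.
#' @return a cleaned `wl_recording`.
#' @export
remove_ocular_artifacts <- function(rec, eog_h, eog_v,
                                    method = c("regression", "component"),
                                    threshold = 0.7) {
  method <- match.arg(method)
  E <- cbind(eog_h$samples[, 1], eog_v$samples[, 1])
  if (nrow(E) != nrow(rec$samples)) {
    abort("EOG and EEG recordings differ in length.")
  }
  out <- rec
  if (all(abs(E) < .Machine$double.eps)) return(out)
  if (method == "regression") {
    Ec <- scale(E, scale = FALSE)
    B <- solve(crossprod(Ec), crossprod(Ec, scale(rec$samples,
                                                  scale = FALSE)))
    out$samples <- rec$samples - Ec %*% B
  } else {
    X <- scale(rec$samples, scale = FALSE)
    pc <- eigen(crossprod(X) / (nrow(X) - 1), symmetric = TRUE)
    S <- X %*% pc$vectors                        # component time courses
    rho <- abs(cor(S, E))
    drop <- apply(rho, 1, max) > threshold
    S[, drop] <- 0
    out$samples <- S %*% t(pc$vectors) +
      matrix(colMeans(rec$samples), nrow(X), ncol(X), byrow = TRUE)
  }
  out
}

#' Artifact subspace reconstruction (simplified)
#'
#' Sliding-window subspace cleaning against calibration statistics: the
#' covariance of a calibration interval defines per-direction reference
#' standard deviations; within each window, principal directions of the
#' calibration decomposition whose projected variance exceeds
#' `cutoff_sd` times the calibration SD are reconstructed from the retained
#' subspace (their projection is rescaled to the calibration SD).
#'
#' @param rec EEG `wl_recording`.
#' @param calibration_interval `[t0, t1)` seconds of clean data (>= 10 s).
#' @param cutoff_sd variance cutoff in calibration SD units.
#' @param window_s sliding-window length.
#' @return a cleaned `wl_recording`.
#' @export
asr_clean <- function(rec, calibration_interval, cutoff_sd = 20,
                      window_s = 1) {
  if (diff(calibration_interval) < 10) {
    abort("calibration window must be at least 10 s.")
  }
  idx <- interval_index(rec, calibration_interval[1],
                        calibration_interval[2])
  C <- scale(rec$samples[idx, , drop = FALSE], scale = FALSE)
  dec <- eigen(crossprod(C) / (nrow(C) - 1), symmetric = TRUE)
  V <- dec$vectors
  ref_sd <- sqrt(pmax(dec$values, .Machine$double.eps))
  fs <- rec$sample_rate_hz
  w <- round(window_s * fs)
  n <- nrow(rec$samples)
  mu <- colMeans(rec$samples[idx, , drop = FALSE])
  out <- rec
  starts <- seq(1, n, by = w)
  for (s in starts) {
    rows <- s:min(s + w - 1, n)
    X <- sweep(rec$samples[rows, , drop = FALSE], 2, mu)
    P <- X %*% V
    psd <- apply(P, 2, sd)
    bad <- is.finite(psd) & psd > cutoff_sd * ref_sd
    if (any(bad)) {
      P[, bad] <- sweep(P[, bad, drop = FALSE], 2,
                        ref_sd[bad] / psd[bad], `*`)
      out$samples[rows, ] <- P %*% t(V) +
        matrix(mu, length(rows), length(mu), byrow = TRUE)
    }
  }
  out
}

#' Moving-window Welch band powers
#'
#' Welch power spectral density over a moving window (default 2 s, hop 1 s),
#' with Hamming sub-segments of half the window length and 50% overlap,
#' integrated over each band's `[lo, hi)` in uV^2.
#'
#' @param rec EEG `wl_recording` (band-passed).
#' @param bands tibble as from [eeg_bands()].
#' @param window_s moving-window length (s).
#' @param hop_s hop between windows (s).
#' @return long tibble: `channel`, `band`, `t_s` (window start), `power`.
#' @export
welch_bandpower <- function(rec, bands = eeg_bands(), window_s = 2,
                            hop_s = 1) {
  fs <- rec$sample_rate_hz
  if (window_s * fs < 2) abort("window too short for the sampling rate.")
  if (any(bands$hi_hz > fs / 2)) abort("band edge above Nyquist.")
  nw <- round(window_s * fs)          # moving window
  ns <- nw %/% 2                      # Welch sub-segment (50% overlap)
  hop_seg <- ns %/% 2
  n <- nrow(rec$samples)
  if (n < nw) abort("recording shorter than one analysis window.")

  # STFT over sub-segments once per channel; each moving window then averages
  # the three sub-segment periodograms it covers
  seg_starts <- seq(1, n - ns + 1, by = hop_seg)
  win_starts <- seq(1, n - nw + 1, by = round(hop_s * fs))
  w <- signal::hamming(ns)
  U <- sum(w^2)
  nf <- floor(ns / 2) + 1
  freq <- (seq_len(nf) - 1) * fs / ns
  dbl <- rep(2, nf); dbl[1] <- 1; if (ns %% 2 == 0) dbl[nf] <- 1
  df <- fs / ns
  band_of <- lapply(seq_len(nrow(bands)), function(i) {
    which(freq >= bands$lo_hz[i] & freq < bands$hi_hz[i])
  })

  out <- vector("list", ncol(rec$samples))
  for (j in seq_len(ncol(rec$samples))) {
    x <- rec$samples[, j]
    segmat <- vapply(seg_starts, function(s) {
      seg <- x[s:(s + ns - 1)]
      seg <- (seg - mean(seg)) * w
      Mod(fft(seg)[seq_len(nf)])^2
    }, numeric(nf))
    segmat <- segmat * dbl / (fs * U)     # one-sided PSD per sub-segment
    powers <- vapply(win_starts, function(s) {
      segs <- which(seg_starts >= s & seg_starts + ns - 1 <= s + nw - 1)
      psd <- rowMeans(segmat[, segs, drop = FALSE])
      vapply(band_of, function(ix) sum(psd[ix]) * df, numeric(1))
    }, numeric(nrow(bands)))
    out[[j]] <- tibble(
      channel = rec$channel_labels[j],
      band = rep(bands$band, times = length(win_starts)),
      t_s = rep((win_starts - 1) / fs, each = nrow(bands)),
      power = as.numeric(powers)
    )
  }
  list_rbind(out)
}

#' Band-ratio workload indices
#'
#' Element-wise window ratios per channel: the engagement ratio
#' `beta / (alpha + theta)`, `theta / alpha`, `theta / beta`, and
#' `(theta + alpha) / (beta + alpha)`. Windows with a zero denominator are
#' emitted as missing.
#'
#' @param bp long band-power tibble from [welch_bandpower()].
#' @return long tibble: `channel`, `band` (ratio name), `t_s`, `power`.
#' @export
ratio_features <- function(bp) {
  need <- c("theta", "alpha", "beta")
  if (!all(need %in% unique(bp$band))) {
    abort("theta, alpha and beta bands are required for ratio indices.")
  }
  wide <- tidyr::pivot_wider(bp, names_from = "band",
                             values_from = "power")
  safe_div <- function(num, den) if_else(den > 0, num / den, NA_real_)
  wide |>
    mutate(
      engagement = safe_div(.data$beta, .data$alpha + .data$theta),
      theta_alpha = safe_div(.data$theta, .data$alpha),
      theta_beta = safe_div(.data$theta, .data$beta),
      ta_ba = safe_div(.data$theta + .data$alpha,
                       .data$beta + .data$alpha)
    ) |>
    select("channel", "t_s", "engagement", "theta_alpha", "theta_beta",
           "ta_ba") |>
    tidyr::pivot_longer(c("engagement", "theta_alpha", "theta_beta",
                          "ta_ba"),
                        names_to = "band", values_to = "power") |>
    select("channel", "band", "t_s", "power")
}

#' Full EEG feature extraction chain
#'
#' Notch (60 Hz) -> band-pass (1-59 Hz) -> optional EOG artifact removal ->
#' moving-window Welch band powers and ratio indices -> block means. With 32
#' channels this yields 32 x (5 bands + 4 ratios) = 288 measures per block.
#'
#' @param rec raw EEG `wl_recording`.
#' @param design block design tibble.
#' @param eog_h,eog_v optional synchronized EOG recordings for artifact
#'   removal.
#' @param asr if `TRUE`, apply [asr_clean()] calibrated on the lead-in
#'   baseline (disabled by default).
#' @return long feature tibble.
#' @export
eeg_features <- function(rec, design, eog_h = NULL, eog_v = NULL,
                         asr = FALSE) {
  check_design(design)
  x <- notch_filter(rec)
  x <- bandpass_filter(x)
  if (!is.null(eog_h) && !is.null(eog_v)) {
    x <- remove_ocular_artifacts(x, eog_h, eog_v)
  }
  if (asr) x <- asr_clean(x, c(0, min(design$t_start_s)))
  bp <- welch_bandpower(x)
  all_series <- bind_rows(bp, ratio_features(bp))
  out <- list()
  for (b in seq_len(nrow(design))) {
    blk <- all_series |>
      filter(.data$t_s >= design$t_start_s[b],
             .data$t_s + 2 <= design$t_end_s[b]) |>
      group_by(.data$channel, .data$band) |>
      summarise(value = mean(.data$power, na.rm = TRUE), .groups = "drop")
    out[[b]] <- tibble(
      design[b, c("subject_id", "task_name", "task_session", "condition",
                  "block_index")],
      modality = "eeg",
      measure_name = sprintf("eeg.%s.%s", blk$band, blk$channel),
      value = blk$value
    )
  }
  list_rbind(out)
}
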