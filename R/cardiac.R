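#' Detect R-peaks in an ECG recording
#'
#' Pan-Tompkins-style chain: band-pass (5-15 Hz) -> derivative -> squaring ->
#' moving-window integration (150 ms) -> adaptive threshold with a 250 ms
#' refractory period, followed by a deterministic correction rule replacing
#' manual editing: intervals deviating more than 30% from the running median
#' RR are deleted (short, spurious) or left flagged (long, missed beat).
#'
#' @param ecg single-channel `wl_recording` at >= 100 Hz.
#' @return a `wl_beats` tibble: `time_s` of each beat, `rr_ms` to the next
#'   beat (`NA` for the last), `flagged` for corrected neighbourhoods, with
#'   attribute `source = "ecg"`.
#' @export
detect_rpeaks <- function(ecg) {
  fs <- ecg$sample_rate_hz
  if (fs < 100) abort("ECG sample rate must be at least 100 Hz.")
  x <- ecg$samples[, 1]
  if (sd(x) < .Machine$double.eps) {
    warn("flat ECG signal; no beats detected.")
    return(beat_series(numeric(0), "ecg"))
  }
  bp <- butter_filtfilt(x, fs, 3, c(5, 15), "pass")
  dx <- c(0, diff(bp)) * fs
  sq <- dx^2
  w <- max(1L, round(0.150 * fs))
  integ <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  integ[is.na(integ)] <- 0

  refr <- round(0.250 * fs)
  # candidate local maxima of the integrated signal
  cand <- which(diff(sign(diff(integ))) < 0) + 1L
  cand <- cand[order(integ[cand], decreasing = TRUE)]
  thr <- 0.25 * mean(integ[integ > quantile(integ, 0.95)])
  keep <- logical(length(x))
  peaks <- integer(0)
  for (i in sort(cand[integ[cand] > thr])) {
    if (length(peaks) == 0 || i - peaks[length(peaks)] > refr) {
      peaks <- c(peaks, i)
    } else if (integ[i] > integ[peaks[length(peaks)]]) {
      peaks[length(peaks)] <- i
    }
  }
  # refine each detection to the local band-passed maximum (R wave apex)
  half <- round(0.10 * fs)
  peaks <- vapply(peaks, function(i) {
    lo <- max(1L, i - half); hi <- min(length(x), i + half)
    lo + which.max(bp[lo:hi]) - 1L
  }, numeric(1))
  peaks <- sort(unique(peaks))
  times <- (peaks - 1) / fs + ecg$t0_s
  correct_beats(beat_series(times, "ecg"))
}

beat_series <- function(times, source) {
  rr <- if (length(times) > 1) c(diff(times) * 1000, NA_real_) else
    rep(NA_real_, length(times))
  out <- tibble(time_s = times, rr_ms = rr,
                flagged = rep(FALSE, length(times)))
  class(out) <- c("wl_beats", class(out))
  attr(out, "source") <- source
  out
}

# median-deviation correction replacing the manual editing step: RR intervals
# deviating >30% from the running median are removed (the later beat of a
# short pair is dropped) and remaining deviant intervals flagged.
correct_beats <- function(beats, max_dev = 0.30) {
  if (nrow(beats) < 3) return(beats)
  times <- beats$time_s
  repeat {
    rr <- diff(times)
    med <- stats::runmed(rr, k = min(9L, (length(rr) - 1) %/% 2 * 2 + 1))
    short <- which(rr < (1 - max_dev) * med)
    if (length(short) == 0) break
    times <- times[-(short[1] + 1)]
    if (length(times) < 3) break
  }
  out <- beat_series(times, attr(beats, "source"))
  rr <- diff(times)
  if (length(rr) > 0) {
    med <- stats::runmed(rr, k = min(9L, (length(rr) - 1) %/% 2 * 2 + 1))
    dev <- abs(rr - med) / med > max_dev
    out$flagged[seq_along(dev)] <- dev
  }
  out
}

#' Time-domain heart-rate variability measures
#'
#' Heart rate (bpm), SDNN (SD of RR intervals, ms) and RMSSD
#' (root-mean-square of successive RR differences, ms).
#'
#' @param beats a `wl_beats` tibble.
#' @return tibble with `heartrate_bpm`, `hrv_sd_ms`, `hrv_rms_ms` (missing
#'   when fewer than 3 beats are available).
#' @export
rr_time_metrics <- function(beats) {
  rr <- beats$rr_ms[!is.na(beats$rr_ms)]
  if (nrow(beats) < 3 || length(rr) < 2) {
    return(tibble(heartrate_bpm = NA_real_, hrv_sd_ms = NA_real_,
                  hrv_rms_ms = NA_real_))
  }
  tibble(
    heartrate_bpm = 60000 / mean(rr),
    hrv_sd_ms = sd(rr),
    hrv_rms_ms = sqrt(mean(diff(rr)^2))
  )
}

#' Frequency-domain heart-rate variability measures
#'
#' The RR tachogram is cubic-spline interpolated to 4 Hz, linearly detrended,
#' and analysed with a Welch PSD. Absolute powers integrate 0.04-0.15 Hz (LF)
#' and 0.15-0.4 Hz (HF) in ms^2; relative powers are normalized units
#' `band / (LF + HF)`, so `lf_rel + hf_rel = 1`.
#'
#' @param beats a `wl_beats` tibble.
#' @param resample_hz tachogram sampling rate.
#' @return tibble with `lf_abs`, `lf_rel`, `hf_abs`, `hf_rel`, `lf_hf`, and
#'   `reliable` (`FALSE` when the span is under 120 s, too short for stable
#'   LF estimates).
#' @export
rr_spectrum <- function(beats, resample_hz = 4) {
  na_out <- tibble(lf_abs = NA_real_, lf_rel = NA_real_, hf_abs = NA_real_,
                   hf_rel = NA_real_, lf_hf = NA_real_, reliable = FALSE)
  if (nrow(beats) < 8) return(na_out)
  times <- beats$time_s[-nrow(beats)]
  rr <- beats$rr_ms[-nrow(beats)]
  span <- diff(range(times))
  if (span < 10) return(na_out)
  grid <- seq(min(times), max(times), by = 1 / resample_hz)
  tach <- stats::spline(times, rr, xout = grid)$y
  tach <- stats::resid(lm(tach ~ grid))
  nper <- min(length(tach), 256)
  ps <- welch_psd(tach, resample_hz, nperseg = nper)
  lf <- integrate_band(ps$freq, ps$psd, 0.04, 0.15)
  hf <- integrate_band(ps$freq, ps$psd, 0.15, 0.40)
  tibble(
    lf_abs = lf, lf_rel = lf / (lf + hf),
    hf_abs = hf, hf_rel = hf / (lf + hf),
    lf_hf = if (hf > 0) lf / hf else NA_real_,
    reliable = span >= 120
  )
}

#' Detect pulses and pulse morphology in a PPG recording
#'
#' Order-7 Butterworth band-pass (0.1-10 Hz), then peak picking with a
#' minimum prominence and a minimum distance of 0.6 times the running median
#' inter-pulse interval (the false-peak correction, rejecting dicrotic
#' notches). Morphology is the mean full width at half prominence and the
#' mean peak amplitude over the recording.
#'
#' @param ppg single-channel `wl_recording` at >= 25 Hz.
#' @param min_prominence_frac minimum peak prominence as a fraction of the
#'   median retained prominence during the initial pass.
#' @return list with `beats` (a `wl_beats`) and `morphology` (tibble
#'   `mean_width_s`, `mean_peak_amplitude`).
#' @export
detect_pulses <- function(ppg, min_prominence_frac = 0.5) {
  fs <- ppg$sample_rate_hz
  if (fs < 25) abort("PPG sample rate must be at least 25 Hz.")
  # order-7 band-pass 0.1-10 Hz, cascaded high/low-pass biquad sections
  x <- sos_filtfilt(ppg$samples[, 1], fs, 7, 0.1, "high")
  x <- sos_filtfilt(x, fs, 7, 10, "low")
  locs <- which(diff(sign(diff(x))) < 0) + 1L
  if (length(locs) == 0 || sd(x) < .Machine$double.eps) {
    warn("no pulses detected in PPG signal.")
    return(list(beats = beat_series(numeric(0), "ppg"),
                morphology = tibble(mean_width_s = NA_real_,
                                    mean_peak_amplitude = NA_real_)))
  }
  prom <- peak_prominence(x, locs)
  # reference prominence: upper decile is dominated by true pulses
  ref <- quantile(prom, 0.9, names = FALSE)
  big <- locs[prom >= min_prominence_frac * ref]
  big <- big[order(big)]
  # false-peak correction: enforce minimum distance of 0.6 x running median IPI
  kept <- integer(0)
  for (i in big) {
    if (length(kept) < 2) {
      if (length(kept) == 0 || (i - kept[length(kept)]) / fs > 0.3) {
        kept <- c(kept, i)
      } else if (x[i] > x[kept[length(kept)]]) kept[length(kept)] <- i
      next
    }
    ipi_med <- median(diff(kept)) / fs
    if ((i - kept[length(kept)]) / fs >= 0.6 * ipi_med) {
      kept <- c(kept, i)
    } else if (x[i] > x[kept[length(kept)]]) {
      kept[length(kept)] <- i
    }
  }
  prom_kept <- peak_prominence(x, kept)
  widths <- vapply(seq_along(kept), function(k) {
    half_prominence_width(x, kept[k], prom_kept[k]) / fs
  }, numeric(1))
  beats <- correct_beats(beat_series((kept - 1) / fs + ppg$t0_s, "ppg"))
  list(
    beats = beats,
    morphology = tibble(mean_width_s = mean(widths, na.rm = TRUE),
                        mean_peak_amplitude = mean(x[kept]))
  )
}

# topographic prominence of local maxima: height above the higher of the two
# minima separating the peak from the nearest higher ground on each side
peak_prominence <- function(x, locs) {
  vapply(locs, function(i) {
    left <- x[seq_len(i)]
    higher_l <- which(left > x[i])
    lmin <- if (length(higher_l)) min(left[max(higher_l):i]) else min(left)
    right <- x[i:length(x)]
    higher_r <- which(right > x[i])
    rmin <- if (length(higher_r)) min(right[seq_len(min(higher_r))]) else
      min(right)
    x[i] - max(lmin, rmin)
  }, numeric(1))
}

# full width at half prominence with linear interpolation at the crossings
half_prominence_width <- function(x, i, prom) {
  h <- x[i] - prom / 2
  li <- i
  while (li > 1 && x[li - 1] > h) li <- li - 1
  left <- if (li == 1) li else {
    li - (h - x[li]) / (x[li - 1] - x[li])
  }
  ri <- i
  n <- length(x)
  while (ri < n && x[ri + 1] > h) ri <- ri + 1
  right <- if (ri == n) ri else {
    ri + (x[ri] - h) / (x[ri] - x[ri + 1])
  }
  right - left
}

#' Block-level cardiac features for one recording
#'
#' Runs beat detection once over the recording and computes the 8 ECG
#' measures (heart rate, SDNN, RMSSD, LF/HF absolute and relative powers,
#' LF/HF ratio) per block, plus pulse width and amplitude for PPG
#' (10 measures). Frequency metrics on short blocks carry the detector's
#' reliability flag but are emitted regardless.
#'
#' @param rec `wl_recording` of modality `"ecg"` or `"ppg"`.
#' @param design block design tibble.
#' @return long feature tibble.
#' @export
cardiac_features <- function(rec, design) {
  check_design(design)
  src <- rec$modality
  if (src == "ecg") {
    beats <- detect_rpeaks(rec)
    morph <- NULL
  } else {
    det <- detect_pulses(rec)
    beats <- det$beats
    morph <- det$morphology
  }
  out <- list()
  for (b in seq_len(nrow(design))) {
    sel <- beats[beats$time_s >= design$t_start_s[b] &
                   beats$time_s < design$t_end_s[b], ]
    class(sel) <- class(beats)
    attr(sel, "source") <- src
    tm <- rr_time_metrics(sel)
    sp <- rr_spectrum(sel)
    vals <- c(heartrate = tm$heartrate_bpm, hrv_sd = tm$hrv_sd_ms,
              hrv_rms = tm$hrv_rms_ms, lf_abs = sp$lf_abs,
              lf_rel = sp$lf_rel, hf_abs = sp$hf_abs, hf_rel = sp$hf_rel,
              lf_hf = sp$lf_hf)
    if (src == "ppg") {
      pm <- pulse_morphology_interval(rec, design$t_start_s[b],
                                      design$t_end_s[b])
      vals <- c(vals, mean_width = pm$mean_width_s,
                mean_peak = pm$mean_peak_amplitude)
    }
    out[[b]] <- tibble(
      design[b, c("subject_id", "task_name", "task_session", "condition",
                  "block_index")],
      modality = src,
      measure_name = paste0(src, ".", names(vals)),
      value = as.numeric(vals)
    )
  }
  list_rbind(out)
}

# morphology over a sub-interval (re-detects within the window)
pulse_morphology_interval <- function(ppg, t0, t1) {
  idx <- interval_index(ppg, t0, t1)
  sub <- wl_recording(ppg$samples[idx, , drop = FALSE], ppg$sample_rate_hz,
                      "ppg", ppg$channel_labels, t0_s = t0)
  suppressWarnings(detect_pulses(sub)$morphology)
}
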