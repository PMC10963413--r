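#' Detect saccades from horizontal and vertical EOG
#'
#' Behrens-style adaptive-acceleration detection: channels are scaled to
#' degrees with the calibration constant, smoothed with a Savitzky-Golay
#' polynomial filter, and differentiated by central differences. The radial
#' eye velocity's acceleration is compared against an adaptive threshold of
#' `k` times the running (trailing-window) SD of acceleration; an event is a
#' supra-threshold acceleration peak pair of opposite sign within
#' `pair_window_ms`. Events closer than `merge_ms` are merged. Amplitude is
#' the 2-D positional displacement from onset to offset.
#'
#' @param eog_h,eog_v synchronized single-channel EOG `wl_recording`s (uV).
#' @param calib_uv_per_deg calibration constant (uV per degree), must be
#'   positive.
#' @param k adaptive threshold multiplier.
#' @param trail_s trailing window for the running acceleration SD (s).
#' @param smooth_ms Savitzky-Golay window (ms).
#' @param pair_window_ms maximum separation of the opposite-sign
#'   acceleration peaks.
#' @param merge_ms events closer than this are merged.
#' @param min_amplitude_deg events smaller than this are discarded.
#' @return tibble of saccade events: `onset_s`, `duration_ms`,
#'   `amplitude_deg`, `peak_velocity_deg_s`, `source = "eog"`.
#' @export
detect_saccades_eog <- function(eog_h, eog_v, calib_uv_per_deg = 10,
                                k = 3.4, trail_s = 2, smooth_ms = 20,
                                pair_window_ms = 100, merge_ms = 50,
                                min_amplitude_deg = 1) {
  if (calib_uv_per_deg <= 0) abort("calibration constant must be positive.")
  if (n_samples(eog_h) != n_samples(eog_v)) {
    abort("EOG channels must be synchronized (equal length).")
  }
  fs <- eog_h$sample_rate_hz
  x <- eog_h$samples[, 1] / calib_uv_per_deg
  y <- eog_v$samples[, 1] / calib_uv_per_deg
  bad <- !is.finite(x) | !is.finite(y)
  if (any(bad)) {
    inform(sprintf("skipping %d non-finite EOG samples", sum(bad)))
    x[bad] <- stats::approx(which(!bad), x[!bad], xout = which(bad),
                            rule = 2)$y
    y[bad] <- stats::approx(which(!bad), y[!bad], xout = which(bad),
                            rule = 2)$y
  }
  nsg <- max(5L, round(smooth_ms / 1000 * fs) * 2 + 1)
  xs <- signal::sgolayfilt(x, p = 3, n = nsg)
  ys <- signal::sgolayfilt(y, p = 3, n = nsg)
  cdiff <- function(v) c(0, (v[-(1:2)] - v[1:(length(v) - 2)]) / 2, 0) * fs
  vx <- cdiff(xs); vy <- cdiff(ys)
  vel <- sqrt(vx^2 + vy^2)
  vel_s <- signal::sgolayfilt(vel, p = 3, n = nsg)
  acc <- cdiff(vel_s)

  # running noise scale of acceleration: rolling MAD over the trailing
  # window (robust to the saccadic acceleration transients themselves, which
  # would inflate a plain running SD when saccades are frequent)
  wtr <- max(5L, round(trail_s * fs))
  if (wtr %% 2 == 0) wtr <- wtr + 1L
  wtr <- min(wtr, (length(acc) - 1) %/% 2 * 2 + 1)
  rsd <- 1.4826 * stats::runmed(abs(acc), k = wtr)
  thr <- k * pmax(rsd, .Machine$double.eps)

  pos_reg <- rle_regions(acc > thr)
  neg_reg <- rle_regions(acc < -thr)
  if (nrow(pos_reg) == 0 || nrow(neg_reg) == 0) return(empty_saccades("eog"))

  pw <- round(pair_window_ms / 1000 * fs)
  events <- list()
  for (r in seq_len(nrow(pos_reg))) {
    ppk <- pos_reg$start[r] + which.max(acc[pos_reg$start[r]:pos_reg$end[r]]) - 1
    cand <- neg_reg[neg_reg$start > ppk & neg_reg$start <= ppk + pw, ]
    if (nrow(cand) == 0) next
    on <- pos_reg$start[r]
    off <- cand$end[1]
    events[[length(events) + 1]] <- c(on, off)
  }
  if (length(events) == 0) return(empty_saccades("eog"))
  ev <- do.call(rbind, events)
  # merge events whose gaps are below merge_ms
  gap <- round(merge_ms / 1000 * fs)
  merged <- list(ev[1, ])
  if (nrow(ev) > 1) {
    for (r in 2:nrow(ev)) {
      last <- merged[[length(merged)]]
      if (ev[r, 1] - last[2] < gap) {
        merged[[length(merged)]] <- c(last[1], max(last[2], ev[r, 2]))
      } else merged[[length(merged) + 1]] <- ev[r, ]
    }
  }
  rows <- map(merged, function(e) {
    on <- e[1]; off <- min(e[2], length(xs))
    tibble(
      onset_s = (on - 1) / fs + eog_h$t0_s,
      duration_ms = (off - on) / fs * 1000,
      amplitude_deg = sqrt((xs[off] - xs[on])^2 + (ys[off] - ys[on])^2),
      peak_velocity_deg_s = max(vel_s[on:off])
    )
  })
  out <- list_rbind(rows) |>
    filter(.data$amplitude_deg >= min_amplitude_deg) |>
    mutate(source = "eog")
  out
}

rle_regions <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  tibble(start = starts[r$values], end = ends[r$values])
}

empty_saccades <- function(source) {
  tibble(onset_s = numeric(), duration_ms = numeric(),
         amplitude_deg = numeric(), peak_velocity_deg_s = numeric(),
         source = character())
}

#' Block-mean saccade features
#'
#' Arithmetic means of peak velocity, duration, and amplitude over events
#' whose onset falls within the interval; an empty interval yields missing
#' values.
#'
#' @param events saccade tibble (from [detect_saccades_eog()] or
#'   [detect_fixations()]).
#' @param interval `[t0, t1)` seconds.
#' @return tibble with `peak_velocity_mean`, `duration_mean`,
#'   `amplitude_mean`.
#' @export
saccade_block_features <- function(events, interval) {
  sel <- filter(events, .data$onset_s >= interval[1],
                .data$onset_s < interval[2])
  if (nrow(sel) == 0) {
    return(tibble(peak_velocity_mean = NA_real_, duration_mean = NA_real_,
                  amplitude_mean = NA_real_))
  }
  tibble(
    peak_velocity_mean = mean(sel$peak_velocity_deg_s),
    duration_mean = mean(sel$duration_ms),
    amplitude_mean = mean(sel$amplitude_deg)
  )
}

#' Dispersion-based fixation detection (I-DT)
#'
#' Grows a sample window while the dispersion (x range plus y range) stays
#' within `dispersion_deg`; windows lasting at least `min_duration_ms` are
#' emitted as fixations. Gaze shifts between consecutive fixations are
#' emitted as gaze-source saccade events whose amplitude is the centroid
#' distance.
#'
#' @param gaze two-channel (x, y) `wl_recording` in degrees.
#' @param dispersion_deg I-DT dispersion threshold.
#' @param min_duration_ms minimum fixation duration.
#' @return list with `fixations` (`onset_s`, `duration_ms`, `x_deg`,
#'   `y_deg`, `dispersion_deg`) and `saccades` (same shape as
#'   [detect_saccades_eog()], `source = "gaze"`).
#' @export
detect_fixations <- function(gaze, dispersion_deg = 1.0,
                             min_duration_ms = 100) {
  fs <- gaze$sample_rate_hz
  x <- gaze$samples[, 1]; y <- gaze$samples[, 2]
  t <- rec_times(gaze)
  ok <- is.finite(x) & is.finite(y)
  min_n <- max(2L, round(min_duration_ms / 1000 * fs))
  n <- length(x)
  fixations <- list()
  i <- 1L
  while (i + min_n - 1 <= n) {
    j <- i + min_n - 1L
    win <- i:j
    if (!all(ok[win])) { i <- i + 1L; next }
    disp <- function(w) diff(range(x[w])) + diff(range(y[w]))
    if (disp(win) > dispersion_deg) { i <- i + 1L; next }
    while (j + 1 <= n && ok[j + 1] &&
             disp(i:(j + 1)) <= dispersion_deg) {
      j <- j + 1L
    }
    fixations[[length(fixations) + 1]] <- tibble(
      onset_s = t[i], duration_ms = (j - i + 1) / fs * 1000,
      x_deg = mean(x[i:j]), y_deg = mean(y[i:j]),
      dispersion_deg = disp(i:j)
    )
    i <- j + 1L
  }
  fixations <- if (length(fixations)) list_rbind(fixations) else
    tibble(onset_s = numeric(), duration_ms = numeric(), x_deg = numeric(),
           y_deg = numeric(), dispersion_deg = numeric())
  saccades <- empty_saccades("gaze")
  if (nrow(fixations) > 1) {
    rows <- map(seq_len(nrow(fixations) - 1), function(r) {
      t0 <- fixations$onset_s[r] + fixations$duration_ms[r] / 1000
      t1 <- fixations$onset_s[r + 1]
      idx <- which(t >= t0 & t <= t1 & ok)
      pv <- if (length(idx) > 1) {
        max(sqrt(diff(x[idx])^2 + diff(y[idx])^2) * fs)
      } else NA_real_
      tibble(
        onset_s = t0, duration_ms = (t1 - t0) * 1000,
        amplitude_deg = sqrt(
          (fixations$x_deg[r + 1] - fixations$x_deg[r])^2 +
            (fixations$y_deg[r + 1] - fixations$y_deg[r])^2),
        peak_velocity_deg_s = pv, source = "gaze"
      )
    })
    # instantaneous transitions (adjacent windows) are kept as zero-duration
    # shift events so fixation + saccade + unclassified time still
    # partitions the interval
    saccades <- list_rbind(rows) |> filter(.data$duration_ms >= 0)
  }
  list(fixations = fixations, saccades = saccades)
}

#' Block-level eye-tracking features
#'
#' The seven gaze/pupil workload correlates over an interval: mean pupil
#' diameter (blink gaps up to 500 ms linearly interpolated first, longer
#' gaps excluded), mean saccade velocity and length, fixation count, mean
#' fixation duration, fixation rate, and the fixation-to-saccade time ratio.
#'
#' @param fixations,saccades event tibbles from [detect_fixations()].
#' @param pupil single-channel pupil `wl_recording` (mm, `NaN` blinks).
#' @param interval `[t0, t1)` seconds.
#' @param max_blink_ms longest NaN run treated as a blink and interpolated.
#' @return tibble with the seven features (ratio missing when there is no
#'   saccade time; all-but-pupil missing when the pupil trace is more than
#'   half missing after blink handling is flagged via `low_quality`).
#' @export
gaze_block_features <- function(fixations, saccades, pupil, interval,
                                max_blink_ms = 500) {
  idx <- interval_index(pupil, interval[1], interval[2])
  p <- pupil$samples[idx, 1]
  p <- interpolate_blinks(p, pupil$sample_rate_hz, max_blink_ms)
  low_quality <- mean(!is.finite(p)) > 0.5
  fx <- filter(fixations, .data$onset_s >= interval[1],
               .data$onset_s < interval[2])
  sc <- filter(saccades, .data$onset_s >= interval[1],
               .data$onset_s < interval[2])
  fix_time <- sum(fx$duration_ms) / 1000
  sacc_time <- sum(sc$duration_ms) / 1000
  tibble(
    pupil_diameter_mean = mean(p, na.rm = TRUE),
    saccade_velocity_mean = if (nrow(sc)) {
      mean(sc$peak_velocity_deg_s, na.rm = TRUE)
    } else NA_real_,
    saccade_length_mean = if (nrow(sc)) mean(sc$amplitude_deg) else
      NA_real_,
    fixation_count = nrow(fx),
    fixation_duration_mean = if (nrow(fx)) mean(fx$duration_ms) else
      NA_real_,
    fixation_rate_per_s = nrow(fx) / diff(interval),
    fixation_saccade_ratio = if (sacc_time > 0) fix_time / sacc_time else
      NA_real_,
    low_quality = low_quality
  )
}

# linear interpolation across NaN runs no longer than max_blink_ms
interpolate_blinks <- function(p, fs, max_blink_ms = 500) {
  bad <- !is.finite(p)
  if (!any(bad) || all(bad)) return(p)
  r <- rle(bad)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  out <- p
  for (g in which(r$values)) {
    if (r$lengths[g] / fs * 1000 <= max_blink_ms) {
      i0 <- starts[g]; i1 <- ends[g]
      lo <- if (i0 > 1) p[i0 - 1] else p[i1 + 1]
      hi <- if (i1 < length(p)) p[i1 + 1] else p[i0 - 1]
      out[i0:i1] <- seq(lo, hi, length.out = r$lengths[g] + 2)[-c(1, r$lengths[g] + 2)]
    }
  }
  out
}

#' Block-level ocular features for a full recording
#'
#' EOG saccade statistics (3 measures: peak velocity, duration, amplitude)
#' and the seven eye-tracking features per block.
#'
#' @param eog_h,eog_v,gaze,pupil recordings as produced by
#'   [simulate_ocular()].
#' @param design block design tibble.
#' @param calib_uv_per_deg EOG calibration constant.
#' @return long feature tibble.
#' @export
ocular_features <- function(eog_h, eog_v, gaze, pupil, design,
                            calib_uv_per_deg = 10) {
  check_design(design)
  eog_ev <- detect_saccades_eog(eog_h, eog_v,
                                calib_uv_per_deg = calib_uv_per_deg)
  det <- detect_fixations(gaze)
  out <- list()
  for (b in seq_len(nrow(design))) {
    iv <- c(design$t_start_s[b], design$t_end_s[b])
    sb <- saccade_block_features(eog_ev, iv)
    gb <- gaze_block_features(det$fixations, det$saccades, pupil, iv)
    vals <- c(
      eog.peak_saccade_velocity = sb$peak_velocity_mean,
      eog.saccade_duration = sb$duration_mean,
      eog.saccade_amplitude = sb$amplitude_mean
    )
    eye <- as.numeric(gb[1, 1:7])
    names(eye) <- paste0("eye.", names(gb)[1:7])
    base <- design[b, c("subject_id", "task_name", "task_session",
                        "condition", "block_index")]
    out[[length(out) + 1]] <- bind_rows(
      tibble(base, modality = "eog", measure_name = names(vals),
             value = as.numeric(vals)),
      tibble(base, modality = "eye", measure_name = names(eye),
             value = eye)
    )
  }
  list_rbind(out)
}
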