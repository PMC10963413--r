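#' Modified Beer-Lambert law parameters
#'
#' Extinction coefficients (1/(mM cm)), differential pathlength factors, and
#' the source-detector separation used to convert optical-density changes to
#' chromophore concentration changes. Defaults are conventional
#' adult-forehead values; the extinction matrix rows are wavelengths (730,
#' 850 nm) and columns chromophores (HbO, HbR).
#'
#' @param extinction 2x2 matrix of extinction coefficients.
#' @param dpf_730,dpf_850 differential pathlength factors.
#' @param separation_cm source-detector distance (cm).
#' @export
mbll_params <- function(extinction = matrix(c(0.390, 1.102,
                                              1.058, 0.691),
                                            nrow = 2, byrow = TRUE,
                                            dimnames = list(c("730", "850"),
                                                            c("HbO", "HbR"))),
                        dpf_730 = 6.0, dpf_850 = 6.0, separation_cm = 2.5) {
  if (any(extinction <= 0) || any(c(dpf_730, dpf_850, separation_cm) <= 0)) {
    abort("all MBLL constants must be strictly positive.")
  }
  if (abs(det(extinction)) < 1e-8) {
    abort("extinction coefficient matrix is singular.")
  }
  structure(list(extinction = extinction, dpf_730 = dpf_730,
                 dpf_850 = dpf_850, separation_cm = separation_cm),
            class = "mbll_params")
}

# wavelength x chromophore sensitivity: OD change per mM concentration change
forward_matrix <- function(params) {
  L <- params$separation_cm * c(params$dpf_730, params$dpf_850)
  diag(L) %*% params$extinction
}

#' Low-pass FIR filter for slow haemodynamics
#'
#' Linear-phase Hamming-window FIR low-pass (default order 20, cutoff
#' 0.1 Hz), applied with group-delay compensation so block-locked features
#' are not shifted in time.
#'
#' @param rec a `wl_recording` (nominally fNIRS intensity at 2 Hz).
#' @param order filter order.
#' @param cutoff_hz cutoff frequency; must be below Nyquist.
#' @return a filtered `wl_recording`.
#' @export
lowpass_fir <- function(rec, order = 20, cutoff_hz = 0.1) {
  fs <- rec$sample_rate_hz
  if (cutoff_hz >= fs / 2) abort("`cutoff_hz` must be below Nyquist.")
  if (fs != 2) warn(sprintf("sample rate is %g Hz; instrument nominally records at 2 Hz", fs))
  b <- as.numeric(signal::fir1(order, cutoff_hz / (fs / 2), type = "low",
                               window = signal::hamming(order + 1)))
  b <- b / sum(b)   # unit DC gain
  delay <- order / 2
  out <- rec
  out$samples <- apply_cols(rec$samples, function(x) {
    n <- length(x)
    xp <- c(rep(x[1], order), x, rep(x[n], order))
    # causal convolution, then shift by the group delay of the linear-phase FIR
    y <- as.numeric(stats::filter(xp, b, method = "convolution", sides = 1))
    y[(order + delay + 1):(order + delay + n)]
  })
  out
}

#' Sliding-window motion artifact rejection (SMAR)
#'
#' Computes a sliding-window standard-deviation profile per optode and masks
#' samples in windows whose SD exceeds `spike_sd` times the running median of
#' the SD profile, or whose raw intensity falls outside `saturation_limits`.
#' Samples are masked, not altered; downstream block statistics skip them.
#'
#' @param rec a `wl_recording` of raw intensities.
#' @param window_s sliding-window length (s).
#' @param spike_sd SD multiple above the running median flagged as motion.
#' @param saturation_limits length-2 numeric; intensities at or beyond these
#'   raw values are masked as saturated.
#' @return list with `rec` (unchanged signal) and `quality_mask` (logical
#'   matrix, `TRUE` = retained), plus `mask_fraction` per channel.
#' @export
smar_reject <- function(rec, window_s = 4, spike_sd = 3,
                        saturation_limits = c(1, 4000)) {
  if (window_s <= 0) abort("`window_s` must be positive.")
  fs <- rec$sample_rate_hz
  w <- max(3L, round(window_s * fs))
  if (w %% 2 == 0) w <- w + 1L
  half <- (w - 1L) %/% 2L
  n <- nrow(rec$samples)
  mask <- matrix(TRUE, n, ncol(rec$samples))
  for (j in seq_len(ncol(rec$samples))) {
    x <- rec$samples[, j]
    # centred rolling SD via rolling moments
    k <- rep(1 / w, w)
    m1 <- as.numeric(stats::filter(x, k, sides = 2))
    m2 <- as.numeric(stats::filter(x^2, k, sides = 2))
    sdp <- sqrt(pmax(0, m2 - m1^2))
    sdp[seq_len(half)] <- sdp[half + 1]
    sdp[(n - half + 1):n] <- sdp[n - half]
    kref <- min(16 * half + 1, if (n %% 2 == 1) n else n - 1)
    ref <- stats::runmed(sdp, k = kref)
    bad_sd <- sdp > spike_sd * pmax(ref, .Machine$double.eps)
    # expand window flags to the samples they cover
    bad <- as.logical(stats::filter(as.numeric(bad_sd), rep(1, w),
                                    sides = 2) > 0)
    bad[is.na(bad)] <- FALSE
    sat <- x <= saturation_limits[1] | x >= saturation_limits[2]
    mask[, j] <- !(bad | sat)
    if (!any(mask[, j])) {
      warn(sprintf("channel %s fully masked by SMAR", rec$channel_labels[j]))
    }
  }
  list(rec = rec, quality_mask = mask,
       mask_fraction = colMeans(!mask))
}

#' Modified Beer-Lambert law conversion to haemoglobin concentrations
#'
#' Converts two-wavelength raw intensities to HbO/HbR concentration changes:
#' `dOD(t) = -log10(I(t) / mean(I over baseline))` per wavelength, then the
#' 2x2 pathlength-scaled extinction system is inverted per sample. Oxygenation
#' (`Oxy = HbO - HbR`) and total haemoglobin (`HbT = HbO + HbR`) are derived.
#'
#' @param i730,i850 intensity `wl_recording`s with matching geometry.
#' @param baseline_interval `[t0, t1)` interval (s) whose mean intensity is
#'   the reference; needs at least 10 s of unmasked samples.
#' @param params a [mbll_params()].
#' @param quality_mask optional logical matrix (from [smar_reject()], applied
#'   per wavelength pair-wise AND); masked samples are excluded from the
#'   baseline and flagged in the output mask.
#' @return a `wl_hemo` object: list of `wl_recording`s `HbO`, `HbR`, `Oxy`,
#'   `HbT` (uM) plus the `quality_mask`.
#' @export
mbll <- function(i730, i850, baseline_interval, params = mbll_params(),
                 quality_mask = NULL) {
  if (nrow(i730$samples) != nrow(i850$samples) ||
      i730$sample_rate_hz != i850$sample_rate_hz) {
    abort("intensity recordings must share length and sampling rate.")
  }
  if (any(i730$samples <= 0, na.rm = TRUE) ||
      any(i850$samples <= 0, na.rm = TRUE)) {
    abort("non-positive intensity encountered; cannot take optical density.")
  }
  idx <- interval_index(i730, baseline_interval[1], baseline_interval[2])
  if (is.null(quality_mask)) {
    quality_mask <- matrix(TRUE, nrow(i730$samples), ncol(i730$samples))
  }
  if (min(colSums(quality_mask[idx, , drop = FALSE])) *
      (1 / i730$sample_rate_hz) < 10) {
    abort("baseline interval must contain at least 10 s of unmasked samples.")
  }
  M <- forward_matrix(params)
  Minv <- solve(M)
  conc <- function(jcol) {
    base730 <- mean(i730$samples[idx, jcol][quality_mask[idx, jcol]])
    base850 <- mean(i850$samples[idx, jcol][quality_mask[idx, jcol]])
    dod <- rbind(-log10(i730$samples[, jcol] / base730),
                 -log10(i850$samples[, jcol] / base850))
    (Minv %*% dod) * 1e3   # mM -> uM
  }
  nch <- ncol(i730$samples)
  hbo <- hbr <- matrix(NA_real_, nrow(i730$samples), nch)
  for (j in seq_len(nch)) {
    cc <- conc(j)
    hbo[, j] <- cc[1, ]
    hbr[, j] <- cc[2, ]
  }
  as_rec <- function(m, lab) {
    wl_recording(m, i730$sample_rate_hz, lab, i730$channel_labels,
                 t0_s = i730$t0_s)
  }
  structure(list(HbO = as_rec(hbo, "HbO"), HbR = as_rec(hbr, "HbR"),
                 Oxy = as_rec(hbo - hbr, "Oxy"),
                 HbT = as_rec(hbo + hbr, "HbT"),
                 quality_mask = quality_mask),
            class = "wl_hemo")
}

#' Block summary statistics of a scalar series
#'
#' The five block statistics applied to every haemodynamic channel: mean,
#' ordinary-least-squares slope against time (units/s), signed peak value,
#' time from block onset to the peak (s), and the sum of samples. Masked
#' samples are excluded; fewer than 4 retained samples yields missing values.
#'
#' @param values numeric vector of samples in the block.
#' @param times sample times (s, recording clock).
#' @param t_start block onset (s) used as the time-to-peak reference.
#' @param mask optional logical keep-mask.
#' @return tibble with columns `mean`, `slope`, `peak`, `time_to_peak`,
#'   `sum`.
#' @export
block_features <- function(values, times, t_start = min(times),
                           mask = NULL) {
  if (!is.null(mask)) {
    values <- values[mask]
    times <- times[mask]
  }
  keep <- is.finite(values)
  values <- values[keep]; times <- times[keep]
  if (length(values) < 4) {
    return(tibble(mean = NA_real_, slope = NA_real_, peak = NA_real_,
                  time_to_peak = NA_real_, sum = NA_real_))
  }
  ipk <- which.max(values)
  tibble(
    mean = mean(values),
    slope = ols_slope(times, values),
    peak = values[ipk],
    time_to_peak = times[ipk] - t_start,
    sum = sum(values)
  )
}

#' Full fNIRS feature extraction chain
#'
#' Runs the processing order intensity -> low-pass FIR -> SMAR -> MBLL, then
#' computes the five block statistics for every optode and chromophore
#' (HbO, HbR, Oxy, HbT), yielding 16 x 4 x 5 = 320 measures per block with a
#' 16-optode montage.
#'
#' @param i730,i850 raw intensity recordings.
#' @param design block design tibble for this recording.
#' @param params a [mbll_params()].
#' @param baseline defaults to the pre-task lead-in `[0, first block start)`.
#' @param smar_args list of overrides passed to [smar_reject()].
#' @return long feature tibble (one row per block x measure).
#' @export
fnirs_features <- function(i730, i850, design, params = mbll_params(),
                           baseline = NULL, smar_args = list()) {
  check_design(design)
  f730 <- lowpass_fir(i730)
  f850 <- lowpass_fir(i850)
  q730 <- do.call(smar_reject, c(list(rec = f730), smar_args))
  q850 <- do.call(smar_reject, c(list(rec = f850), smar_args))
  mask <- q730$quality_mask & q850$quality_mask
  baseline <- baseline %||% c(0, min(design$t_start_s))
  hemo <- mbll(f730, f850, baseline, params, quality_mask = mask)
  hemo_block_features(hemo, design)
}

# block statistics over every chromophore x optode of a wl_hemo
hemo_block_features <- function(hemo, design) {
  t <- rec_times(hemo$HbO)
  chroms <- c("HbO", "HbR", "Oxy", "HbT")
  out <- list()
  for (b in seq_len(nrow(design))) {
    idx <- which(t >= design$t_start_s[b] & t < design$t_end_s[b])
    for (ch in chroms) {
      rec <- hemo[[ch]]
      for (j in seq_len(ncol(rec$samples))) {
        feats <- block_features(rec$samples[idx, j], t[idx],
                                t_start = design$t_start_s[b],
                                mask = hemo$quality_mask[idx, j])
        out[[length(out) + 1]] <- tibble(
          design[b, c("subject_id", "task_name", "task_session",
                      "condition", "block_index")],
          modality = "fnirs",
          measure_name = sprintf("fnirs.%s.%s.%s", ch,
                                 rec$channel_labels[j],
                                 names(feats)),
          value = as.numeric(feats[1, ])
        )
      }
    }
  }
  list_rbind(out)
}
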