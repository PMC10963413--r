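#' Simulate two-wavelength fNIRS intensity recordings
#'
#' Forward model: per optode, block-locked HbO responses are built by
#' convolving the block boxcar with a canonical double-gamma impulse response
#' (peak 6 s, undershoot 16 s), scaled so the plateau equals the block's
#' `hemo_amplitude` (uM); HbR is -1/3 of HbO. Concentrations are pushed
#' through the modified Beer-Lambert law in the forward direction to raw
#' intensities at 730 and 850 nm around a baseline intensity, then sinusoidal
#' physiological components (Mayer-wave 0.1 Hz, respiratory 0.25 Hz),
#' multiplicative white noise and optional motion spikes are added.
#'
#' @param truth ground-truth tibble from [generate_ground_truth()] for a
#'   single recording (one subject, task, session).
#' @param n_optodes number of optode channels.
#' @param sample_rate_hz sampling rate (the instrument records at 2 Hz).
#' @param baseline_intensity raw intensity level, a.u.
#' @param noise_sd multiplicative white-noise SD (fraction of baseline).
#' @param physio_amp amplitude of each physiological sinusoid as an
#'   equivalent HbO excursion (uM).
#' @param n_spikes motion spikes per recording (10x amplitude, 2 s).
#' @param params [mbll_params()] used for the forward model.
#' @param duration_s recording length; defaults to 30 s past the last block.
#' @param seed integer seed; output is bit-reproducible given the seed.
#' @return a list with elements `i730` and `i850` (both `wl_recording`).
#' @export
simulate_fnirs <- function(truth, n_optodes = 16, sample_rate_hz = 2,
                           baseline_intensity = 1000, noise_sd = 0.001,
                           physio_amp = 0.05, n_spikes = 0,
                           params = mbll_params(), duration_s = NULL,
                           seed = 1) {
  if (nrow(truth) == 0) abort("`truth` must contain at least one block.")
  check_design(truth)
  duration_s <- duration_s %||% (max(truth$t_end_s) + 30)
  n <- round(duration_s * sample_rate_hz)
  t <- (seq_len(n) - 1) / sample_rate_hz

  # unit-plateau block regressor: boxcar convolved with the HRF, normalised
  # by the HRF area so a sustained block reaches the injected amplitude
  dt <- 1 / sample_rate_hz
  hrf <- hrf_double_gamma(seq(0, 32, by = dt))
  # scale so the step response peaks at 1: a sustained block then reaches
  # exactly the injected amplitude
  hrf <- hrf / max(cumsum(hrf) * dt)
  hbo_uM <- numeric(n)
  for (b in seq_len(nrow(truth))) {
    box <- as.numeric(t >= truth$t_start_s[b] & t < truth$t_end_s[b])
    resp <- stats::convolve(box, rev(hrf), type = "open")[seq_len(n)] * dt
    hbo_uM <- hbo_uM + truth$hemo_amplitude[b] * resp
  }
  hbr_uM <- -hbo_uM / 3

  M <- forward_matrix(params)  # 2x2: wavelength x chromophore, per mM
  dod <- M %*% rbind(hbo_uM, hbr_uM) * 1e-3   # OD change per wavelength

  make_rec <- function(row, modality, s) {
    with_seed(s, {
      base <- baseline_intensity * 10^(-dod[row, ])
      physio <- physio_amp * (sin(2 * pi * 0.1 * t + runif(1, 0, 2 * pi)) +
                                sin(2 * pi * 0.25 * t + runif(1, 0, 2 * pi)))
      # physiological component expressed as an equivalent OD modulation
      base <- base * 10^(-physio * M[row, 1] * 1e-3)
      samples <- matrix(NA_real_, n, n_optodes)
      for (k in seq_len(n_optodes)) {
        x <- base * (1 + rnorm(n, sd = noise_sd))
        if (n_spikes > 0) {
          at <- sample(seq_len(n - 4), n_spikes)
          for (a in at) x[a:(a + 3)] <- x[a:(a + 3)] * (1 + 0.5)
        }
        samples[, k] <- x
      }
      wl_recording(samples, sample_rate_hz, modality,
                   channel_labels = sprintf("opt%02d", seq_len(n_optodes)))
    })
  }
  list(
    i730 = make_rec(1, "fnirs_730", child_seed(seed, "fnirs730")),
    i850 = make_rec(2, "fnirs_850", child_seed(seed, "fnirs850"))
  )
}
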