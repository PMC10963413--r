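#' Simulate ECG and PPG recordings from a modulated RR series
#'
#' Beat times are generated iteratively from an RR interval function:
#' block-wise `mean_rr` (ms) modulated by two sinusoids at 0.1 Hz ("LF") and
#' 0.25 Hz ("HF") whose variances follow the block's `rr_lf_hf_ratio`, plus
#' white jitter. The ECG is a QRS-complex template train at those times; the
#' PPG is a smooth pulse template train delayed by the pulse-arrival lag.
#'
#' @param truth ground-truth tibble for one recording.
#' @param ecg_rate_hz,ppg_rate_hz sampling rates.
#' @param rr_mod_sd total RR modulation SD across both sinusoids (ms).
#' @param rr_jitter_sd white beat-to-beat jitter SD (ms).
#' @param ppg_delay_s pulse arrival delay after the R-peak (s).
#' @param ppg_width_s base width of the PPG pulse template (s).
#' @param ppg_amp pulse amplitude (a.u.).
#' @param noise_sd additive measurement noise SD for both signals.
#' @param duration_s recording length; defaults to 30 s past the last block.
#' @param seed integer seed.
#' @return list with `ecg`, `ppg` (`wl_recording`) and `rpeak_times_s`
#'   (the ground-truth R-peak times).
#' @export
simulate_cardiac <- function(truth, ecg_rate_hz = 500, ppg_rate_hz = 100,
                             rr_mod_sd = 40, rr_jitter_sd = 5,
                             ppg_delay_s = 0.25, ppg_width_s = 0.35,
                             ppg_amp = 1, noise_sd = 0.02,
                             duration_s = NULL, seed = 1) {
  if (nrow(truth) == 0) abort("`truth` must contain at least one block.")
  duration_s <- duration_s %||% (max(truth$t_end_s) + 30)

  rr_at <- function(tm) {
    i <- findInterval(tm, truth$t_start_s)
    truth$mean_rr[pmax(1, i)]
  }
  ratio_at <- function(tm) {
    i <- findInterval(tm, truth$t_start_s)
    truth$rr_lf_hf_ratio[pmax(1, i)]
  }

  with_seed(child_seed(seed, "cardiac"), {
    times <- numeric(0)
    tm <- 0.5
    while (tm < duration_s - 0.5) {
      times <- c(times, tm)
      r <- ratio_at(tm)
      # sinusoid amplitudes: var = A^2/2, lf_var/hf_var = r, total = rr_mod_sd^2
      a_hf <- sqrt(2 * rr_mod_sd^2 / (1 + r))
      a_lf <- sqrt(r) * a_hf
      rr <- rr_at(tm) + a_lf * sin(2 * pi * 0.1 * tm) +
        a_hf * sin(2 * pi * 0.25 * tm) + rnorm(1, sd = rr_jitter_sd)
      tm <- tm + rr / 1000
    }

    ecg <- template_train(times, duration_s, ecg_rate_hz, ecg_template,
                          noise_sd = noise_sd)
    ppg <- template_train(times + ppg_delay_s, duration_s, ppg_rate_hz,
                          function(tau) ppg_template(tau, ppg_width_s,
                                                     ppg_amp),
                          noise_sd = noise_sd)
    list(
      ecg = wl_recording(ecg, ecg_rate_hz, "ecg", channel_labels = "ecg"),
      ppg = wl_recording(ppg, ppg_rate_hz, "ppg", channel_labels = "ppg"),
      rpeak_times_s = times
    )
  })
}

# Sum-of-Gaussians QRS-complex template (mV), centred on the R-peak.
ecg_template <- function(tau) {
  g <- function(mu, a, s) a * exp(-((tau - mu) / s)^2 / 2)
  g(-0.20, 0.10, 0.030) +   # P
    g(-0.025, -0.10, 0.010) + # Q
    g(0, 1.0, 0.010) +        # R
    g(0.025, -0.20, 0.010) +  # S
    g(0.18, 0.25, 0.040)      # T
}

# Smooth unimodal pulse (raised-sine squared over base width w).
ppg_template <- function(tau, w = 0.35, amp = 1) {
  out <- numeric(length(tau))
  in_pulse <- tau >= 0 & tau <= w
  out[in_pulse] <- amp * sin(pi * tau[in_pulse] / w)^2
  out
}

# Render a template at each event time onto a sampling grid.
template_train <- function(times, duration_s, rate, template, noise_sd = 0,
                           support = c(-0.3, 0.5)) {
  n <- round(duration_s * rate)
  t <- (seq_len(n) - 1) / rate
  x <- numeric(n)
  for (ev in times) {
    i0 <- max(1, floor((ev + support[1]) * rate) + 1)
    i1 <- min(n, ceiling((ev + support[2]) * rate) + 1)
    if (i1 < i0) next
    idx <- i0:i1
    x[idx] <- x[idx] + template(t[idx] - ev)
  }
  if (noise_sd > 0) x <- x + rnorm(n, sd = noise_sd)
  x
}
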