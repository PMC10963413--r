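#' Simulate EOG, gaze, and pupil recordings with known eye events
#'
#' Generates a fixation-saccade alternation: fixation durations follow an
#' exponential hold time set by the block's `saccade_rate`, saccade amplitudes
#' scatter around the block's `saccade_amplitude_mean`, and saccade kinematics
#' follow a main-sequence rule (peak velocity `V_max * (1 - exp(-A / A_0))`)
#' with a minimum-jerk displacement profile. EOG channels are the gaze traces
#' scaled by the degree-to-microvolt calibration constant plus noise; gaze and
#' pupil are sampled at the eye-tracker rate; blinks appear as spikes on the
#' vertical EOG and NaN dropouts in the pupil trace.
#'
#' @param truth ground-truth tibble for one recording.
#' @param eog_rate_hz,gaze_rate_hz sampling rates (EOG follows the amplifier,
#'   gaze/pupil the eye tracker at 60 Hz).
#' @param calib_uv_per_deg EOG calibration constant (uV per degree). The
#'   default, 10 uV/deg, is the value the EOG detector assumes.
#' @param v_max_deg_s,a0_deg main-sequence parameters.
#' @param eog_noise_uv,gaze_noise_deg,pupil_noise_mm additive noise SDs.
#' @param blink_rate_hz mean blink rate (0 disables blinks).
#' @param duration_s recording length; defaults to 30 s past the last block.
#' @param seed integer seed.
#' @return list with recordings `eog_h`, `eog_v`, `gaze` (2 channels),
#'   `pupil`, and tibbles `saccades` (onset_s, duration_ms, amplitude_deg,
#'   peak_velocity_deg_s) and `fixations` (onset_s, duration_ms, x_deg,
#'   y_deg) holding the ground truth.
#' @export
simulate_ocular <- function(truth, eog_rate_hz = 500, gaze_rate_hz = 60,
                            calib_uv_per_deg = 10, v_max_deg_s = 500,
                            a0_deg = 15, eog_noise_uv = 2,
                            gaze_noise_deg = 0.1, pupil_noise_mm = 0.02,
                            blink_rate_hz = 0.1, duration_s = NULL,
                            seed = 1) {
  if (nrow(truth) == 0) abort("`truth` must contain at least one block.")
  duration_s <- duration_s %||% (max(truth$t_end_s) + 30)
  n_hi <- round(duration_s * eog_rate_hz)
  t_hi <- (seq_len(n_hi) - 1) / eog_rate_hz

  rate_at <- function(tm) {
    i <- findInterval(tm, truth$t_start_s)
    truth$saccade_rate[pmax(1, i)]
  }
  amp_at <- function(tm) {
    i <- findInterval(tm, truth$t_start_s)
    truth$saccade_amplitude_mean[pmax(1, i)]
  }

  with_seed(child_seed(seed, "ocular"), {
    x <- numeric(n_hi); y <- numeric(n_hi)
    pos <- c(0, 0)
    tm <- 0
    sacc <- list(); fixs <- list()
    while (tm < duration_s) {
      r <- rate_at(tm)
      fix_dur <- if (r <= 0) duration_s - tm else {
        max(0.08, stats::rexp(1, rate = r))
      }
      fix_end <- min(tm + fix_dur, duration_s)
      idx <- which(t_hi >= tm & t_hi < fix_end)
      x[idx] <- pos[1]; y[idx] <- pos[2]
      fixs[[length(fixs) + 1]] <- tibble(
        onset_s = tm, duration_ms = (fix_end - tm) * 1000,
        x_deg = pos[1], y_deg = pos[2])
      tm <- fix_end
      if (tm >= duration_s) break

      amp <- max(0.5, rnorm(1, amp_at(tm), 0.1 * amp_at(tm)))
      ang <- runif(1, 0, 2 * pi)
      target <- pos + amp * c(cos(ang), sin(ang))
      if (any(abs(target) > 12)) {       # steer back toward centre
        ang <- atan2(-pos[2], -pos[1]) + runif(1, -0.5, 0.5)
        target <- pos + amp * c(cos(ang), sin(ang))
      }
      v_peak <- v_max_deg_s * (1 - exp(-amp / a0_deg))
      dur <- 1.875 * amp / v_peak        # minimum-jerk peak-velocity ratio
      idx <- which(t_hi >= tm & t_hi < tm + dur)
      if (length(idx) > 0) {
        s <- (t_hi[idx] - tm) / dur
        prof <- 10 * s^3 - 15 * s^4 + 6 * s^5
        x[idx] <- pos[1] + (target[1] - pos[1]) * prof
        y[idx] <- pos[2] + (target[2] - pos[2]) * prof
      }
      sacc[[length(sacc) + 1]] <- tibble(
        onset_s = tm, duration_ms = dur * 1000, amplitude_deg = amp,
        peak_velocity_deg_s = v_peak)
      tm <- tm + dur
      pos <- target
    }
    saccades <- if (length(sacc)) list_rbind(sacc) else
      tibble(onset_s = numeric(), duration_ms = numeric(),
             amplitude_deg = numeric(), peak_velocity_deg_s = numeric())
    fixations <- list_rbind(fixs)

    # EOG channels: calibrated gaze plus noise
    eog_h <- x * calib_uv_per_deg + rnorm(n_hi, sd = eog_noise_uv)
    eog_v <- y * calib_uv_per_deg + rnorm(n_hi, sd = eog_noise_uv)

    # gaze / pupil at the eye-tracker rate
    keep <- seq(1, n_hi, by = round(eog_rate_hz / gaze_rate_hz))
    t_lo <- t_hi[keep]
    gx <- x[keep] + rnorm(length(keep), sd = gaze_noise_deg)
    gy <- y[keep] + rnorm(length(keep), sd = gaze_noise_deg)
    pupil_mean_at <- function(tmv) {
      i <- findInterval(tmv, truth$t_start_s)
      truth$pupil_mean[pmax(1, i)]
    }
    pupil <- pupil_mean_at(t_lo) + 0.1 * sin(2 * pi * 0.05 * t_lo) +
      rnorm(length(keep), sd = pupil_noise_mm)

    if (blink_rate_hz > 0) {
      n_blinks <- stats::rpois(1, blink_rate_hz * duration_s)
      blink_t <- sort(runif(n_blinks, 1, duration_s - 1))
      for (bt in blink_t) {
        bi <- which(t_hi >= bt & t_hi < bt + 0.2)
        eog_v[bi] <- eog_v[bi] +
          150 * sin(pi * (t_hi[bi] - bt) / 0.2)^2
        pi_lo <- which(t_lo >= bt & t_lo < bt + 0.15)
        pupil[pi_lo] <- NA_real_
      }
    }

    list(
      eog_h = wl_recording(eog_h, eog_rate_hz, "eog_h", "eog_h"),
      eog_v = wl_recording(eog_v, eog_rate_hz, "eog_v", "eog_v"),
      gaze = wl_recording(cbind(gx, gy), gaze_rate_hz, "gaze",
                          c("gaze_x", "gaze_y")),
      pupil = wl_recording(pupil, gaze_rate_hz, "pupil", "pupil"),
      saccades = saccades, fixations = fixations
    )
  })
}

#' Simulate block-level behavioural performance measures
#'
#' Per-block reaction time is lognormal around the ground-truth mean (which
#' decreases over task sessions and increases under the hard condition) and
#' accuracy is the binomial proportion of correct responses at the block's
#' `accuracy_prob`.
#'
#' @param truth ground-truth tibble (any number of subjects/recordings).
#' @param n_trials trials per block for the accuracy proportion.
#' @param rt_sdlog lognormal shape parameter of reaction times.
#' @param subject_sd SD of a lognormal per-subject reaction-time offset
#'   (random intercept heterogeneity).
#' @param seed integer seed.
#' @return a long feature table: one `perf.reaction_time` and one
#'   `perf.accuracy` row per block.
#' @export
simulate_behavior <- function(truth, n_trials = 20, rt_sdlog = 0.2,
                              subject_sd = 0.1, seed = 1) {
  with_seed(child_seed(seed, "behavior"), {
    subjects <- unique(truth$subject_id)
    offs <- setNames(rnorm(length(subjects), sd = subject_sd), subjects)
    rt <- rlnorm(nrow(truth),
                 meanlog = log(truth$reaction_time_mean) +
                   offs[truth$subject_id] - rt_sdlog^2 / 2,
                 sdlog = rt_sdlog)
    acc <- rbinom(nrow(truth), n_trials, truth$accuracy_prob) / n_trials
    base <- truth |>
      select("subject_id", "task_name", "task_session", "condition",
             "block_index")
    bind_rows(
      mutate(base, modality = "performance",
             measure_name = "perf.reaction_time", value = rt),
      mutate(base, modality = "performance",
             measure_name = "perf.accuracy", value = acc)
    )
  })
}
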