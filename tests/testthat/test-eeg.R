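test_that("notch filter suppresses the line tone and passes neighbours", {
  tone60 <- tone_recording(60, 500)
  out <- notch_filter(tone60)
  expect_lt(sd(central(out$samples[, 1])) / sd(central(tone60$samples[, 1])),
            0.01)
  tone10 <- tone_recording(10, 500)
  expect_equal(sd(central(notch_filter(tone10)$samples[, 1])) /
                 sd(central(tone10$samples[, 1])), 1, tolerance = 0.05)
  zero <- wl_recording(rep(0, 5000), 500, "eeg")
  expect_equal(max(abs(notch_filter(zero)$samples)), 0)
  slow <- wl_recording(rep(0, 100), 100, "eeg")
  expect_error(notch_filter(slow), "Nyquist")
})

test_that("band-pass attenuates drift, removes DC, and passes mid-band", {
  drift <- tone_recording(0.1, 500, dur_s = 60)
  atten <- sd(central(bandpass_filter(drift)$samples[, 1])) /
    sd(central(drift$samples[, 1]))
  expect_lt(20 * log10(atten), -20)
  tone10 <- tone_recording(10, 500)
  expect_equal(sd(central(bandpass_filter(tone10)$samples[, 1])) /
                 sd(central(tone10$samples[, 1])), 1, tolerance = 0.05)
  dc <- wl_recording(rep(3, 5000), 500, "eeg")
  expect_equal(mean(central(bandpass_filter(dc)$samples[, 1])), 0,
               tolerance = 0.02)
})

test_that("Welch band powers localise tones and respect Parseval", {
  tone10 <- tone_recording(10, 500)
  bp <- welch_bandpower(tone10)
  agg <- bp |>
    dplyr::group_by(band) |>
    dplyr::summarise(p = mean(power))
  expect_gt(agg$p[agg$band == "alpha"] / sum(agg$p), 0.90)
  # equal-amplitude 6 Hz + 20 Hz tones split power evenly theta vs beta
  t <- (0:9999) / 500
  mix <- wl_recording(sin(2 * pi * 6 * t) + sin(2 * pi * 20 * t), 500, "eeg")
  agg2 <- welch_bandpower(mix) |>
    dplyr::group_by(band) |>
    dplyr::summarise(p = mean(power))
  expect_equal(agg2$p[agg2$band == "theta"], agg2$p[agg2$band == "beta"],
               tolerance = 0.1)
  zero <- wl_recording(rep(0, 2000), 500, "eeg")
  expect_equal(sum(welch_bandpower(zero)$power), 0)
  # tone power integrates to ~A^2/2 and band sum stays below total power
  expect_equal(sum(agg$p), 0.5, tolerance = 0.02)
  expect_error(welch_bandpower(tone10, bands = tibble::tibble(
    band = "x", lo_hz = 200, hi_hz = 300)), "Nyquist")
})

test_that("ratio indices follow their definitions", {
  bp <- tidyr::expand_grid(channel = "E01", t_s = c(0, 1),
                           band = c("delta", "theta", "alpha", "beta",
                                    "gamma"))
  bp$power <- 1
  r <- ratio_features(bp)
  expect_equal(r$power[r$band == "engagement"], c(0.5, 0.5))
  expect_equal(r$power[r$band == "theta_alpha"], c(1, 1))
  expect_equal(r$power[r$band == "theta_beta"], c(1, 1))
  expect_equal(r$power[r$band == "ta_ba"], c(1, 1))
  bp2 <- bp
  bp2$power[bp2$band == "beta"] <- 2
  r2 <- ratio_features(bp2)
  expect_equal(r2$power[r2$band == "engagement"], c(1, 1))
  # ratios computed from an actual 10 Hz tone PSD: theta/alpha near zero,
  # engagement equals beta over (alpha + theta) from the integrated powers
  tone10 <- tone_recording(10, 500)
  bp3 <- welch_bandpower(tone10)
  r3 <- ratio_features(bp3)
  w <- tidyr::pivot_wider(bp3, names_from = band, values_from = power)
  expect_equal(mean(r3$power[r3$band == "theta_alpha"]),
               mean(w$theta / w$alpha), tolerance = 1e-9)
  expect_lt(mean(r3$power[r3$band == "theta_alpha"]), 0.01)
  # zero denominators are emitted missing
  bp4 <- bp
  bp4$power[bp4$band %in% c("theta", "alpha")] <- 0
  r4 <- ratio_features(bp4)
  expect_true(all(is.na(r4$power[r4$band == "theta_alpha"])))
})

test_that("EOG artifact removal strips a constructed contamination", {
  set.seed(4)
  n <- 5000
  clean <- matrix(rnorm(3 * n), n, 3)
  eog1 <- cumsum(rnorm(n)); eog1 <- eog1 / sd(eog1)
  eog2 <- cumsum(rnorm(n)); eog2 <- eog2 / sd(eog2)
  mixed <- clean + cbind(4 * eog1, -3 * eog1 + 2 * eog2, 2 * eog2)
  rec <- wl_recording(mixed, 500, "eeg")
  rh <- wl_recording(eog1, 500, "eog_h")
  rv <- wl_recording(eog2, 500, "eog_v")
  out <- remove_ocular_artifacts(rec, rh, rv, method = "regression")
  expect_lt(max(abs(cor(out$samples, cbind(eog1, eog2)))), 0.2)
  # the component route needs the threshold below the rotation loss of a
  # two-source contamination spread over the principal directions
  outc <- remove_ocular_artifacts(rec, rh, rv, method = "component",
                                  threshold = 0.5)
  expect_lt(max(abs(cor(outc$samples, cbind(eog1, eog2)))), 0.2)
  # zero EOG reference leaves the signal untouched
  zero <- wl_recording(rep(0, n), 500, "eog_h")
  expect_equal(remove_ocular_artifacts(rec, zero, zero)$samples,
               rec$samples)
  # degenerate threshold removes nothing
  same <- remove_ocular_artifacts(rec, rh, rv, method = "component",
                                  threshold = 1.0)
  expect_equal(same$samples, rec$samples, tolerance = 1e-8,
               ignore_attr = TRUE)
  bad <- wl_recording(rep(0, 10), 500, "eog_h")
  expect_error(remove_ocular_artifacts(rec, bad, bad), "length")
})

test_that("ASR shrinks an injected burst and is inert otherwise", {
  set.seed(5)
  n <- 30 * 500
  x <- matrix(rnorm(n * 4), n, 4)
  rec <- wl_recording(x, 500, "eeg")
  out <- asr_clean(rec, c(0, 20))
  expect_equal(out$samples[1:5000, ], rec$samples[1:5000, ],
               tolerance = 1e-6)

  burst <- x
  idx <- 11000:11500
  burst[idx, 1:3] <- burst[idx, 1:3] * 50
  brec <- wl_recording(burst, 500, "eeg")
  cleaned <- asr_clean(brec, c(0, 20), cutoff_sd = 5)
  expect_gt(var(as.numeric(burst[idx, 1:3])) /
              var(as.numeric(cleaned$samples[idx, 1:3])), 10)
  quiet <- 2000:7000
  expect_equal(cleaned$samples[quiet, ], burst[quiet, ], tolerance = 0.05,
               ignore_attr = TRUE)
  # infinite cutoff is the identity
  ident <- asr_clean(brec, c(0, 20), cutoff_sd = Inf)
  expect_equal(ident$samples, brec$samples)
  expect_error(asr_clean(rec, c(0, 5)), "10 s")
})

test_that("the EEG chain emits 32 x 9 = 288 measures per block", {
  gt <- two_block_truth(dur = 20, gap = 10)
  sim <- simulate_eeg(gt, seed = 2)
  feats <- eeg_features(sim, gt)
  expect_equal(dplyr::n_distinct(feats$measure_name), 288)
  expect_equal(nrow(feats), 288 * nrow(gt))
})
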