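test_that("null fNIRS forward model yields constant intensity", {
  gt <- two_block_truth()
  gt$hemo_amplitude <- 0
  sim <- simulate_fnirs(gt, n_optodes = 2, noise_sd = 0, physio_amp = 0,
                        seed = 2)
  expect_equal(sd(sim$i730$samples[, 1]), 0)
  expect_equal(sd(sim$i850$samples[, 2]), 0)
})

test_that("fNIRS simulate/invert round trip recovers block amplitudes", {
  gt <- two_block_truth()
  sim <- simulate_fnirs(gt, n_optodes = 2, noise_sd = 0, physio_amp = 0,
                        seed = 2)
  hemo <- mbll(sim$i730, sim$i850, c(0, min(gt$t_start_s)))
  t <- rec_times(hemo$HbO)
  for (b in seq_len(nrow(gt))) {
    idx <- t >= gt$t_start_s[b] & t < gt$t_end_s[b]
    peak <- max(hemo$HbO$samples[idx, 1])
    expect_lt(abs(peak - gt$hemo_amplitude[b]) / gt$hemo_amplitude[b], 0.05)
    # HbR is generated at -1/3 of HbO
    trough <- min(hemo$HbR$samples[idx, 1])
    expect_lt(abs(trough + gt$hemo_amplitude[b] / 3) /
                (gt$hemo_amplitude[b] / 3), 0.05)
  }
})

test_that("simulators are bit-reproducible and seeds differentiate noise", {
  gt <- two_block_truth(dur = 10, gap = 5)
  a <- simulate_fnirs(gt, n_optodes = 2, seed = 9)
  b <- simulate_fnirs(gt, n_optodes = 2, seed = 9)
  expect_identical(a$i730$samples, b$i730$samples)
  expect_false(identical(
    a$i730$samples,
    simulate_fnirs(gt, n_optodes = 2, seed = 10)$i730$samples))

  e1 <- simulate_eeg(gt, n_channels = 2, seed = 4)
  expect_identical(e1$samples, simulate_eeg(gt, n_channels = 2,
                                            seed = 4)$samples)
  c1 <- simulate_cardiac(gt, seed = 4)
  c2 <- simulate_cardiac(gt, seed = 4)
  expect_identical(c1$ecg$samples, c2$ecg$samples)
  expect_identical(c1$rpeak_times_s, c2$rpeak_times_s)
  o1 <- simulate_ocular(gt, seed = 4)
  o2 <- simulate_ocular(gt, seed = 4)
  expect_identical(o1$gaze$samples, o2$gaze$samples)
  expect_identical(o1$saccades, o2$saccades)
})

test_that("EEG generator scales band power and is silent when zeroed", {
  gt <- two_block_truth(dur = 20, gap = 5)
  gt[paste0("scale_", c("delta", "theta", "alpha", "beta", "gamma"))] <- 0
  sim <- simulate_eeg(gt, n_channels = 2, pink_amp_uV = 0, line_amp_uV = 0,
                      seed = 3)
  expect_equal(max(abs(sim$samples)), 0)

  gt2 <- two_block_truth(dur = 30, gap = 10)
  gt2$scale_alpha <- ifelse(gt2$condition == "hard", 2, 1)
  sim2 <- simulate_eeg(gt2, n_channels = 2, pink_amp_uV = 0,
                       line_amp_uV = 0, seed = 5)
  bp <- welch_bandpower(sim2)
  blocks <- purrr::map_dbl(seq_len(nrow(gt2)), function(b) {
    sel <- dplyr::filter(bp, band == "alpha", t_s >= gt2$t_start_s[b],
                         t_s + 2 <= gt2$t_end_s[b])
    mean(sel$power)
  })
  ratio <- blocks[gt2$condition == "hard"] / blocks[gt2$condition == "easy"]
  expect_lt(abs(ratio - 2), 0.2)
})

test_that("EEG generator rejects unknown band scales", {
  gt <- two_block_truth(dur = 10, gap = 5)
  gt$scale_alpha <- NULL
  expect_error(simulate_eeg(gt, n_channels = 1, seed = 1), "scale_")
})

test_that("constant RR produces one template peak per interval", {
  gt <- two_block_truth(dur = 20, gap = 5)
  gt$mean_rr <- 1000
  sim <- simulate_cardiac(gt, rr_mod_sd = 0, rr_jitter_sd = 0,
                          duration_s = 61, seed = 2)
  expect_equal(diff(range(diff(sim$rpeak_times_s))), 0, tolerance = 1e-9)
  # exactly one beat per second of simulated minute
  expect_equal(sum(sim$rpeak_times_s < 60.5), 60)
})

test_that("RR LF/HF modulation ratio is recovered from the true beat times", {
  gt <- two_block_truth()
  gt$rr_lf_hf_ratio <- 2
  sim <- simulate_cardiac(gt, rr_jitter_sd = 0, duration_s = 360, seed = 6)
  beats <- detect_rpeaks(sim$ecg)
  sp <- rr_spectrum(beats)
  expect_lt(abs(sp$lf_hf - 2) / 2, 0.2)
})

test_that("zero saccade rate yields a single fixation and no saccades", {
  gt <- two_block_truth(dur = 10, gap = 5)
  gt$saccade_rate <- 0
  sim <- simulate_ocular(gt, blink_rate_hz = 0, seed = 2)
  expect_equal(nrow(sim$saccades), 0)
  expect_equal(nrow(sim$fixations), 1)
})

test_that("simulated saccades follow the main-sequence monotonicity", {
  gt <- two_block_truth()
  sim <- simulate_ocular(gt, seed = 7)
  s <- dplyr::arrange(sim$saccades, amplitude_deg)
  expect_true(all(diff(s$peak_velocity_deg_s) >= 0))
})

test_that("behavioural generator injects the configured condition contrast", {
  gt <- two_block_truth()
  expect_true(all(gt$accuracy_prob[gt$condition == "hard"] <
                    gt$accuracy_prob[gt$condition == "easy"]))
  beh <- simulate_behavior(gt, seed = 3)
  expect_identical(beh, simulate_behavior(gt, seed = 3))
  expect_equal(nrow(beh), 2 * nrow(gt))
  expect_setequal(unique(beh$measure_name),
                  c("perf.reaction_time", "perf.accuracy"))
})
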