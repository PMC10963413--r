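# build an EOG pair containing minimum-jerk horizontal saccades at given
# onset times and amplitudes (deg), 10 uV/deg calibration
make_eog_saccades <- function(onsets, amps, dur_s = 10, fs = 500,
                              noise_uv = 1, seed = 1) {
  set.seed(seed)
  t <- (seq_len(dur_s * fs) - 1) / fs
  x <- numeric(length(t))
  pos <- 0
  for (i in seq_along(onsets)) {
    a <- amps[i]
    vp <- 500 * (1 - exp(-a / 15))
    d <- 1.875 * a / vp
    s <- pmin(pmax((t - onsets[i]) / d, 0), 1)
    x <- x + a * (10 * s^3 - 15 * s^4 + 6 * s^5)
  }
  h <- wl_recording(x * 10 + rnorm(length(t), sd = noise_uv), fs, "eog_h")
  v <- wl_recording(rnorm(length(t), sd = noise_uv), fs, "eog_v")
  list(h = h, v = v)
}

test_that("pure noise produces essentially no saccade detections", {
  set.seed(2)
  h <- wl_recording(rnorm(500 * 60, sd = 2), 500, "eog_h")
  v <- wl_recording(rnorm(500 * 60, sd = 2), 500, "eog_v")
  ev <- detect_saccades_eog(h, v)
  expect_lt(nrow(ev) / 60, 0.1)
})

test_that("a single 10 degree saccade is detected with accurate amplitude", {
  eog <- make_eog_saccades(5, 10)
  ev <- detect_saccades_eog(eog$h, eog$v)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$amplitude_deg - 10) / 10, 0.1)
  expect_lt(abs(ev$onset_s - 5), 0.05)
  # peak velocity is at least amplitude over duration (event invariant)
  expect_gte(ev$peak_velocity_deg_s,
             ev$amplitude_deg / (ev$duration_ms / 1000))
})

test_that("two saccades 500 ms apart are both detected in order", {
  eog <- make_eog_saccades(c(4, 4.5), c(8, 6))
  ev <- detect_saccades_eog(eog$h, eog$v)
  expect_equal(nrow(ev), 2)
  expect_true(all(diff(ev$onset_s) > 0))
  expect_lt(abs(ev$amplitude_deg[1] - 8) / 8, 0.15)
  expect_lt(abs(ev$amplitude_deg[2] - 6) / 6, 0.15)
})

test_that("saccade block features are arithmetic means over the interval", {
  ev <- tibble::tibble(
    onset_s = c(1, 2, 10), duration_ms = c(40, 60, 80),
    amplitude_deg = c(5, 7, 9), peak_velocity_deg_s = c(200, 300, 400),
    source = "eog")
  one <- saccade_block_features(ev[1, ], c(0, 5))
  expect_equal(one$peak_velocity_mean, 200)
  expect_equal(one$duration_mean, 40)
  expect_equal(one$amplitude_mean, 5)
  both <- saccade_block_features(ev, c(0, 5))
  expect_equal(both$amplitude_mean, 6)
  expect_equal(both$peak_velocity_mean, 250)
  empty <- saccade_block_features(ev, c(20, 30))
  expect_true(all(is.na(empty)))
})

test_that("I-DT finds fixations and rejects fast alternation", {
  fs <- 60
  static <- wl_recording(cbind(rep(1, fs), rep(-2, fs)), fs, "gaze",
                         c("gaze_x", "gaze_y"))
  det <- detect_fixations(static)
  expect_equal(nrow(det$fixations), 1)
  expect_equal(det$fixations$duration_ms, 1000, tolerance = 20)

  # alternation between two points 5 degrees apart every 50 ms
  alt_x <- rep(c(0, 5), each = 3, length.out = 600)
  alt <- wl_recording(cbind(alt_x, rep(0, 600)), fs, "gaze",
                      c("gaze_x", "gaze_y"))
  expect_equal(nrow(detect_fixations(alt)$fixations), 0)
})

test_that("a synthetic scanpath is recovered with accurate centroids", {
  fs <- 60
  pts <- cbind(c(0, 4, -3, 2, 6, -5, 1), c(0, 2, 5, -4, -1, 3, 6))
  x <- c(); y <- c()
  for (i in seq_len(nrow(pts))) {
    x <- c(x, rep(pts[i, 1], 30))   # 500 ms fixations
    y <- c(y, rep(pts[i, 2], 30))
  }
  set.seed(3)
  gaze <- wl_recording(cbind(x + rnorm(length(x), sd = 0.05),
                             y + rnorm(length(y), sd = 0.05)), fs, "gaze",
                       c("gaze_x", "gaze_y"))
  det <- detect_fixations(gaze)
  expect_equal(nrow(det$fixations), 7)
  for (i in 1:7) {
    expect_lt(sqrt((det$fixations$x_deg[i] - pts[i, 1])^2 +
                     (det$fixations$y_deg[i] - pts[i, 2])^2), 0.5)
  }
  expect_equal(nrow(det$saccades), 6)
})

test_that("gaze block features equal brute-force recomputation", {
  fs <- 60
  pupil <- wl_recording(rep(4, 10 * fs), fs, "pupil", "pupil")
  fx <- tibble::tibble(onset_s = c(1, 3), duration_ms = c(900, 800),
                       x_deg = c(0, 3), y_deg = c(0, 0),
                       dispersion_deg = 0.2)
  sc <- tibble::tibble(onset_s = c(1.9, 4.2), duration_ms = c(100, 50),
                       amplitude_deg = c(3, 2),
                       peak_velocity_deg_s = c(150, 120), source = "gaze")
  f <- gaze_block_features(fx, sc, pupil, c(0, 10))
  expect_equal(f$pupil_diameter_mean, 4)
  expect_equal(f$saccade_velocity_mean, 135)
  expect_equal(f$saccade_length_mean, 2.5)
  expect_equal(f$fixation_count, 2)
  expect_equal(f$fixation_duration_mean, 850)
  expect_equal(f$fixation_rate_per_s, 0.2)
  expect_equal(f$fixation_saccade_ratio, (0.9 + 0.8) / 0.15)

  # one 900 ms fixation plus one 100 ms saccade in one second
  f2 <- gaze_block_features(fx[1, ], sc[1, ], pupil, c(1, 2))
  expect_equal(f2$fixation_saccade_ratio, 9)
  expect_equal(f2$fixation_rate_per_s, 1)
  # no saccade time -> missing ratio
  f3 <- gaze_block_features(fx[1, ], sc[0, ], pupil, c(1, 2))
  expect_true(is.na(f3$fixation_saccade_ratio))
})

test_that("pupil blinks are interpolated up to 500 ms and excluded beyond", {
  fs <- 60
  p <- rep(4, 10 * fs)
  p[121:139] <- NA            # ~317 ms blink
  p[301:400] <- NA            # ~1.7 s dropout
  rec <- wl_recording(p, fs, "pupil", "pupil")
  f <- gaze_block_features(tibble::tibble(onset_s = numeric(),
                                          duration_ms = numeric(),
                                          x_deg = numeric(),
                                          y_deg = numeric(),
                                          dispersion_deg = numeric()),
                           workloadr:::empty_saccades("gaze"),
                           rec, c(0, 10))
  expect_equal(f$pupil_diameter_mean, 4)
})

test_that("detected amplitudes preserve main-sequence ordering on synthetic data", {
  gt <- two_block_truth()
  sim <- simulate_ocular(gt, seed = 8)
  ev <- detect_saccades_eog(sim$eog_h, sim$eog_v)
  tr <- dplyr::filter(sim$saccades, amplitude_deg >= 2)
  m <- match_events(ev$onset_s, tr$onset_s, tol_s = 0.05)
  hit <- m$err < 0.05
  expect_gt(cor(ev$amplitude_deg[m$idx][hit], tr$amplitude_deg[hit],
                method = "spearman"), 0.9)
})

test_that("the ocular chain emits 3 EOG and 7 eye-tracking measures", {
  gt <- two_block_truth(dur = 15, gap = 10)
  sim <- simulate_ocular(gt, seed = 2)
  feats <- ocular_features(sim$eog_h, sim$eog_v, sim$gaze, sim$pupil, gt)
  eog <- dplyr::filter(feats, modality == "eog")
  eye <- dplyr::filter(feats, modality == "eye")
  expect_equal(dplyr::n_distinct(eog$measure_name), 3)
  expect_equal(dplyr::n_distinct(eye$measure_name), 7)
})
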