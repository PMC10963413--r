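# Shared fixtures: small designs, truths and tone recordings, all built in
# code at test time.

tiny_design <- function(task = "SituationAwareness", session = 1, seed = 3,
                        subject = "S01") {
  block_design(subject, task, session, seed = seed)
}

tiny_truth <- function(task = "SituationAwareness", session = 1, seed = 3,
                       effects = wl_effects()) {
  generate_ground_truth(tiny_design(task, session, seed), effects)
}

# two-block design (one easy, one hard) for fast signal-level tests
two_block_truth <- function(dur = 30, gap = 10, lead = 30,
                            effects = wl_effects()) {
  d <- tibble::tibble(
    subject_id = "S01", task_name = "WorkingMemory", task_session = 1L,
    condition = c("easy", "hard"), block_index = 1:2,
    t_start_s = c(lead, lead + dur + gap),
    t_end_s = c(lead + dur, lead + 2 * dur + gap)
  )
  generate_ground_truth(d, effects)
}

tone_recording <- function(freq_hz, fs, dur_s = 20, amp = 1,
                           modality = "eeg") {
  t <- (seq_len(round(fs * dur_s)) - 1) / fs
  wl_recording(amp * sin(2 * pi * freq_hz * t), fs, modality)
}

# central portion of a signal (avoids zero-phase filter edge transients)
central <- function(x) {
  n <- length(x)
  x[(n %/% 4):(3 * n %/% 4)]
}

# greedy matching of detected event times against ground truth
match_events <- function(detected, truth, tol_s) {
  if (length(detected) == 0 || length(truth) == 0) {
    return(list(recall = 0, idx = integer(0)))
  }
  d <- outer(detected, truth, function(a, b) abs(a - b))
  nearest <- apply(d, 2, min)
  idx <- apply(d, 2, which.min)
  list(recall = mean(nearest < tol_s), idx = idx, err = nearest)
}
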