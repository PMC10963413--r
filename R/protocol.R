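#' Task battery constants
#'
#' The six cognitive-domain tasks of the protocol. Each subject performs four
#' of the six tasks in each of the first three weekly sessions and all six in
#' the final session, so every task is seen in exactly three sessions.
#' @export
wl_tasks <- function() {
  c("WorkingMemory", "Vigilance", "RiskAssessment",
    "ShiftingAttention", "SituationAwareness", "InhibitoryControl")
}

# per-task block layout: n easy + n hard blocks, block duration (s), gap (s),
# and whether blocks run contiguously (the vigilance run is one 5-min sweep
# split into 8 segments, first four low-workload, last four high-workload)
task_block_spec <- function(task) {
  switch(task,
    WorkingMemory      = list(n_easy = 3, n_hard = 3, dur = 40, gap = 15, contiguous = FALSE),
    RiskAssessment     = list(n_easy = 3, n_hard = 3, dur = 40, gap = 15, contiguous = FALSE),
    InhibitoryControl  = list(n_easy = 3, n_hard = 3, dur = 40, gap = 15, contiguous = FALSE),
    ShiftingAttention  = list(n_easy = 3, n_hard = 3, dur = 30, gap = 15, contiguous = FALSE),
    SituationAwareness = list(n_easy = 2, n_hard = 2, dur = 30, gap = 15, contiguous = FALSE),
    Vigilance          = list(n_easy = 4, n_hard = 4, dur = 37.5, gap = 0, contiguous = TRUE),
    abort(paste0("unknown task: ", task))
  )
}

#' Generate counterbalanced multi-session protocol schedules
#'
#' Assigns tasks to sessions for each subject: sessions 1-3 hold four of the
#' six tasks each (so each task skips exactly one early session) and session 4
#' holds all six. The task-to-skipped-session assignment is rotated across
#' subjects for counterbalancing, and the within-session task order is
#' shuffled pseudo-randomly.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param seed integer seed; schedules are deterministic given the seed.
#' @return a tibble with columns `subject_id`, `session` (1-4), `task_name`,
#'   `task_order` (position within the session), and `task_session` (the nth
#'   time this subject sees this task, 1-3).
#' @examples
#' sched <- generate_protocol(2, seed = 7)
#' dplyr::count(sched, subject_id)   # 18 task-sessions per subject
#' @export
generate_protocol <- function(n_subjects, seed = 1) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1 || n_subjects < 1) {
    abort("`n_subjects` must be a positive count.")
  }
  n_subjects <- as.integer(n_subjects)
  tasks <- wl_tasks()
  with_seed(seed, {
    rows <- map(seq_len(n_subjects), function(s) {
      # tasks t and t+3 skip the same early session; the skipped session
      # rotates with the subject index so the assignment is counterbalanced
      skip_by_task <- ((seq_len(6L) - 1L + (s - 1L)) %% 3L) + 1L
      per_session <- map(1:4, function(ses) {
        present <- if (ses == 4L) tasks else tasks[skip_by_task != ses]
        tibble(subject_id = sprintf("S%02d", s), session = ses,
               task_name = sample(present), task_order = seq_along(present))
      })
      list_rbind(per_session)
    })
    sched <- list_rbind(rows)
  })
  sched |>
    group_by(.data$subject_id, .data$task_name) |>
    arrange(.data$session, .by_group = TRUE) |>
    mutate(task_session = row_number()) |>
    ungroup() |>
    arrange(.data$subject_id, .data$session, .data$task_order)
}

#' Lay out the block structure of one task run
#'
#' Produces the block bookkeeping for a single task-session recording: block
#' condition, index, and the `[t_start_s, t_end_s)` interval on the recording
#' clock. A 30 s rest baseline precedes the first block. Most tasks present
#' three blocks per condition in a shuffled interleave; the vigilance run is
#' contiguous with the first half low- and second half high-workload.
#'
#' @param subject_id,task_name,task_session identifiers carried into the rows.
#' @param seed seed controlling the condition interleave.
#' @param lead_in_s rest baseline before the first block (s).
#' @return a tibble with one row per block: `subject_id`, `task_name`,
#'   `task_session`, `condition`, `block_index`, `t_start_s`, `t_end_s`.
#' @export
block_design <- function(subject_id, task_name, task_session = 1, seed = 1,
                         lead_in_s = 30) {
  spec <- task_block_spec(task_name)
  conds <- c(rep("easy", spec$n_easy), rep("hard", spec$n_hard))
  if (!spec$contiguous) {
    conds <- with_seed(seed, sample(conds))
  }
  n <- length(conds)
  starts <- lead_in_s + (seq_len(n) - 1) * (spec$dur + spec$gap)
  tibble(
    subject_id = subject_id, task_name = task_name,
    task_session = as.integer(task_session), condition = conds,
    block_index = seq_len(n),
    t_start_s = starts, t_end_s = starts + spec$dur
  )
}

check_design <- function(design) {
  stopifnot(all(design$t_end_s > design$t_start_s))
  d <- arrange(design, .data$t_start_s)
  if (nrow(d) > 1 && any(d$t_start_s[-1] < d$t_end_s[-nrow(d)])) {
    abort("block intervals overlap within the recording.")
  }
  invisible(design)
}

#' Effect configuration for the synthetic generators
#'
#' Bundles the injected session (learning) and condition (workload) effects
#' that the generators apply on top of per-modality baselines. Session effects
#' are per unit of `task_session - 1`; condition effects apply to hard blocks.
#' Passing `null = TRUE` zeroes every effect (for type-I-error calibration).
#'
#' @param null if `TRUE`, all effects are zero.
#' @param hemo_cond,hemo_sess haemodynamic amplitude shifts (uM).
#' @param alpha_cond multiplicative alpha-band power factor for hard blocks.
#' @param theta_sess multiplicative theta factor per session step.
#' @param rr_cond,rr_sess mean RR shifts (ms).
#' @param lfhf_cond LF/HF ratio shift for hard blocks.
#' @param sacc_amp_cond,sacc_amp_sess saccade amplitude shifts (deg).
#' @param pupil_cond,pupil_sess pupil diameter shifts (mm).
#' @param rt_cond reaction-time shift for hard blocks (s).
#' @param rt_sess_factor multiplicative RT factor per session step (< 1 =
#'   learning).
#' @param acc_cond accuracy log-odds shift for hard blocks.
#' @export
wl_effects <- function(null = FALSE,
                       hemo_cond = 0.4, hemo_sess = -0.08,
                       alpha_cond = 0.8, theta_sess = 1.10,
                       rr_cond = -30, rr_sess = 20,
                       lfhf_cond = 0.5,
                       sacc_amp_cond = -0.6, sacc_amp_sess = 0.4,
                       pupil_cond = 0.3, pupil_sess = -0.15,
                       rt_cond = 0.15, rt_sess_factor = 0.90,
                       acc_cond = -0.6) {
  eff <- list(hemo_cond = hemo_cond, hemo_sess = hemo_sess,
              alpha_cond = alpha_cond, theta_sess = theta_sess,
              rr_cond = rr_cond, rr_sess = rr_sess, lfhf_cond = lfhf_cond,
              sacc_amp_cond = sacc_amp_cond, sacc_amp_sess = sacc_amp_sess,
              pupil_cond = pupil_cond, pupil_sess = pupil_sess,
              rt_cond = rt_cond, rt_sess_factor = rt_sess_factor,
              acc_cond = acc_cond)
  if (null) {
    eff <- map(eff, function(x) 0)
    eff$alpha_cond <- 1; eff$theta_sess <- 1; eff$rt_sess_factor <- 1
  }
  structure(eff, class = "wl_effects")
}

#' Ground-truth block parameters for the simulators
#'
#' Expands a block design into the per-block generative parameters every
#' simulator reads: haemodynamic response amplitude, per-band EEG power
#' scales, mean RR interval and LF/HF balance, saccade statistics, pupil
#' diameter, and behavioural reaction time / accuracy. Injected session and
#' condition effects come from [wl_effects()].
#'
#' @param design a block-design tibble (see [block_design()]).
#' @param effects a [wl_effects()] configuration.
#' @return the design joined with one ground-truth column per parameter; all
#'   scale parameters strictly positive.
#' @export
generate_ground_truth <- function(design, effects = wl_effects()) {
  check_design(design)
  hard <- as.numeric(design$condition == "hard")
  ds <- design$task_session - 1
  tibble(
    design,
    hemo_amplitude = pmax(0.05, 0.6 + effects$hemo_cond * hard +
                            effects$hemo_sess * ds),
    scale_delta = rep(1, nrow(design)),
    scale_theta = effects$theta_sess^ds,
    scale_alpha = 1.2 * ifelse(hard > 0, effects$alpha_cond, 1),
    scale_beta = 1 + 0.1 * hard,
    scale_gamma = rep(1, nrow(design)),
    mean_rr = 850 + effects$rr_cond * hard + effects$rr_sess * ds,
    rr_lf_hf_ratio = 1.5 + effects$lfhf_cond * hard,
    saccade_rate = 2 + 0.5 * hard,
    saccade_amplitude_mean = pmax(0.5, 5 + effects$sacc_amp_cond * hard +
                                    effects$sacc_amp_sess * ds),
    pupil_mean = 4 + effects$pupil_cond * hard + effects$pupil_sess * ds,
    reaction_time_mean = 0.9 * effects$rt_sess_factor^ds +
      effects$rt_cond * hard,
    accuracy_prob = stats::plogis(stats::qlogis(0.85) + effects$acc_cond * hard)
  )
}
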