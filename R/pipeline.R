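#' Simulate the full study design and ground truth
#'
#' Generates the counterbalanced schedule, the per-recording block designs
#' (one recording per subject x task x task-session), and the ground-truth
#' parameters with the configured injected effects.
#'
#' @param n_subjects subjects (the study cohort was 23).
#' @param seed integer seed.
#' @param tasks task subset (default all six).
#' @param effects a [wl_effects()].
#' @return list with `schedule`, `truth` (block design + ground truth, one
#'   row per block over all recordings).
#' @export
wl_simulate_study <- function(n_subjects = 23, seed = 1,
                              tasks = wl_tasks(),
                              effects = wl_effects()) {
  schedule <- generate_protocol(n_subjects, seed = seed) |>
    filter(.data$task_name %in% tasks)
  truth <- schedule |>
    dplyr::rowwise() |>
    dplyr::group_split() |>
    map(function(row) {
      des <- block_design(row$subject_id, row$task_name, row$task_session,
                          seed = child_seed(seed, paste0(row$subject_id,
                                                         row$task_name,
                                                         row$task_session)))
      generate_ground_truth(des, effects)
    }) |>
    list_rbind()
  list(schedule = schedule, truth = truth)
}

# ground truth rows for one recording
recording_truth <- function(truth, subject, task, session) {
  filter(truth, .data$subject_id == subject, .data$task_name == task,
         .data$task_session == session)
}

#' Simulate the six modality recordings for one task run
#'
#' @param truth_rec ground-truth rows of a single recording.
#' @param seed integer seed.
#' @param modalities subset of `c("fnirs", "eeg", "cardiac", "ocular")`.
#' @return named list of recordings and ground-truth event sets.
#' @export
simulate_recording_set <- function(truth_rec, seed = 1,
                                   modalities = c("fnirs", "eeg",
                                                  "cardiac", "ocular")) {
  tag <- paste0(truth_rec$subject_id[1], truth_rec$task_name[1],
                truth_rec$task_session[1])
  out <- list()
  if ("ocular" %in% modalities || "eeg" %in% modalities) {
    out$ocular <- simulate_ocular(truth_rec,
                                  seed = child_seed(seed, paste0(tag, "o")))
  }
  if ("fnirs" %in% modalities) {
    out$fnirs <- simulate_fnirs(truth_rec,
                                seed = child_seed(seed, paste0(tag, "f")))
  }
  if ("eeg" %in% modalities) {
    out$eeg <- simulate_eeg(truth_rec,
                            seed = child_seed(seed, paste0(tag, "e")))
  }
  if ("cardiac" %in% modalities) {
    out$cardiac <- simulate_cardiac(truth_rec,
                                    seed = child_seed(seed, paste0(tag, "c")))
  }
  out
}

#' Extract all block features from one recording set
#'
#' Runs each modality's processing chain in its stated order and returns the
#' combined long feature table for the recording.
#'
#' @param recs list from [simulate_recording_set()] (or recordings read from
#'   disk with the same shape).
#' @param design block design rows of the recording.
#' @return long feature tibble.
#' @export
extract_recording_features <- function(recs, design) {
  parts <- list()
  if (!is.null(recs$fnirs)) {
    parts$fnirs <- fnirs_features(recs$fnirs$i730, recs$fnirs$i850, design)
  }
  if (!is.null(recs$eeg)) {
    eh <- recs$ocular$eog_h; ev <- recs$ocular$eog_v
    if (!is.null(eh) && n_samples(eh) != n_samples(recs$eeg)) {
      eh <- ev <- NULL   # unsynchronized reference; skip removal
    }
    parts$eeg <- eeg_features(recs$eeg, design, eog_h = eh, eog_v = ev)
  }
  if (!is.null(recs$cardiac$ecg)) {
    parts$ecg <- cardiac_features(recs$cardiac$ecg, design)
  }
  if (!is.null(recs$cardiac$ppg)) {
    parts$ppg <- cardiac_features(recs$cardiac$ppg, design)
  }
  if (!is.null(recs$ocular)) {
    parts$ocular <- ocular_features(recs$ocular$eog_h, recs$ocular$eog_v,
                                    recs$ocular$gaze, recs$ocular$pupil,
                                    design)
  }
  list_rbind(parts)
}

#' In-memory end-to-end feature table
#'
#' Simulates recordings and extracts features for every recording of the
#' study (or a subset), appending the behavioural measures. This is the
#' programmatic equivalent of the simulate + extract pipeline stages.
#'
#' @param study list from [wl_simulate_study()].
#' @param seed integer seed.
#' @param modalities modality subset.
#' @param progress print one line per recording.
#' @return long feature tibble.
#' @export
wl_feature_table <- function(study, seed = 1,
                             modalities = c("fnirs", "eeg", "cardiac",
                                            "ocular"),
                             progress = FALSE) {
  recs <- study$truth |>
    distinct(.data$subject_id, .data$task_name, .data$task_session)
  parts <- map(seq_len(nrow(recs)), function(i) {
    tr <- recording_truth(study$truth, recs$subject_id[i],
                          recs$task_name[i], recs$task_session[i])
    if (progress) {
      inform(sprintf("extracting %s %s session %d", recs$subject_id[i],
                     recs$task_name[i], recs$task_session[i]))
    }
    set <- simulate_recording_set(tr, seed = seed, modalities = modalities)
    extract_recording_features(set, tr)
  })
  bind_rows(list_rbind(parts),
            simulate_behavior(study$truth, seed = seed))
}

#' Write a synthetic dataset to disk
#'
#' Writes the recordings (CSV + JSON sidecars), the block design, the ground
#' truth, the behavioural feature table, and a manifest with the seed.
#'
#' @param out_dir output directory.
#' @param n_subjects,seed,tasks,effects passed to [wl_simulate_study()].
#' @param modalities modality subset to write.
#' @param force overwrite an existing non-empty directory.
#' @return `out_dir`, invisibly.
#' @export
wl_simulate_dataset <- function(out_dir, n_subjects = 2, seed = 1,
                                tasks = wl_tasks(),
                                effects = wl_effects(),
                                modalities = c("fnirs", "eeg", "cardiac",
                                               "ocular"),
                                force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force) {
    abort("output directory exists and is not empty; use `force = TRUE`.")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  study <- wl_simulate_study(n_subjects, seed, tasks, effects)
  readr::write_csv(study$schedule, file.path(out_dir, "schedule.csv"))
  jsonlite::write_json(study$truth, file.path(out_dir, "ground_truth.json"),
                       dataframe = "rows", digits = NA)
  readr::write_csv(
    select(study$truth, "subject_id", "task_name", "task_session",
           "condition", "block_index", "t_start_s", "t_end_s"),
    file.path(out_dir, "design.csv"))
  readr::write_csv(simulate_behavior(study$truth, seed = seed),
                   file.path(out_dir, "behavior.csv"))
  recs <- study$truth |>
    distinct(.data$subject_id, .data$task_name, .data$task_session)
  for (i in seq_len(nrow(recs))) {
    tr <- recording_truth(study$truth, recs$subject_id[i],
                          recs$task_name[i], recs$task_session[i])
    set <- simulate_recording_set(tr, seed = seed, modalities = modalities)
    sub_dir <- file.path(out_dir, recs$subject_id[i])
    dir.create(sub_dir, showWarnings = FALSE)
    stem <- file.path(sub_dir, sprintf("%s_s%d", recs$task_name[i],
                                       recs$task_session[i]))
    if (!is.null(set$fnirs)) {
      write_recording(set$fnirs$i730, paste0(stem, "_fnirs730.csv"))
      write_recording(set$fnirs$i850, paste0(stem, "_fnirs850.csv"))
    }
    if (!is.null(set$eeg)) write_recording(set$eeg, paste0(stem, "_eeg.csv"))
    if (!is.null(set$cardiac)) {
      write_recording(set$cardiac$ecg, paste0(stem, "_ecg.csv"))
      write_recording(set$cardiac$ppg, paste0(stem, "_ppg.csv"))
    }
    if (!is.null(set$ocular)) {
      write_recording(set$ocular$eog_h, paste0(stem, "_eog_h.csv"))
      write_recording(set$ocular$eog_v, paste0(stem, "_eog_v.csv"))
      write_recording(set$ocular$gaze, paste0(stem, "_gaze.csv"))
      write_recording(set$ocular$pupil, paste0(stem, "_pupil.csv"))
    }
  }
  manifest <- list(seed = seed, n_subjects = n_subjects, tasks = tasks,
                   modalities = modalities,
                   package = as.character(utils::packageVersion("workloadr")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Extract features from an on-disk dataset
#'
#' @param dataset_dir directory written by [wl_simulate_dataset()].
#' @param out_file optional CSV path for the combined feature table.
#' @return long feature tibble.
#' @export
wl_extract_features <- function(dataset_dir, out_file = NULL) {
  design <- readr::read_csv(file.path(dataset_dir, "design.csv"),
                            show_col_types = FALSE, progress = FALSE)
  man_path <- file.path(dataset_dir, "manifest.json")
  expected <- if (file.exists(man_path)) {
    unlist(jsonlite::read_json(man_path,
                               simplifyVector = TRUE)$modalities)
  } else c("fnirs", "eeg", "cardiac", "ocular")
  files_of <- list(fnirs = c("fnirs730", "fnirs850"), eeg = "eeg",
                   cardiac = c("ecg", "ppg"),
                   ocular = c("eog_h", "eog_v", "gaze", "pupil"))
  expected_files <- unlist(files_of[expected])
  recs <- design |>
    distinct(.data$subject_id, .data$task_name, .data$task_session)
  parts <- map(seq_len(nrow(recs)), function(i) {
    des <- filter(design, .data$subject_id == recs$subject_id[i],
                  .data$task_name == recs$task_name[i],
                  .data$task_session == recs$task_session[i])
    stem <- file.path(dataset_dir, recs$subject_id[i],
                      sprintf("%s_s%d", recs$task_name[i],
                              recs$task_session[i]))
    get <- function(sfx) {
      p <- paste0(stem, "_", sfx, ".csv")
      if (!file.exists(p)) {
        if (sfx %in% expected_files) {
          warn(sprintf("missing %s; modality skipped for this recording",
                       p))
        }
        return(NULL)
      }
      read_recording(p)
    }
    set <- list()
    f730 <- get("fnirs730"); f850 <- get("fnirs850")
    if (!is.null(f730) && !is.null(f850)) {
      set$fnirs <- list(i730 = f730, i850 = f850)
    }
    set$eeg <- get("eeg")
    ecg <- get("ecg"); ppg <- get("ppg")
    if (!is.null(ecg) || !is.null(ppg)) {
      set$cardiac <- list(ecg = ecg, ppg = ppg)
    }
    eh <- get("eog_h"); ev <- get("eog_v")
    gz <- get("gaze"); pu <- get("pupil")
    if (!is.null(eh) && !is.null(ev) && !is.null(gz) && !is.null(pu)) {
      set$ocular <- list(eog_h = eh, eog_v = ev, gaze = gz, pupil = pu)
    }
    extract_recording_features(set, des)
  })
  out <- list_rbind(parts)
  beh_path <- file.path(dataset_dir, "behavior.csv")
  if (file.exists(beh_path)) {
    out <- bind_rows(out, readr::read_csv(beh_path, show_col_types = FALSE,
                                          progress = FALSE))
  }
  if (!is.null(out_file)) readr::write_csv(out, out_file)
  out
}

#' Run the statistical layer on a feature table
#'
#' Fits the per-measure mixed models, applies FDR control, computes the PCA
#' variance partition, and selects report rows.
#'
#' @param table long feature table.
#' @param measures measure subset for the mixed models (default all).
#' @param pca_subset feature subset entering the PCA (default all
#'   non-performance measures).
#' @param alpha significance level.
#' @param n_repeats,seed PCA bootstrap settings.
#' @param out_dir optional directory for `effects.csv`, `report_rows.csv`,
#'   and `pca_summary.json`.
#' @param ... passed to [fit_lmm()].
#' @return list with `effects`, `report_rows`, `pca`.
#' @export
wl_analyze <- function(table, measures = NULL, pca_subset = NULL,
                       alpha = 0.05, n_repeats = 30, seed = 1,
                       out_dir = NULL, ...) {
  if (nrow(table) == 0) abort("empty feature table.")
  effects <- fit_all_lmm(table, measures = measures, alpha = alpha, ...)
  report <- select_report_rows(effects)
  pca_subset <- pca_subset %||%
    unique(table$measure_name[table$modality != "performance"])
  pca <- pca_variance_partition(table, feature_subset = pca_subset,
                                n_repeats = n_repeats, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(effects, file.path(out_dir, "effects.csv"))
    readr::write_csv(report, file.path(out_dir, "report_rows.csv"))
    jsonlite::write_json(
      list(summary = glance(pca), modality_share_pct = tidy(pca)),
      file.path(out_dir, "pca_summary.json"), auto_unbox = TRUE,
      digits = NA, dataframe = "rows")
  }
  list(effects = effects, report_rows = report, pca = pca)
}
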