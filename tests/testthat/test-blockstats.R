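# balanced synthetic feature table for mixed-model tests
lmm_table <- function(n_subjects = 10, n_blocks = 4, cond_shift = 0,
                      sess_shift = 0, subj_sd = 0.5, seed = 1) {
  set.seed(seed)
  grid <- tidyr::expand_grid(
    subject_id = sprintf("S%02d", seq_len(n_subjects)),
    task_session = 1:3, condition = c("easy", "hard"),
    block_index = seq_len(n_blocks))
  subj_eff <- stats::setNames(rnorm(n_subjects, sd = subj_sd),
                              sprintf("S%02d", seq_len(n_subjects)))
  grid |>
    dplyr::mutate(task_name = "X", modality = "performance",
                  measure_name = "m",
                  value = rnorm(dplyr::n()) + subj_eff[subject_id] +
                    cond_shift * (condition == "hard") +
                    sess_shift * (task_session - 2))
}

test_that("partial eta-squared reproduces printed table arithmetic", {
  expect_equal(round(partial_eta_squared(125.63, 1, 374.9), 3), 0.251)
  expect_equal(round(partial_eta_squared(39.59, 2, 380.4), 3), 0.172)
  expect_equal(partial_eta_squared(0, 3, 100), 0)
  expect_error(partial_eta_squared(1, 0, 10), "positive")
  expect_error(partial_eta_squared(-1, 1, 10), "non-negative")
})

test_that("emitted effect rows satisfy the eta-squared identity", {
  tb <- lmm_table(cond_shift = 0.5)
  eff <- tidy(fit_lmm(tb, "m"))
  expect_equal(eff$partial_eta2,
               eff$F * eff$df_num / (eff$F * eff$df_num + eff$df_den),
               tolerance = 1e-6)
  expect_true(all(eff$F >= 0))
  expect_true(all(eff$p >= 0 & eff$p <= 1))
})

test_that("with no subject variance the mixed-model F matches fixed-effects ANOVA", {
  tb <- lmm_table(cond_shift = 0.5, subj_sd = 0, seed = 42)
  fit <- suppressMessages(fit_lmm(tb, "m", engine = "lmer"))
  a <- anova(lm(value ~ factor(task_session) * factor(condition),
                data = tb))
  f_cond <- tidy(fit)$F[tidy(fit)$factor == "condition"]
  expect_equal(f_cond, a["factor(condition)", "F value"],
               tolerance = 0.01)
})

test_that("fit_lmm validates its preconditions", {
  tb <- lmm_table()
  expect_error(fit_lmm(dplyr::filter(tb, subject_id == "S01"), "m"),
               "2 subjects")
  expect_error(fit_lmm(dplyr::filter(tb, condition == "easy"), "m"),
               "conditions")
  tb0 <- tb
  tb0$value <- 1
  expect_error(fit_lmm(tb0, "m"), "zero-variance")
})

test_that("heterogeneous and Satterthwaite engines agree on balanced data", {
  tb <- lmm_table(cond_shift = 0.8, seed = 7)
  f1 <- tidy(fit_lmm(tb, "m", engine = "lme"))
  f2 <- tidy(suppressMessages(fit_lmm(tb, "m", engine = "lmer")))
  expect_equal(f1$F, f2$F, tolerance = 0.15)
  expect_equal(f1$p < 0.05, f2$p < 0.05)
})

test_that("BH step-up flags match the brute-force definition and p.adjust", {
  expect_identical(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(TRUE, 4))
  expect_identical(bh_fdr(c(0.9, 0.8, 0.7)), rep(FALSE, 3))
  expect_identical(bh_fdr(0.001), TRUE)
  expect_identical(bh_fdr(numeric(0)), logical(0))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")

  # independent formulation: the rejection threshold is the largest sorted
  # p-value under its step-up line; everything at or below it is rejected
  brute <- function(p, a = 0.05) {
    m <- length(p)
    ps <- sort(p)
    under <- ps[ps <= seq_len(m) / m * a]
    if (length(under) == 0) return(rep(FALSE, m))
    p <= max(under)
  }
  set.seed(11)
  for (r in 1:300) {
    p <- round(runif(sample(1:12, 1)), 3)  # rounding forces ties
    expect_identical(bh_fdr(p), brute(p))
    expect_identical(bh_fdr(p), p.adjust(p, "BH") <= 0.05)
  }
  # group-wise application is independent per group
  p <- c(0.01, 0.04, 0.2, 0.01, 0.5)
  g <- c("a", "a", "a", "b", "b")
  expect_identical(bh_fdr(p, groups = g),
                   c(bh_fdr(p[1:3]), bh_fdr(p[4:5])))
})

test_that("PCA partition shares are normalized, scale-free, and order the signal", {
  set.seed(1)
  n <- 120
  latentA <- rnorm(n, sd = sqrt(3)); latentB <- rnorm(n)
  meta <- tibble::tibble(
    subject_id = rep(sprintf("S%02d", 1:12), each = 10), task_name = "X",
    task_session = rep(1:2, 60), condition = rep(c("easy", "hard"), 60),
    block_index = rep(1:10, 12))
  mk <- function(latent, mod, noise_sd) {
    purrr::map(1:6, function(j) {
      dplyr::mutate(meta, modality = mod,
                    measure_name = paste0(mod, ".m", j),
                    value = latent + rnorm(n, sd = noise_sd))
    }) |> purrr::list_rbind()
  }
  tb <- dplyr::bind_rows(mk(latentA, "A", 0.4), mk(latentB, "B", 0.7))
  p <- pca_variance_partition(tb, n_repeats = 30, seed = 4)
  expect_equal(sum(tidy(p)$share_pct), 100, tolerance = 0.1)
  wide <- tidyr::pivot_wider(p$per_repeat, names_from = modality,
                             values_from = share_pct)
  expect_true(all(wide$A > wide$B))
  expect_equal(glance(p)$n_repeats, 30)

  # correlation-based: rescaling a feature changes nothing
  tb2 <- dplyr::mutate(tb, value = ifelse(measure_name == "A.m1",
                                          value * 1000, value))
  p2 <- pca_variance_partition(tb2, n_repeats = 5, seed = 4)
  p1 <- pca_variance_partition(tb, n_repeats = 5, seed = 4)
  expect_equal(tidy(p2)$share_pct, tidy(p1)$share_pct, tolerance = 1e-8)

  # row order of the long table does not matter
  p3 <- pca_variance_partition(dplyr::arrange(tb, dplyr::desc(measure_name)),
                               n_repeats = 5, seed = 4)
  expect_equal(dplyr::arrange(tidy(p3), modality),
               dplyr::arrange(tidy(p1), modality), tolerance = 1e-8)
})

test_that("a single informative modality takes essentially all PCA share", {
  set.seed(2)
  n <- 80
  latent <- rnorm(n, sd = 3)
  meta <- tibble::tibble(
    subject_id = rep(sprintf("S%02d", 1:8), each = 10), task_name = "X",
    task_session = 1L, condition = "easy", block_index = rep(1:10, 8))
  tb <- dplyr::bind_rows(
    purrr::map(1:5, function(j) dplyr::mutate(
      meta, modality = "A", measure_name = paste0("A.m", j),
      value = latent + rnorm(n, sd = 0.05))) |> purrr::list_rbind(),
    purrr::map(1:5, function(j) dplyr::mutate(
      meta, modality = "B", measure_name = paste0("B.m", j),
      value = rnorm(n))) |> purrr::list_rbind())
  p <- pca_variance_partition(tb, n_repeats = 10, seed = 3)
  shareA <- tidy(p)$share_pct[tidy(p)$modality == "A"]
  expect_gt(shareA, 60)
  expect_gt(shareA, tidy(p)$share_pct[tidy(p)$modality == "B"])
})

test_that("report-row selection follows the standardized rule", {
  mk_rows <- function(mod, n, factor = "session", sig = TRUE) {
    tibble::tibble(
      measure_name = paste0(mod, ".m", seq_len(n)), factor = factor,
      F = seq_len(n) + 1, df_num = 1, df_den = 100,
      p = ifelse(sig, 0.001, 0.5),
      partial_eta2 = seq_len(n) / (n + 5),
      modality = mod, fdr_group = mod, fdr_significant = sig)
  }
  res <- mk_rows("eeg", 10)
  sel <- select_report_rows(res)
  expect_equal(nrow(sel), 5)
  expect_equal(sel$partial_eta2, sort(res$partial_eta2,
                                      decreasing = TRUE)[1:5])

  # only one factor significant -> all selected rows carry it
  res2 <- dplyr::bind_rows(mk_rows("ecg", 4, "session", sig = TRUE),
                           mk_rows("ecg", 3, "condition", sig = FALSE))
  sel2 <- select_report_rows(res2)
  expect_true(all(sel2$factor == "session"))

  # mixed factors: every significant factor is represented even when one
  # dominates the effect sizes
  res3 <- dplyr::bind_rows(
    mk_rows("fnirs", 6, "session"),
    dplyr::mutate(mk_rows("fnirs", 2, "condition"),
                  partial_eta2 = c(0.01, 0.02),
                  measure_name = paste0("fnirs.c", 1:2)))
  sel3 <- select_report_rows(res3)
  expect_lte(nrow(sel3), 5)
  expect_true("condition" %in% sel3$factor)
  expect_true("session" %in% sel3$factor)
})
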