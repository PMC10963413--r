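#' Partial eta-squared effect size from an F statistic
#'
#' `eta_p^2 = F * df_num / (F * df_num + df_den)`, the effect size printed
#' alongside every mixed-model F test.
#'
#' @param f F statistic (>= 0).
#' @param df_num,df_den numerator and denominator degrees of freedom
#'   (positive; the denominator may be fractional).
#' @return partial eta-squared in `[0, 1)`. Vectorized.
#' @examples
#' partial_eta_squared(125.63, 1, 374.9)  # 0.251
#' @export
partial_eta_squared <- function(f, df_num, df_den) {
  if (any(df_num <= 0) || any(df_den <= 0)) {
    abort("degrees of freedom must be positive.")
  }
  if (any(f < 0)) abort("F statistics must be non-negative.")
  f * df_num / (f * df_num + df_den)
}

#' Fit the block-level linear mixed model for one measure
#'
#' Fixed effects of task session (categorical, up to 3 levels), condition
#' (easy/hard), and their interaction; random intercept per subject; REML.
#' The default engine (`"lme"`) estimates a diagonal residual covariance
#' with heterogeneous variances across session-by-condition cells
#' (`nlme::varIdent`) and reports marginal F tests; if that fit fails to
#' converge it falls back to homogeneous residual variance and flags the
#' result. Engine `"lmer"` fits the homogeneous model with
#' Satterthwaite-approximated (fractional) denominator degrees of freedom.
#'
#' @param table long feature table.
#' @param measure measure name to model.
#' @param engine `"lme"` (heterogeneous diagonal residuals) or `"lmer"`
#'   (Satterthwaite df).
#' @param heterogeneous for the `"lme"` engine, estimate per-cell residual
#'   variances (the diagonal covariance pattern).
#' @return a `wl_lmm` object; `tidy()` gives one row per factor with `F`,
#'   `df_num`, `df_den`, `p`, `partial_eta2`.
#' @export
fit_lmm <- function(table, measure, engine = c("lme", "lmer"),
                    heterogeneous = TRUE) {
  engine <- match.arg(engine)
  d <- table |>
    filter(.data$measure_name == measure, is.finite(.data$value)) |>
    mutate(session = factor(.data$task_session),
           condition = factor(.data$condition, levels = c("easy", "hard")),
           subject = factor(.data$subject_id),
           cell = interaction(.data$task_session, .data$condition))
  # sum-to-zero contrasts so the marginal F tests are genuine main effects
  stats::contrasts(d$session) <- stats::contr.sum(nlevels(d$session))
  stats::contrasts(d$condition) <- stats::contr.sum(nlevels(d$condition))
  if (dplyr::n_distinct(d$subject) < 2) {
    abort("at least 2 subjects are required.")
  }
  if (dplyr::n_distinct(d$condition) < 2 ||
      dplyr::n_distinct(d$session) < 2) {
    abort("both conditions and at least 2 sessions are required.")
  }
  if (sd(d$value) < 1e-12) {
    abort(sprintf("zero-variance response for %s (singular fit).", measure))
  }
  flagged <- FALSE
  if (engine == "lme") {
    ctrl <- nlme::lmeControl(maxIter = 100, msMaxIter = 100, opt = "optim",
                             returnObject = FALSE)
    fit <- NULL
    if (heterogeneous) {
      fit <- tryCatch(
        nlme::lme(value ~ session * condition, random = ~ 1 | subject,
                  weights = nlme::varIdent(form = ~ 1 | cell),
                  data = d, method = "REML", control = ctrl),
        error = function(e) NULL)
      if (is.null(fit)) flagged <- TRUE
    }
    if (is.null(fit)) {
      fit <- nlme::lme(value ~ session * condition, random = ~ 1 | subject,
                       data = d, method = "REML", control = ctrl)
    }
    an <- anova(fit, type = "marginal")
    rows <- c("session", "condition", "session:condition")
    eff <- tibble(
      measure_name = measure,
      factor = c("session", "condition", "interaction"),
      F = an[rows, "F-value"],
      df_num = an[rows, "numDF"],
      df_den = an[rows, "denDF"],
    )
  } else {
    fit <- lmerTest::lmer(value ~ session * condition + (1 | subject),
                          data = d, REML = TRUE)
    an <- suppressMessages(anova(fit, type = 3, ddf = "Satterthwaite"))
    rows <- c("session", "condition", "session:condition")
    eff <- tibble(
      measure_name = measure,
      factor = c("session", "condition", "interaction"),
      F = an[rows, "F value"],
      df_num = an[rows, "NumDF"],
      df_den = an[rows, "DenDF"],
    )
  }
  eff <- eff |>
    mutate(p = pf(.data$F, .data$df_num, .data$df_den, lower.tail = FALSE),
           partial_eta2 = partial_eta_squared(.data$F, .data$df_num,
                                              .data$df_den))
  structure(list(effects = eff, model = fit, engine = engine,
                 heterogeneous = heterogeneous && !flagged,
                 fallback = flagged, n_obs = nrow(d)),
            class = "wl_lmm")
}

#' @export
print.wl_lmm <- function(x, ...) {
  cat(sprintf("<wl_lmm: %s>  engine %s%s, %d obs\n",
              x$effects$measure_name[1], x$engine,
              if (x$heterogeneous) " (heterogeneous residuals)" else "",
              x$n_obs))
  print(x$effects)
  invisible(x)
}

#' @rdname fit_lmm
#' @param x a `wl_lmm`.
#' @param ... unused.
#' @export
tidy.wl_lmm <- function(x, ...) x$effects

#' @rdname fit_lmm
#' @export
glance.wl_lmm <- function(x, ...) {
  tibble(engine = x$engine, heterogeneous = x$heterogeneous,
         fallback = x$fallback, n_obs = x$n_obs,
         logLik = as.numeric(stats::logLik(x$model)))
}

#' Fit mixed models for every measure and apply FDR control
#'
#' Maps [fit_lmm()] over all (or a subset of) measures and applies
#' Benjamini-Hochberg FDR within fNIRS and EEG channel families: all
#' channels of one data type (e.g. every optode's `HbO.peak`, every
#' electrode's `alpha` power) form one group per factor, mirroring the
#' across-optode/electrode correction. Other modalities are assessed at the
#' raw alpha level. Measures whose fit fails are skipped with a message.
#'
#' @param table long feature table.
#' @param measures measure names (default: all in `table`).
#' @param alpha significance level.
#' @param ... passed to [fit_lmm()].
#' @return tibble of effect rows with `fdr_group` and `fdr_significant`.
#' @export
fit_all_lmm <- function(table, measures = NULL, alpha = 0.05, ...) {
  measures <- measures %||% unique(table$measure_name)
  res <- list()
  for (m in measures) {
    fit <- tryCatch(fit_lmm(table, m, ...), error = function(e) {
      inform(sprintf("skipping %s: %s", m, conditionMessage(e)))
      NULL
    })
    if (!is.null(fit)) res[[m]] <- tidy(fit)
  }
  if (length(res) == 0) abort("no measure could be fitted.")
  out <- list_rbind(res)
  mod_of <- table |> distinct(.data$measure_name, .data$modality)
  out <- left_join(out, mod_of, by = "measure_name") |>
    mutate(fdr_group = paste(fdr_family(.data$measure_name,
                                        .data$modality),
                             .data$factor, sep = ":"))
  grouped <- out$modality %in% c("fnirs", "eeg")
  out$fdr_significant <- out$p < alpha
  if (any(grouped)) {
    out$fdr_significant[grouped] <- bh_fdr(out$p[grouped], alpha = alpha,
                                           groups = out$fdr_group[grouped])
  }
  out
}

# channel-collapsed family id: fnirs.HbO.opt02.peak -> fnirs.HbO.peak;
# eeg.alpha.E07 -> eeg.alpha; other modalities keep the full name
fdr_family <- function(measure_name, modality) {
  parts <- stringr::str_split(measure_name, stringr::fixed("."))
  map_chr(seq_along(parts), function(i) {
    p <- parts[[i]]
    if (modality[i] == "fnirs" && length(p) == 4) {
      paste(p[c(1, 2, 4)], collapse = ".")
    } else if (modality[i] == "eeg" && length(p) == 3) {
      paste(p[1:2], collapse = ".")
    } else measure_name[i]
  })
}

#' Benjamini-Hochberg step-up FDR flags, by group
#'
#' Within each group independently, p-values are sorted ascending and the
#' largest rank `i` with `p_(i) <= (i / m) * alpha` is found; all hypotheses
#' at ranks up to `i` are flagged significant. Stable under ties.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @param alpha FDR level.
#' @param groups optional grouping vector partitioning the p-values;
#'   correction is applied within each group.
#' @return logical vector aligned with `p_values`.
#' @export
bh_fdr <- function(p_values, alpha = 0.05, groups = NULL) {
  if (length(p_values) == 0) return(logical(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1].")
  }
  groups <- groups %||% rep(1L, length(p_values))
  out <- logical(length(p_values))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    p <- p_values[idx]
    m <- length(p)
    ord <- order(p)
    ok <- p[ord] <= seq_len(m) / m * alpha
    k <- if (any(ok)) max(which(ok)) else 0L
    flag <- logical(m)
    if (k > 0) flag[ord[seq_len(k)]] <- TRUE
    out[idx] <- flag
  }
  out
}

#' Repeated PCA variance partition across modalities
#'
#' Per repeat, observations (blocks) are bootstrap-resampled, features are
#' z-scored, and the correlation matrix is eigendecomposed. Components with
#' eigenvalues above 1 are retained; the total variance explained is their
#' eigenvalue sum over the feature count, and each modality's share is the
#' eigenvalue-weighted sum of squared loadings of its features over all
#' retained components, normalized across modalities. Means over repeats are
#' reported; per-repeat detail is kept for inspection.
#'
#' @param table long feature table.
#' @param feature_subset optional measure names entering the PCA.
#' @param n_repeats bootstrap repeats.
#' @param seed integer seed.
#' @param impute impute missing cells with the column mean before scaling.
#' @return a `wl_pca_summary`: `summary` (one row), `modality_share_pct`
#'   (one row per modality), `per_repeat` (one row per repeat per modality).
#' @export
pca_variance_partition <- function(table, feature_subset = NULL,
                                   n_repeats = 30, seed = 1,
                                   impute = TRUE) {
  tb <- table
  if (!is.null(feature_subset)) {
    tb <- filter(tb, .data$measure_name %in% feature_subset)
  }
  mod_of <- tb |> distinct(.data$measure_name, .data$modality)
  if (any(table(mod_of$modality) < 2)) {
    abort("need at least 2 features per modality in the PCA subset.")
  }
  wide <- tb |>
    select("subject_id", "task_name", "task_session", "condition",
           "block_index", "measure_name", "value") |>
    tidyr::pivot_wider(names_from = "measure_name",
                       values_from = "value")
  X <- as.matrix(wide[, mod_of$measure_name, drop = FALSE])
  if (impute) {
    for (j in seq_len(ncol(X))) {
      miss <- !is.finite(X[, j])
      if (any(miss)) X[miss, j] <- mean(X[!miss, j])
    }
  }
  keep <- apply(X, 2, sd) > 1e-12
  if (!all(keep)) {
    warn(sprintf("dropping %d zero-variance features from PCA",
                 sum(!keep)))
    X <- X[, keep, drop = FALSE]
    mod_of <- mod_of[keep, ]
  }
  if (ncol(X) > nrow(X)) {
    warn("more features than observations; shares still computed.")
  }
  mods <- mod_of$modality
  reps <- with_seed(child_seed(seed, "pca"), {
    map(seq_len(n_repeats), function(r) {
      rows <- sample(nrow(X), replace = TRUE)
      Z <- X[rows, , drop = FALSE]
      sds <- apply(Z, 2, sd)
      ok <- sds > 1e-12
      Z <- scale(Z[, ok, drop = FALSE])
      dec <- eigen(stats::cor(Z), symmetric = TRUE)
      retained <- which(dec$values > 1)
      lam <- dec$values[retained]
      V <- dec$vectors[, retained, drop = FALSE]
      contrib <- colSums(t(V^2) * lam)        # per-feature weighted loading
      share <- tapply(contrib, mods[ok], sum)
      share <- share / sum(share) * 100
      tibble(repeat_id = r,
             n_components = length(retained),
             total_variance_pct = sum(lam) / ncol(Z) * 100,
             modality = names(share),
             share_pct = as.numeric(share))
    })
  })
  per_repeat <- list_rbind(reps)
  shares <- per_repeat |>
    group_by(.data$modality) |>
    summarise(share_pct = mean(.data$share_pct), .groups = "drop")
  summary <- per_repeat |>
    distinct(.data$repeat_id, .data$n_components,
             .data$total_variance_pct) |>
    summarise(n_components_mean = mean(.data$n_components),
              total_variance_explained_pct =
                mean(.data$total_variance_pct),
              n_repeats = dplyr::n())
  structure(list(summary = summary, modality_share_pct = shares,
                 per_repeat = per_repeat),
            class = "wl_pca_summary")
}

#' @export
print.wl_pca_summary <- function(x, ...) {
  cat(sprintf(
    "<wl_pca_summary> %.1f components (mean), %.1f%% variance, %d repeats\n",
    x$summary$n_components_mean, x$summary$total_variance_explained_pct,
    x$summary$n_repeats))
  print(x$modality_share_pct)
  invisible(x)
}

#' @rdname pca_variance_partition
#' @param x a `wl_pca_summary`.
#' @param ... unused.
#' @export
tidy.wl_pca_summary <- function(x, ...) x$modality_share_pct

#' @rdname pca_variance_partition
#' @export
glance.wl_pca_summary <- function(x, ...) x$summary

#' Standardized report-row selection
#'
#' Applies the reporting rule used for the per-task summary tables: at most
#' five rows per modality, fNIRS and EEG rows must be FDR-significant (other
#' modalities raw-significant), rows sorted by partial eta-squared
#' descending, with at least one row for each factor that has any
#' significant row in that modality.
#'
#' @param results effect tibble from [fit_all_lmm()].
#' @param max_rows per-modality cap.
#' @return the selected rows, ordered by modality then descending effect
#'   size.
#' @export
select_report_rows <- function(results, max_rows = 5) {
  results |>
    group_by(.data$modality) |>
    dplyr::group_modify(function(df, key) {
      sig <- filter(df, .data$fdr_significant)
      if (nrow(sig) == 0) return(sig)
      sig <- arrange(sig, dplyr::desc(.data$partial_eta2))
      # guarantee one row per significant factor before filling by effect size
      first_per_factor <- sig |>
        group_by(.data$factor) |>
        dplyr::slice_head(n = 1) |>
        ungroup()
      rest <- dplyr::anti_join(
        sig, first_per_factor,
        by = c("measure_name", "factor"))
      picked <- bind_rows(
        head(first_per_factor, max_rows),
        head(rest, max(0, max_rows - nrow(first_per_factor))))
      arrange(picked, dplyr::desc(.data$partial_eta2))
    }) |>
    ungroup()
}
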