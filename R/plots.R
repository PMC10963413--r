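#' Plot a recording's channels over time
#'
#' @param object a `wl_recording`.
#' @param channels channel labels to show (default first 4).
#' @param interval optional `[t0, t1)` time window (s).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.wl_recording <- function(object, channels = NULL, interval = NULL,
                                  ...) {
  channels <- channels %||% head(object$channel_labels, 4)
  df <- as_tibble(object) |>
    tidyr::pivot_longer(-"time_s", names_to = "channel",
                        values_to = "value") |>
    filter(.data$channel %in% channels)
  if (!is.null(interval)) {
    df <- filter(df, .data$time_s >= interval[1], .data$time_s < interval[2])
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = object$modality) +
    ggplot2::theme_minimal()
}

#' Plot the PCA variance partition across modalities
#'
#' @param object a `wl_pca_summary`.
#' @param ... unused.
#' @return a ggplot bar chart of mean modality shares.
#' @export
autoplot.wl_pca_summary <- function(object, ...) {
  ggplot2::ggplot(object$modality_share_pct,
                  ggplot2::aes(stats::reorder(.data$modality,
                                              -.data$share_pct),
                               .data$share_pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "explained variance share (%)") +
    ggplot2::theme_minimal()
}

#' Plot effect sizes per modality and factor
#'
#' Dot plot of partial eta-squared for the fitted measures, split by fixed
#' factor and coloured by FDR significance.
#'
#' @param effects effect tibble from [fit_all_lmm()].
#' @return a ggplot.
#' @export
plot_effect_sizes <- function(effects) {
  ggplot2::ggplot(effects,
                  ggplot2::aes(.data$partial_eta2, .data$modality,
                               colour = .data$fdr_significant)) +
    ggplot2::geom_jitter(height = 0.15, width = 0, alpha = 0.6) +
    ggplot2::facet_wrap(~factor) +
    ggplot2::labs(x = expression(partial ~ eta^2), y = NULL,
                  colour = "FDR significant") +
    ggplot2::theme_minimal()
}
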