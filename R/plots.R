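#' @importFrom ggplot2 autoplot
NULL

#' Forest plot of differential-abundance odds ratios
#'
#' @param object `myo_abundance` tibble from [diff_abundance()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.myo_abundance <- function(object, ...) {
  df <- dplyr::arrange(tibble::as_tibble(object), .data$OR)
  df$cluster <- factor(df$cluster, levels = df$cluster)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$OR, y = .data$cluster)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, color = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      height = 0.2, color = "grey40") +
    ggplot2::geom_point(ggplot2::aes(color = .data$significant), size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (case vs control)", y = NULL,
                  color = "FDR < 10%") +
    ggplot2::theme_minimal()
}

#' Hill diversity profile curve
#'
#' @param object `myo_diversity` tibble from [hill_diversity()].
#' @param ... Ignored.
#' @return A ggplot of qD against the diversity order q.
#' @export
autoplot.myo_diversity <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$q, y = .data$qD)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "diversity order q", y = "Hill diversity qD") +
    ggplot2::theme_minimal()
}

#' Normalized clone-proportion scatter for tissue enrichment
#'
#' Heart vs tumor normalized clone proportions (each tissue frequency
#' divided by the control-tissue frequency), colored by enrichment call.
#'
#' @param heart,tumor `myo_enrichment` tibbles for the two tissues.
#' @return A ggplot on log-log axes.
#' @export
plot_enrichment_scatter <- function(heart, tumor) {
  df <- dplyr::full_join(
    dplyr::select(tibble::as_tibble(heart), "clone_key",
                  heart_ratio = "normalized_ratio",
                  heart_enriched = "enriched"),
    dplyr::select(tibble::as_tibble(tumor), "clone_key",
                  tumor_ratio = "normalized_ratio",
                  tumor_enriched = "enriched"),
    by = "clone_key") |>
    tidyr::replace_na(list(heart_ratio = 1, tumor_ratio = 1,
                           heart_enriched = FALSE, tumor_enriched = FALSE)) |>
    dplyr::mutate(call = dplyr::case_when(
      .data$heart_enriched & .data$tumor_enriched ~ "both",
      .data$heart_enriched ~ "heart",
      .data$tumor_enriched ~ "tumor",
      TRUE ~ "neither"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$heart_ratio,
                                   y = .data$tumor_ratio,
                                   color = .data$call)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "normalized heart proportion",
                  y = "normalized tumor proportion",
                  color = "enriched in") +
    ggplot2::theme_minimal()
}

#' Serum analyte comparison plot
#'
#' Log-scale group difference against p-value per analyte.
#'
#' @param object `myo_serum` tibble from [serum_compare()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.myo_serum <- function(object, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      delta = .data$mean_log_case - .data$mean_log_control)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta, y = -log10(.data$p),
                                   color = .data$flagged)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = 2,
                        color = "grey60") +
    ggplot2::labs(x = "difference of mean log(value + 1), case - control",
                  y = "-log10 p", color = "p < 0.05") +
    ggplot2::theme_minimal()
}
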