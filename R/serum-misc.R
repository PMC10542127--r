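#' Serum analyte group comparison
#'
#' Per analyte, values are transformed `x -> ln(x + 1)` and compared
#' between case and control donors with a two-sided t-test (Welch by
#' default). Raw p-values are reported without multiplicity adjustment;
#' `flagged` marks p < 0.05.
#'
#' @param serum_table Tibble: `donor_id`, `group`, `analyte`, `value`
#'   (non-negative).
#' @param case_level Case label in `group`.
#' @param var_equal Use Student's pooled-variance t instead of Welch.
#' @return `myo_serum` tibble: analyte, n_case, n_control, mean_log_case,
#'   mean_log_control, t_stat, p, flagged.
#' @export
serum_compare <- function(serum_table, case_level = "case",
                          var_equal = FALSE) {
  serum_table <- tibble::as_tibble(serum_table)
  if (any(serum_table$value < 0)) {
    stop("negative analyte value(s)", call. = FALSE)
  }
  out <- serum_table |>
    dplyr::mutate(logv = log1p(.data$value),
                  is_case = .data$group == case_level) |>
    dplyr::group_by(.data$analyte) |>
    dplyr::group_modify(function(d, key) {
      a <- d$logv[d$is_case]; b <- d$logv[!d$is_case]
      if (length(a) < 2 || length(b) < 2) {
        stop("need >= 2 donors per group for analyte ", key$analyte,
             call. = FALSE)
      }
      tt <- tryCatch(
        stats::t.test(a, b, var.equal = var_equal),
        error = function(e) NULL)  # both groups constant
      tibble::tibble(
        n_case = length(a), n_control = length(b),
        mean_log_case = mean(a), mean_log_control = mean(b),
        t_stat = if (is.null(tt)) 0 else unname(tt$statistic),
        p = if (is.null(tt)) 1 else tt$p.value)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(flagged = .data$p < 0.05)
  class(out) <- c("myo_serum", class(out))
  out
}

#' Fold comparison of cell densities between regions
#'
#' Ratio of mean densities (cells per 1e5 total cells) between two
#' regions, with a one-sided (greater) two-sample t-test when both
#' regions have at least two samples.
#'
#' @param density_table Tibble: `region`, `density` per sample.
#' @param region_a,region_b Numerator and denominator regions.
#' @return One-row tibble: regions, means, fold_ratio, fold_display
#'   (one decimal), p (one-sided t; NA when untestable).
#' @export
density_fold_compare <- function(density_table, region_a, region_b) {
  a <- density_table$density[density_table$region == region_a]
  b <- density_table$density[density_table$region == region_b]
  if (length(a) < 1 || length(b) < 1) {
    stop("need >= 1 sample per region", call. = FALSE)
  }
  if (mean(b) == 0) {
    return(tibble::tibble(region_a = region_a, region_b = region_b,
                          mean_a = mean(a), mean_b = 0,
                          fold_ratio = NA_real_, fold_display = NA_character_,
                          p = NA_real_,
                          reason = "zero denominator mean"))
  }
  fold <- mean(a) / mean(b)
  p <- if (length(a) >= 2 && length(b) >= 2) {
    tryCatch(stats::t.test(a, b, alternative = "greater")$p.value,
             error = function(e) NA_real_)  # zero-variance degenerate data
  } else NA_real_
  tibble::tibble(
    region_a = region_a, region_b = region_b,
    mean_a = mean(a), mean_b = mean(b),
    fold_ratio = fold,
    fold_display = paste0(format_ratio_display(fold), "-fold"),
    p = p, reason = NA_character_
  )
}
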