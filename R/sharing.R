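#' Flag blood cells carrying heart-expanded clones
#'
#' Marks `myo_clone = 1` on blood cells whose clone key belongs to the
#' same donor's union of bulk- and single-cell-expanded heart clone sets.
#' Matching is strictly within donor; donors without heart expansion data
#' are skipped.
#'
#' @param blood_cells Tibble of blood cells with `donor_id`, `barcode`,
#'   `clone_key` (NA when no TCR was recovered).
#' @param heart_expanded Named list: donor -> character vector of expanded
#'   heart clone keys (bulk and sc sets already unioned).
#' @return `blood_cells` with a `myo_clone` 0/1 column; cells of donors
#'   absent from `heart_expanded` are dropped with a message.
#' @export
mark_heart_expanded_in_blood <- function(blood_cells, heart_expanded) {
  blood_cells <- tibble::as_tibble(blood_cells)
  known <- blood_cells$donor_id %in% names(heart_expanded)
  skipped <- unique(blood_cells$donor_id[!known])
  if (length(skipped)) {
    message("skipping donors without heart expansion data: ",
            paste(skipped, collapse = ", "))
  }
  out <- blood_cells[known, , drop = FALSE]
  out$myo_clone <- as.integer(purrr::map2_lgl(
    out$clone_key, out$donor_id,
    function(key, don) !is.na(key) && key %in% heart_expanded[[don]]))
  out
}

## logistic LRT on the per-donor 2x2 of (in-subset x myo_clone)
subset_lrt <- function(in_subset, flagged) {
  full <- stats::glm(in_subset ~ flagged, family = stats::binomial())
  null <- stats::glm(in_subset ~ 1, family = stats::binomial())
  lrt <- max(0, 2 * (as.numeric(stats::logLik(full)) -
                       as.numeric(stats::logLik(null))))
  beta1 <- unname(stats::coef(full)[2])
  list(beta1 = beta1, lrt = lrt,
       p = stats::pchisq(lrt, df = 1, lower.tail = FALSE))
}

#' Per-donor subset sharing test
#'
#' Within one donor's blood cells, each subset is tested for enrichment of
#' heart-expanded clones with a plain logistic model
#' `in_subset ~ 1 + myo_clone` compared to the intercept-only null by
#' likelihood-ratio test; BH FDR across that donor's subsets, significant
#' at FDR < 5%.
#'
#' @param blood_cells Output of [mark_heart_expanded_in_blood()] for one
#'   donor or many (a `donor_id` column groups the scans).
#' @param fdr_threshold Significance rule (default 0.05).
#' @return `myo_sharing` tibble: donor_id, blood_subset, n_cells_subset,
#'   n_shared_cells_subset, beta1, OR, lrt_p, fdr, significant, unstable,
#'   plus donor-level n_unique_shared_clones and n_total_shared_cells.
#' @export
subset_sharing_test <- function(blood_cells, fdr_threshold = 0.05) {
  blood_cells |>
    dplyr::group_by(.data$donor_id) |>
    dplyr::group_modify(function(d, key) {
      n_flag <- sum(d$myo_clone)
      donor_clones <- length(unique(d$clone_key[d$myo_clone == 1]))
      subsets <- sort(unique(d$cluster))
      if (n_flag == 0) {
        return(tibble::tibble(
          blood_subset = subsets,
          n_cells_subset = as.integer(table(factor(d$cluster,
                                                   subsets))[subsets]),
          n_shared_cells_subset = 0L, beta1 = NA_real_, OR = NA_real_,
          lrt_p = NA_real_, fdr = NA_real_, significant = FALSE,
          unstable = FALSE, n_unique_shared_clones = 0L,
          n_total_shared_cells = 0L,
          reason = "no heart-expanded clones in blood"))
      }
      rows <- purrr::map(subsets, function(k) {
        in_k <- as.integer(d$cluster == k)
        n_k <- sum(in_k)
        n_shared <- sum(in_k == 1 & d$myo_clone == 1)
        sep <- n_shared == n_flag && sum(in_k) == n_shared
        fit <- suppressWarnings(subset_lrt(in_k, d$myo_clone))
        tibble::tibble(
          blood_subset = k, n_cells_subset = n_k,
          n_shared_cells_subset = n_shared,
          beta1 = fit$beta1, OR = exp(fit$beta1), lrt_p = fit$p,
          unstable = sep || abs(fit$beta1) > 12)
      })
      out <- dplyr::bind_rows(rows)
      out$fdr <- bh_fdr(out$lrt_p)
      out$significant <- !is.na(out$fdr) & out$fdr < fdr_threshold
      out$n_unique_shared_clones <- donor_clones
      out$n_total_shared_cells <- n_flag
      out$reason <- NA_character_
      out
    }) |>
    dplyr::ungroup()
}

#' Fatal-outcome association of subset sharing
#'
#' Builds the 2x2 of donors (significant sharing in the designated subset
#' yes/no by fatal yes/no) and returns the two-sided Fisher exact p.
#'
#' @param sharing Per-donor logical vector (or `myo_sharing` rows for one
#'   subset): significant sharing.
#' @param fatal Per-donor logical vector, aligned with `sharing`.
#' @return List with `table` (2x2) and `p` (two-sided Fisher).
#' @export
fatal_association_test <- function(sharing, fatal) {
  sharing <- as.logical(sharing); fatal <- as.logical(fatal)
  stopifnot(length(sharing) == length(fatal))
  if (length(unique(fatal)) < 2 || length(unique(sharing)) < 2) {
    warning("an outcome or sharing class is empty; p = 1")
  }
  tab <- matrix(c(sum(fatal & sharing), sum(fatal & !sharing),
                  sum(!fatal & sharing), sum(!fatal & !sharing)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("fatal", "nonfatal"),
                                c("sharing", "no_sharing")))
  list(table = tab, p = fisher_exact_2x2(tab)$p_two_sided)
}

#' Map blood-shared clones onto heart T subsets
#'
#' Counts heart cells per subset carrying any blood-shared clone key;
#' donors with 10 or fewer qualifying cells are flagged low-evidence.
#'
#' @param heart_cells Heart cell tibble with `donor_id`, `cluster`,
#'   `clone_key`.
#' @param shared_keys Named list donor -> shared clone keys.
#' @return Tibble: donor_id, cluster, n_shared_cells, pct_of_donor_shared,
#'   low_evidence.
#' @export
map_shared_clones_to_heart_subsets <- function(heart_cells, shared_keys) {
  heart_cells |>
    dplyr::filter(.data$donor_id %in% names(shared_keys)) |>
    dplyr::group_by(.data$donor_id) |>
    dplyr::group_modify(function(d, key) {
      keys <- shared_keys[[key$donor_id]]
      hit <- !is.na(d$clone_key) & d$clone_key %in% keys
      total <- sum(hit)
      d |>
        dplyr::group_by(.data$cluster) |>
        dplyr::summarise(
          n_shared_cells = sum(!is.na(.data$clone_key) &
                                 .data$clone_key %in% keys),
          .groups = "drop") |>
        dplyr::mutate(
          pct_of_donor_shared = if (total > 0)
            100 * .data$n_shared_cells / total else 0,
          low_evidence = total <= 10)
    }) |>
    dplyr::ungroup()
}
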