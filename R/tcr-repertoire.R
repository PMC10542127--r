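#' Call clonal expansion
#'
#' A clone is expanded when it represents strictly more than 0.5% of the
#' specimen's repertoire AND has count >= 2 (reads for bulk data, cells
#' for single-cell data).
#'
#' @param clone_table Tibble with `clone_key`, `count` (and optionally
#'   `frequency`; recomputed from counts when absent).
#' @param mode `"bulk"` or `"sc"` (identical rule; unit of `count`
#'   differs).
#' @param freq_threshold Strict lower frequency bound (default 0.005).
#' @param min_count Minimum count (default 2).
#' @return Tibble with `clone_key`, `count`, `frequency`, `expanded`.
#' @export
call_expanded <- function(clone_table, mode = c("bulk", "sc"),
                          freq_threshold = 0.005, min_count = 2L) {
  mode <- match.arg(mode)
  clone_table <- tibble::as_tibble(clone_table)
  total <- sum(clone_table$count)
  if (nrow(clone_table) == 0 || total == 0) {
    stop("empty clone table: expansion is undefined", call. = FALSE)
  }
  clone_table$frequency <- clone_table$count / total
  clone_table$expanded <- clone_table$frequency > freq_threshold &
    clone_table$count >= min_count
  clone_table
}

#' Control-tissue-normalized clone enrichment
#'
#' For every clone expanded in the tissue of interest, a one-sided
#' (greater-in-tissue) Fisher's exact test compares its frequency against
#' the matched control-tissue repertoire; BH FDR over the candidates with
#' enrichment called at FDR < 5%. The plotted normalized ratio divides the
#' tissue frequency by the control frequency, substituting
#' `0.5/total_control` when the clone is absent from control (the test
#' itself always uses the true zero).
#'
#' @param tissue_table Clone tibble (`clone_key`, `count`) for heart or
#'   tumor.
#' @param control_table Clone tibble for the adjacent-normal control
#'   tissue.
#' @param tissue Label stored in the result.
#' @param fdr_threshold Enrichment rule (default 0.05).
#' @param two_sided Use the two-sided Fisher p instead (default FALSE).
#' @return `myo_enrichment` tibble: clone_key, tissue, freq_tissue,
#'   freq_control, normalized_ratio, fisher_p, fdr, enriched.
#' @export
tissue_enrichment <- function(tissue_table, control_table, tissue = "heart",
                              fdr_threshold = 0.05, two_sided = FALSE) {
  tissue_table <- call_expanded(tissue_table)
  total_t <- sum(tissue_table$count)
  total_c <- sum(control_table$count)
  if (total_c == 0) stop("control repertoire is empty", call. = FALSE)
  cand <- tissue_table[tissue_table$expanded, , drop = FALSE]
  if (nrow(cand) == 0) {
    message("no expanded clones in ", tissue, "; empty enrichment result")
    return(tibble::tibble(clone_key = character(), tissue = character(),
                          freq_tissue = double(), freq_control = double(),
                          normalized_ratio = double(), fisher_p = double(),
                          fdr = double(), enriched = logical()))
  }
  ctrl_counts <- stats::setNames(control_table$count,
                                 control_table$clone_key)
  cc <- as.integer(ctrl_counts[cand$clone_key])
  cc[is.na(cc)] <- 0L
  p <- purrr::map2_dbl(cand$count, cc, function(a, b) {
    tab <- matrix(c(a, total_t - a, b, total_c - b), nrow = 2, byrow = TRUE)
    f <- fisher_exact_2x2(tab)
    if (two_sided) f$p_two_sided else f$p_greater
  })
  freq_c <- cc / total_c
  pseudo <- 0.5 / total_c
  out <- tibble::tibble(
    clone_key = cand$clone_key,
    tissue = tissue,
    freq_tissue = cand$frequency,
    freq_control = freq_c,
    normalized_ratio = cand$frequency / ifelse(freq_c > 0, freq_c, pseudo),
    fisher_p = p,
    fdr = bh_fdr(p)
  )
  out$enriched <- out$fdr < fdr_threshold
  class(out) <- c("myo_enrichment", class(out))
  out
}

## Hill number of order q for a frequency vector
hill_number <- function(p, q) {
  p <- p[p > 0]
  if (abs(q - 1) < 1e-12) return(exp(-sum(p * log(p))))
  sum(p^q)^(1 / (1 - q))
}

#' Hill diversity profile of a repertoire
#'
#' Diversity `qD = (sum p_i^q)^(1/(1-q))` (with the Shannon limit at
#' q = 1) over a grid of orders, refused for specimens with fewer than 100
#' total sequences. With `rarefy_depth` set, each qD is the mean over
#' `n_boot` seeded multinomial resamples at that depth.
#'
#' @param clone_table Tibble with `count` per clone.
#' @param q_grid Diversity orders (default `seq(0, 4, by = 0.1)`).
#' @param rarefy_depth Optional resampling depth (<= total sequences).
#' @param n_boot Bootstrap resamples (default 200).
#' @param seed RNG seed for the resampling.
#' @param min_sequences Minimum total sequences (default 100).
#' @return `myo_diversity` tibble: `q`, `qD`, with attribute
#'   `n_sequences`.
#' @export
hill_diversity <- function(clone_table, q_grid = seq(0, 4, by = 0.1),
                           rarefy_depth = NULL, n_boot = 200L, seed = 1L,
                           min_sequences = 100L) {
  counts <- clone_table$count
  n_seq <- sum(counts)
  if (n_seq < min_sequences) {
    stop("diversity refused: ", n_seq, " sequences < required ",
         min_sequences, call. = FALSE)
  }
  if (is.null(rarefy_depth)) {
    p <- counts / n_seq
    qd <- vapply(q_grid, function(q) hill_number(p, q), numeric(1))
  } else {
    if (rarefy_depth > n_seq) {
      stop("rarefy_depth exceeds the number of sequences", call. = FALSE)
    }
    set.seed(seed)
    draws <- stats::rmultinom(n_boot, rarefy_depth, counts / n_seq)
    qd <- vapply(q_grid, function(q) {
      mean(apply(draws, 2, function(x) hill_number(x / sum(x), q)))
    }, numeric(1))
  }
  out <- tibble::tibble(q = q_grid, qD = qd)
  attr(out, "n_sequences") <- n_seq
  class(out) <- c("myo_diversity", class(out))
  out
}

#' Heart-tumor overlap of enriched clones
#'
#' Intersection summary of the heart-enriched and tumor-enriched clone
#' sets with percentages of each (exact values retained; whole-percent
#' rounding applied in the display columns).
#'
#' @param heart_enrichment,tumor_enrichment `myo_enrichment` tibbles (or
#'   any tibble with `clone_key` and logical `enriched`).
#' @return One-row tibble: n_heart, n_tumor, n_shared, pct_of_heart,
#'   pct_of_tumor plus display columns rounded to whole percent.
#' @export
heart_tumor_overlap <- function(heart_enrichment, tumor_enrichment) {
  h <- unique(heart_enrichment$clone_key[heart_enrichment$enriched])
  t <- unique(tumor_enrichment$clone_key[tumor_enrichment$enriched])
  shared <- intersect(h, t)
  pct_h <- if (length(h)) 100 * length(shared) / length(h) else 0
  pct_t <- if (length(t)) 100 * length(shared) / length(t) else 0
  tibble::tibble(
    n_heart = length(h), n_tumor = length(t), n_shared = length(shared),
    pct_of_heart = pct_h, pct_of_tumor = pct_t,
    pct_of_heart_display = paste0(round(pct_h), "%"),
    pct_of_tumor_display = paste0(round(pct_t), "%")
  )
}

#' Overlap summary from enriched-set sizes
#'
#' Convenience wrapper when only the set sizes are known (e.g. published
#' counts): returns the same summary as [heart_tumor_overlap()].
#'
#' @param n_heart,n_tumor,n_shared Enriched-set sizes and intersection.
#' @return One-row overlap tibble.
#' @export
overlap_from_counts <- function(n_heart, n_tumor, n_shared) {
  stopifnot(n_shared <= n_heart, n_shared <= n_tumor)
  pct_h <- if (n_heart) 100 * n_shared / n_heart else 0
  pct_t <- if (n_tumor) 100 * n_shared / n_tumor else 0
  tibble::tibble(
    n_heart = n_heart, n_tumor = n_tumor, n_shared = n_shared,
    pct_of_heart = pct_h, pct_of_tumor = pct_t,
    pct_of_heart_display = paste0(round(pct_h), "%"),
    pct_of_tumor_display = paste0(round(pct_t), "%")
  )
}
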