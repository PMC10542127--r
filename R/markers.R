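#' Per-gene AUROC for cluster membership
#'
#' Area under the ROC curve of each gene's logCPM as a predictor of
#' membership in `cluster`, computed from the Mann-Whitney U statistic
#' with mid-rank tie handling, within the supplied lineage of cells.
#'
#' @param logcpm Gene x cell matrix (sparse or dense) restricted to the
#'   analyzed lineage.
#' @param cell_table Cell tibble aligned to `logcpm` columns.
#' @param cluster Cluster whose membership is predicted.
#' @param marker_threshold AUROC at or above which a gene is a marker
#'   (default 0.75).
#' @return Tibble `gene`, `auroc`, `is_auroc_marker` (auroc >= 0.75).
#' @export
auroc_scan <- function(logcpm, cell_table, cluster, marker_threshold = 0.75) {
  in_cl <- cell_table$cluster == cluster
  n1 <- sum(in_cl); n0 <- sum(!in_cl)
  if (n1 == 0) stop("cluster ", cluster, " is empty", call. = FALSE)
  if (n0 == 0) stop("complement of cluster ", cluster, " is empty",
                    call. = FALSE)
  m <- as.matrix(logcpm)
  auc <- apply(m, 1, function(v) {
    r <- rank(v)
    (sum(r[in_cl]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  })
  tibble::tibble(gene = rownames(m), auroc = unname(auc),
                 is_auroc_marker = unname(auc) >= marker_threshold)
}

#' Estimate the variance-prior hyperparameters for moderated t
#'
#' Fits the scaled inverse-chi-square prior `s^2_g ~ s0^2 * F(d, d0)` by
#' method of moments on `ln s^2_g`: the excess dispersion of log sample
#' variances beyond `trigamma(d/2)` identifies `d0` through the trigamma
#' inverse, and the mean identifies `s0^2`. When the observed dispersion
#' does not exceed the theoretical minimum, `d0 = Inf` (all genes share
#' one variance).
#'
#' @param s2 Per-gene sample variances (>= 10 finite positive values).
#' @param df Residual degrees of freedom of each variance (scalar).
#' @return List `d0`, `s0_sq`.
#' @export
estimate_variance_prior <- function(s2, df) {
  s2 <- s2[is.finite(s2)]
  if (all(s2 == 0)) stop("all sample variances are zero", call. = FALSE)
  if (length(s2) < 10) {
    stop("need >= 10 genes with positive residual df", call. = FALSE)
  }
  z <- log(pmax(s2, 1e-300))
  e_bias <- digamma(df / 2) - log(df / 2)
  if (stats::var(z) < 1e-12) {
    ## exactly equal variances: no sampling noise to correct for; the
    ## shared value is the prior variance
    return(list(d0 = Inf, s0_sq = exp(mean(z))))
  }
  excess <- stats::var(z) - trigamma(df / 2)
  if (excess <= 0) {
    return(list(d0 = Inf, s0_sq = exp(mean(z) - e_bias)))
  }
  d0 <- 2 * trigamma_inverse(excess)
  s0_sq <- exp(mean(z) - e_bias + (digamma(d0 / 2) - log(d0 / 2)))
  list(d0 = d0, s0_sq = s0_sq)
}

## log2 counts-per-million with a 0.5 offset, per pseudobulk unit
log2_cpm <- function(pb) {
  tot <- colSums(pb)
  log2(sweep(pb, 2, tot / 1e6, `/`) + 0.5)
}

#' One-versus-all moderated-t marker test for one cluster
#'
#' Linear model `gene ~ in_clust` on log2(CPM + 0.5)-transformed
#' pseudobulk units, with empirical-Bayes posterior variances
#' `s~2 = (d0 s0^2 + d s^2_g) / (d0 + d)` and t on `d + d0` degrees of
#' freedom. BH FDR within the scan; markers are FDR < 0.05 with positive
#' log2 fold change.
#'
#' @param pseudobulk Output of [pseudobulk_sum()].
#' @param cluster Cluster tested against all others.
#' @param prior Optional list `d0`, `s0_sq` (estimated from the scan when
#'   `NULL`; `d0 = 0` gives the ordinary t).
#' @param fdr_threshold Marker FDR rule (default 0.05).
#' @return `myo_markers` tibble: gene, cluster, log2fc, t_mod, p, fdr,
#'   is_ova_marker.
#' @export
ova_moderated_t <- function(pseudobulk, cluster, prior = NULL,
                            fdr_threshold = 0.05) {
  units <- pseudobulk$units
  in_cl <- units$cluster == cluster
  if (sum(in_cl) < 2 || sum(!in_cl) < 2) {
    warning("cluster ", cluster, " has fewer than 2 units on a side; skipped")
    return(tibble::tibble())
  }
  y <- log2_cpm(pseudobulk$counts)
  n1 <- sum(in_cl); n0 <- sum(!in_cl); n <- n1 + n0
  m1 <- rowMeans(y[, in_cl, drop = FALSE])
  m0 <- rowMeans(y[, !in_cl, drop = FALSE])
  beta <- m1 - m0
  rss <- rowSums((y[, in_cl, drop = FALSE] - m1)^2) +
    rowSums((y[, !in_cl, drop = FALSE] - m0)^2)
  d <- n - 2
  s2 <- rss / d
  if (is.null(prior)) prior <- estimate_variance_prior(s2, d)
  d0 <- prior$d0; s0 <- prior$s0_sq
  s2_post <- if (is.infinite(d0)) rep(s0, length(s2)) else
    (d0 * s0 + d * s2) / (d0 + d)
  v <- 1 / n1 + 1 / n0
  t_mod <- beta / sqrt(s2_post * v)
  df_total <- if (is.infinite(d0)) Inf else d + d0
  p <- 2 * stats::pt(abs(t_mod), df = df_total, lower.tail = FALSE)
  p[!is.finite(t_mod)] <- 1
  t_mod[!is.finite(t_mod)] <- 0
  fdr <- bh_fdr(p)
  out <- tibble::tibble(
    gene = rownames(y), cluster = cluster, log2fc = unname(beta),
    t_mod = unname(t_mod), p = unname(p), fdr = unname(fdr),
    is_ova_marker = unname(fdr < fdr_threshold & beta > 0)
  )
  attr(out, "prior") <- prior
  class(out) <- c("myo_markers", class(out))
  out
}

#' Combined marker scan (AUROC + OVA moderated t) per cluster
#'
#' @param logcpm Gene x cell logCPM matrix for the lineage.
#' @param cell_table Cells aligned to `logcpm`.
#' @param pseudobulk Output of [pseudobulk_sum()] on the same lineage.
#' @param clusters Clusters to scan (default all).
#' @param auroc_threshold AUROC marker rule (default 0.75).
#' @return Tibble with both marker calls per gene per cluster.
#' @export
marker_scan <- function(logcpm, cell_table, pseudobulk, clusters = NULL,
                        auroc_threshold = 0.75) {
  if (is.null(clusters)) clusters <- sort(unique(cell_table$cluster))
  purrr::map(clusters, function(k) {
    ova <- ova_moderated_t(pseudobulk, k)
    if (nrow(ova) == 0) return(NULL)
    auc <- auroc_scan(logcpm, cell_table, k,
                      marker_threshold = auroc_threshold)
    dplyr::left_join(ova, auc, by = "gene")
  }) |>
    dplyr::bind_rows()
}
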