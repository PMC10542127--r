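## Mean expression per gene per cluster for a set of genes; returns a
## genes x clusters matrix. Used both for the observed statistic and for
## each permutation.
cluster_means <- function(logcpm, labels, genes) {
  f <- factor(labels)
  ind <- Matrix::t(Matrix::fac2sparse(f))      # cells x clusters
  sums <- as.matrix(logcpm[genes, , drop = FALSE] %*% ind)
  sweep(sums, 2, as.numeric(table(f)[colnames(sums)]), `/`)
}

#' Receptor-ligand interaction statistic for one pair of clusters
#'
#' The mean-of-means score `(mean ligand in sender + mean receptor in
#' receiver) / 2`, subject to the expression filters: each gene expressed
#' in strictly more than 10% of its cluster's cells, and both clusters
#' holding at least 20 cells.
#'
#' @param logcpm Gene x cell logCPM matrix.
#' @param cell_table Cells aligned to `logcpm`, with `cluster`.
#' @param ligand,receptor Gene names.
#' @param sender,receiver Cluster labels.
#' @param min_frac,min_cells Filter rules (defaults 0.10 strict and 20).
#' @return List `statistic` (NA when excluded), `passes_expression_filter`.
#' @export
interaction_statistic <- function(logcpm, cell_table, ligand, receptor,
                                  sender, receiver,
                                  min_frac = 0.10, min_cells = 20L) {
  for (g in c(ligand, receptor)) {
    if (!g %in% rownames(logcpm)) stop("unknown gene: ", g, call. = FALSE)
  }
  s_idx <- which(cell_table$cluster == sender)
  r_idx <- which(cell_table$cluster == receiver)
  frac_l <- sum(logcpm[ligand, s_idx] > 0) / length(s_idx)
  frac_r <- sum(logcpm[receptor, r_idx] > 0) / length(r_idx)
  ok <- length(s_idx) >= min_cells && length(r_idx) >= min_cells &&
    frac_l > min_frac && frac_r > min_frac
  stat <- if (ok) {
    (mean(logcpm[ligand, s_idx]) + mean(logcpm[receptor, r_idx])) / 2
  } else NA_real_
  list(statistic = stat, passes_expression_filter = ok)
}

#' Permutation test for receptor-ligand interactions
#'
#' Scores every (ligand, receptor, sender, receiver) combination from the
#' pair list across all cluster pairs, then shuffles cluster labels over
#' cells B times (one shared set of permutations for all pairs) and
#' reports the add-one empirical p-value
#' `(1 + #\{T_b >= T_obs\}) / (1 + B)`. Significance follows the strict
#' empirical P < 0.001 rule, so B must exceed 999 for any pair to pass.
#'
#' @param logcpm Gene x cell logCPM matrix.
#' @param cell_table Cells aligned to `logcpm`, with `cluster`.
#' @param pairs Tibble with `ligand` and `receptor` columns.
#' @param B Number of permutations (default 1000).
#' @param seed RNG seed.
#' @param clusters Clusters to cross (default all).
#' @param p_threshold Significance rule (default 0.001, strict).
#' @inheritParams interaction_statistic
#' @return `myo_interactions` tibble: ligand, receptor, sender, receiver,
#'   statistic, empirical_p, passes_expression_filter,
#'   passes_significance.
#' @export
permutation_test <- function(logcpm, cell_table, pairs, B = 1000L,
                             seed = 1L, clusters = NULL,
                             min_frac = 0.10, min_cells = 20L,
                             p_threshold = 0.001) {
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  genes <- unique(c(pairs$ligand, pairs$receptor))
  missing <- setdiff(genes, rownames(logcpm))
  if (length(missing)) {
    stop("unknown gene(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  labels <- cell_table$cluster
  if (is.null(clusters)) clusters <- sort(unique(labels))
  obs_means <- cluster_means(logcpm, labels, genes)
  n_per <- stats::setNames(as.integer(table(factor(labels))[clusters]),
                           clusters)
  frac_nz <- vapply(clusters, function(k) {
    idx <- which(labels == k)
    Matrix::rowSums(logcpm[genes, idx, drop = FALSE] > 0) / length(idx)
  }, numeric(length(genes)))
  dimnames(frac_nz) <- list(genes, clusters)
  grid <- tidyr::expand_grid(pair = seq_len(nrow(pairs)),
                             sender = clusters, receiver = clusters)
  grid$ligand <- pairs$ligand[grid$pair]
  grid$receptor <- pairs$receptor[grid$pair]
  grid$passes_expression_filter <- as.vector(
    n_per[grid$sender] >= min_cells & n_per[grid$receiver] >= min_cells &
      frac_nz[cbind(grid$ligand, grid$sender)] > min_frac &
      frac_nz[cbind(grid$receptor, grid$receiver)] > min_frac)
  t_obs <- as.vector(obs_means[cbind(grid$ligand, grid$sender)] +
                       obs_means[cbind(grid$receptor, grid$receiver)]) / 2
  ## permutation null: shared label shuffles
  set.seed(seed)
  exceed <- integer(nrow(grid))
  for (b in seq_len(B)) {
    perm <- sample(labels)
    pm <- cluster_means(logcpm, perm, genes)
    t_b <- (pm[cbind(grid$ligand, grid$sender)] +
              pm[cbind(grid$receptor, grid$receiver)]) / 2
    exceed <- exceed + as.integer(t_b >= t_obs)
  }
  emp_p <- (1 + exceed) / (1 + B)
  out <- tibble::tibble(
    ligand = grid$ligand, receptor = grid$receptor,
    sender = grid$sender, receiver = grid$receiver,
    statistic = ifelse(grid$passes_expression_filter, t_obs, NA_real_),
    empirical_p = emp_p,
    passes_expression_filter = grid$passes_expression_filter,
    passes_significance = grid$passes_expression_filter &
      emp_p < p_threshold
  )
  class(out) <- c("myo_interactions", class(out))
  out
}

#' Apply DE, abundance, and curation filters to interaction results
#'
#' Keeps interactions where (a) the ligand is differentially expressed in
#' the sender or the receptor in the receiver (FDR < 0.1), (b) the sender
#' or receiver belongs to the disease-enriched cluster set, and (c) the
#' pair is on the curated literature list. `final_call` additionally
#' requires the expression and significance filters.
#'
#' @param results `myo_interactions` tibble from [permutation_test()].
#' @param de_table `myo_de` tibble with `gene`, `subset`, `fdr`.
#' @param enriched_clusters Character vector of disease-enriched clusters.
#' @param curated_pairs Tibble with `ligand`, `receptor` (mandatory).
#' @param de_fdr DE filter threshold (default 0.1).
#' @return Filtered tibble with filter booleans and `final_call`.
#' @export
filter_interactions <- function(results, de_table, enriched_clusters,
                                curated_pairs, de_fdr = 0.1) {
  if (is.null(curated_pairs) || nrow(curated_pairs) == 0) {
    stop("curated pair list is mandatory and must be non-empty",
         call. = FALSE)
  }
  de_sig <- de_table[!is.na(de_table$fdr) & de_table$fdr < de_fdr,
                     c("gene", "subset")]
  de_key <- paste(de_sig$gene, de_sig$subset)
  out <- results
  out$passes_de_filter <-
    paste(out$ligand, out$sender) %in% de_key |
    paste(out$receptor, out$receiver) %in% de_key
  out$passes_abundance_filter <- out$sender %in% enriched_clusters |
    out$receiver %in% enriched_clusters
  out$in_curated_list <- paste(out$ligand, out$receptor) %in%
    paste(curated_pairs$ligand, curated_pairs$receptor)
  out$final_call <- out$passes_expression_filter &
    out$passes_significance & out$passes_de_filter &
    out$passes_abundance_filter & out$in_curated_list
  out
}
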