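#' The 13 mitochondrial genes used for the QC mito fraction
#'
#' Fraction of mitochondrial UMIs is computed from this fixed list only,
#' regardless of what other MT- features the annotation carries.
#' @export
MITO_GENES_13 <- c("MT-ND6", "MT-CO2", "MT-CYB", "MT-ND2", "MT-ND5",
                   "MT-CO1", "MT-ND3", "MT-ND4", "MT-ND1", "MT-ATP6",
                   "MT-CO3", "MT-ND4L", "MT-ATP8")

#' QC thresholds for droplet filtering
#'
#' Defaults follow the study conventions: keep a cell iff its mitochondrial
#' UMI fraction is strictly below 20% and its unique-gene count strictly
#' exceeds the compartment threshold (300 for heart tissue, 400 for blood).
#'
#' @param max_mito_fraction Upper (exclusive) bound on mito UMI fraction.
#' @param min_genes_heart,min_genes_blood Lower (exclusive) bounds on the
#'   number of detected genes per compartment.
#' @param mito_genes Gene symbols used to compute the mito fraction.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(max_mito_fraction = 0.20,
                          min_genes_heart = 300L,
                          min_genes_blood = 400L,
                          mito_genes = MITO_GENES_13) {
  stopifnot(max_mito_fraction > 0, min_genes_heart > 0, min_genes_blood > 0,
            length(mito_genes) > 0)
  structure(list(max_mito_fraction = max_mito_fraction,
                 min_genes_heart = as.integer(min_genes_heart),
                 min_genes_blood = as.integer(min_genes_blood),
                 mito_genes = mito_genes),
            class = "qc_thresholds")
}

#' Filter low-quality droplets
#'
#' Applies the compartment-specific QC rule. If the cell table lacks
#' `mito_frac`/`n_genes` columns they are computed from the count matrix
#' (mito fraction over the fixed 13-gene list, unique genes as features
#' with nonzero UMIs).
#'
#' @param cell_table Tibble with `barcode` and `compartment` (values
#'   `heart`, `blood`, `tumor`, `control_tissue`); optional `mito_frac`,
#'   `n_genes`.
#' @param counts Sparse gene x cell matrix, columns aligned to
#'   `cell_table$barcode`.
#' @param thresholds A [qc_thresholds()] object.
#' @return List with filtered `cell_table`, `counts`, and `qc_report`
#'   (per-sample kept/dropped tallies when a `sample_id` column exists).
#' @export
qc_filter <- function(cell_table, counts, thresholds = qc_thresholds()) {
  cell_table <- tibble::as_tibble(cell_table)
  known <- c("heart", "blood", "tumor", "control_tissue")
  if (!all(cell_table$compartment %in% known)) {
    bad <- setdiff(unique(cell_table$compartment), known)
    stop("unknown compartment(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  has_mito <- "mito_frac" %in% names(cell_table)
  has_ngenes <- "n_genes" %in% names(cell_table)
  if (!has_mito || !has_ngenes) {
    totals <- Matrix::colSums(counts)
    mito <- intersect(thresholds$mito_genes, rownames(counts))
    mito_sum <- if (length(mito)) {
      Matrix::colSums(counts[mito, , drop = FALSE])
    } else {
      numeric(ncol(counts))
    }
    if (!has_mito) {
      cell_table$mito_frac <- as.numeric(ifelse(totals > 0, mito_sum / totals, 0))
    }
    if (!has_ngenes) {
      cell_table$n_genes <- unname(Matrix::colSums(counts > 0))
    }
  }
  min_genes <- ifelse(cell_table$compartment == "blood",
                      thresholds$min_genes_blood, thresholds$min_genes_heart)
  keep <- cell_table$mito_frac < thresholds$max_mito_fraction &
    cell_table$n_genes > min_genes
  report <- NULL
  if ("sample_id" %in% names(cell_table)) {
    report <- cell_table |>
      dplyr::mutate(kept = keep) |>
      dplyr::count(.data$sample_id, .data$kept) |>
      tidyr::pivot_wider(names_from = "kept", values_from = "n",
                         values_fill = 0L,
                         names_prefix = "kept_")
  }
  list(
    cell_table = cell_table[keep, , drop = FALSE],
    counts = counts[, keep, drop = FALSE],
    qc_report = report
  )
}

#' Log-normalize UMI counts to logCPM
#'
#' `logCPM = log1p(1e5 * count / cell_total)` with natural log; zeros stay
#' zero so sparsity is preserved.
#'
#' @param counts Sparse gene x cell matrix; every cell total must be > 0.
#' @return Sparse matrix of the same shape.
#' @export
log_normalize <- function(counts) {
  counts <- methods::as(counts, "CsparseMatrix")
  totals <- Matrix::colSums(counts)
  if (any(totals <= 0)) {
    bad <- colnames(counts)[totals <= 0] %||% which(totals <= 0)
    stop("zero-total cell(s): ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  out <- counts
  per_col <- diff(out@p)
  out@x <- log1p(1e5 * out@x / rep(totals, per_col))
  out
}

#' Sum counts into pseudobulk units
#'
#' Sums UMI counts over cells within each sample x cluster combination,
#' yielding a genes x units integer matrix. Units with zero cells are
#' absent.
#'
#' @param counts Sparse gene x cell matrix.
#' @param cell_table Tibble with `sample_id` and `cluster` per cell, rows
#'   aligned to columns of `counts`.
#' @return List with `counts` (dense genes x units matrix), `units` tibble
#'   (`unit`, `sample_id`, `cluster`, `n_cells`).
#' @export
pseudobulk_sum <- function(counts, cell_table) {
  stopifnot(nrow(cell_table) == ncol(counts))
  if (any(is.na(cell_table$cluster))) {
    stop("every cell needs a cluster label", call. = FALSE)
  }
  unit <- factor(paste(cell_table$sample_id, cell_table$cluster, sep = "|"))
  ind <- Matrix::t(Matrix::fac2sparse(unit))     # cells x units
  pb <- as.matrix(counts %*% ind)
  lv <- levels(unit)
  n_cells <- as.integer(table(unit)[lv])
  units <- tibble::tibble(
    unit = lv,
    sample_id = sub("\\|[^|]*$", "", lv),
    cluster = sub("^.*\\|", "", lv),
    n_cells = n_cells
  )
  storage.mode(pb) <- "double"
  colnames(pb) <- units$unit
  list(counts = pb, units = units)
}

#' Per-gene expression summary within a cluster
#'
#' Fraction of cells with nonzero expression and mean expression (zeros
#' included) for one cluster — the quantities behind the receptor-ligand
#' expression filters.
#'
#' @param logcpm Sparse gene x cell logCPM matrix.
#' @param cell_table Cell tibble aligned to `logcpm` columns.
#' @param cluster Cluster label to summarize.
#' @return Tibble with `gene`, `frac_nonzero`, `mean_expr`, `n_cells`.
#' @export
expression_summary <- function(logcpm, cell_table, cluster) {
  idx <- which(cell_table$cluster == cluster)
  if (length(idx) == 0) stop("cluster ", cluster, " is empty", call. = FALSE)
  sub <- logcpm[, idx, drop = FALSE]
  tibble::tibble(
    gene = rownames(sub),
    frac_nonzero = unname(Matrix::rowSums(sub > 0)) / length(idx),
    mean_expr = unname(Matrix::rowSums(sub)) / length(idx),
    n_cells = length(idx)
  )
}
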