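#' @importFrom rlang .data
#' @import tibble
NULL

#' Read a CellRanger-style sparse count matrix
#'
#' Loads a MatrixMarket coordinate file with its companion features and
#' barcodes TSVs into a sparse gene x cell matrix. Dimensions are checked
#' against the companion files and mismatches are reported by file name.
#'
#' @param matrix_path Path to the `.mtx` coordinate file (integer values).
#' @param features_path TSV of gene identifiers, one per matrix row.
#' @param barcodes_path TSV of cell barcodes, one per matrix column.
#' @return List with `counts` (a `dgCMatrix` with dimnames) and `cell_table`,
#'   a tibble skeleton with one row per barcode.
#' @export
read_count_matrix <- function(matrix_path, features_path, barcodes_path) {
  m <- Matrix::readMM(matrix_path)
  if (any(m@x != round(m@x))) {
    stop("non-integer values in count matrix: ", matrix_path, call. = FALSE)
  }
  features <- readr::read_tsv(features_path, col_names = FALSE,
                              show_col_types = FALSE, progress = FALSE)
  barcodes <- readr::read_tsv(barcodes_path, col_names = FALSE,
                              show_col_types = FALSE, progress = FALSE)
  if (nrow(features) != nrow(m)) {
    stop("dimension mismatch: ", features_path, " has ", nrow(features),
         " rows but matrix has ", nrow(m), " rows", call. = FALSE)
  }
  if (nrow(barcodes) != ncol(m)) {
    stop("dimension mismatch: ", barcodes_path, " has ", nrow(barcodes),
         " rows but matrix has ", ncol(m), " columns", call. = FALSE)
  }
  counts <- methods::as(Matrix::drop0(m), "CsparseMatrix")
  dimnames(counts) <- list(features[[1]], barcodes[[1]])
  list(
    counts = counts,
    cell_table = tibble::tibble(barcode = barcodes[[1]])
  )
}

#' Write a sparse count matrix in MatrixMarket + TSV layout
#'
#' @param counts Sparse gene x cell matrix with dimnames.
#' @param matrix_path,features_path,barcodes_path Output paths.
#' @return Invisibly, the matrix path.
#' @export
write_count_matrix <- function(counts, matrix_path, features_path, barcodes_path) {
  Matrix::writeMM(methods::as(counts, "TsparseMatrix"), matrix_path)
  readr::write_tsv(tibble::tibble(x = rownames(counts)), features_path,
                   col_names = FALSE)
  readr::write_tsv(tibble::tibble(x = colnames(counts)), barcodes_path,
                   col_names = FALSE)
  invisible(matrix_path)
}

## Clone key: v gene stripped to gene level + "|" + CDR3 nucleotide junction;
## amino-acid fallback when the nucleotide junction is missing. The
## nucleotide key is the stricter default for matching bulk TCR-beta data
## against single-cell beta chains; the aa key keeps cross-platform matching
## possible.
make_clone_key <- function(v_call, junction_nt, junction_aa,
                           key = c("nt", "aa")) {
  key <- match.arg(key)
  v_gene <- sub("\\*.*$", "", v_call)
  cdr3 <- if (key == "nt") junction_nt else junction_aa
  use_aa <- key == "nt" & (is.na(cdr3) | cdr3 == "")
  cdr3[use_aa] <- junction_aa[use_aa]
  paste0(v_gene, "|", cdr3)
}

airr_cols <- c(junction = "junction", junction_aa = "junction_aa",
               v_call = "v_call", j_call = "j_call",
               count = "duplicate_count", productive = "productive")
immunoseq_cols <- c(junction = "nucleotide", junction_aa = "aminoAcid",
                    v_call = "vGeneName", j_call = "jGeneName",
                    count = "count", productive = "sequenceStatus")

#' Read a bulk TCR-beta clone table
#'
#' Parses AIRR rearrangement TSVs or immunoSEQ-style exports into a tidy
#' clone table. Unproductive rows are dropped, rows sharing a clone key are
#' collapsed with summed counts, and frequencies are computed over the
#' productive total.
#'
#' @param path TSV file path.
#' @param dialect `"airr"` (community-standard column names) or
#'   `"immunoseq_like"`.
#' @param key Clone key flavor: `"nt"` (V gene + CDR3 nucleotide, default) or
#'   `"aa"` (V gene + CDR3 amino acid).
#' @return Tibble with `clone_key`, `count`, `frequency`; attribute
#'   `total_count` holds the productive total (0 for an empty file).
#' @export
read_clone_table <- function(path, dialect = c("airr", "immunoseq_like"),
                             key = c("nt", "aa")) {
  dialect <- match.arg(dialect)
  key <- match.arg(key)
  cols <- if (dialect == "airr") airr_cols else immunoseq_cols
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0 && ncol(df) == 0) {
    out <- tibble::tibble(clone_key = character(), count = integer(),
                          frequency = double())
    attr(out, "total_count") <- 0L
    return(out)
  }
  missing <- setdiff(unname(cols), names(df))
  if (length(missing)) {
    stop("clone table ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  productive <- if (dialect == "airr") {
    toupper(as.character(df[[cols[["productive"]]]])) %in% c("T", "TRUE", "1")
  } else {
    df[[cols[["productive"]]]] %in% c("In", "in")
  }
  df <- df[productive, , drop = FALSE]
  out <- tibble::tibble(
    clone_key = make_clone_key(df[[cols[["v_call"]]]], df[[cols[["junction"]]]],
                               df[[cols[["junction_aa"]]]], key = key),
    count = as.integer(df[[cols[["count"]]]])
  ) |>
    dplyr::group_by(.data$clone_key) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  total <- sum(out$count)
  out$frequency <- if (total > 0) out$count / total else double(nrow(out))
  attr(out, "total_count") <- total
  out
}

#' Read single-cell TCR contig annotations
#'
#' Keeps productive beta-chain (TRB) contigs only and maps each cell barcode
#' to one clone key. Cells carrying more than one distinct productive beta
#' clone key are ambiguous and excluded from clonotype analyses.
#'
#' @param path Contig CSV with `barcode`, `chain`, `productive`, `cdr3_nt`,
#'   `cdr3`, `v_gene` columns.
#' @inheritParams read_clone_table
#' @return Tibble with `barcode` and `clone_key`; attribute `n_ambiguous`
#'   counts the excluded multi-beta cells.
#' @export
read_sc_contigs <- function(path, key = c("nt", "aa")) {
  key <- match.arg(key)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("barcode", "chain", "productive", "cdr3_nt", "cdr3", "v_gene")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("contig file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  keep <- df$chain == "TRB" &
    toupper(as.character(df$productive)) %in% c("T", "TRUE", "1")
  df <- df[keep, , drop = FALSE]
  df$clone_key <- make_clone_key(df$v_gene, df$cdr3_nt, df$cdr3, key = key)
  per_cell <- df |>
    dplyr::distinct(.data$barcode, .data$clone_key) |>
    dplyr::add_count(.data$barcode, name = "n_keys")
  ambiguous <- unique(per_cell$barcode[per_cell$n_keys > 1])
  out <- per_cell |>
    dplyr::filter(.data$n_keys == 1) |>
    dplyr::select("barcode", "clone_key")
  attr(out, "n_ambiguous") <- length(ambiguous)
  out
}

#' Write a result table as TSV with display columns
#'
#' Writes any pipeline result tibble with full-precision values plus
#' `*_display` companions for the reporting columns: odds ratios and fold
#' changes to one decimal, p-values and FDRs to two significant figures.
#'
#' @param result A result tibble.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_result_table <- function(result, path) {
  result <- tibble::as_tibble(result)
  ratio_cols <- intersect(names(result),
                          c("OR", "odds_ratio", "fold_ratio", "normalized_ratio"))
  p_cols <- intersect(names(result), c("p", "fdr", "fisher_p", "empirical_p",
                                       "lrt_p", "p_two_sided", "p_greater"))
  for (cc in ratio_cols) {
    result[[paste0(cc, "_display")]] <- format_ratio_display(result[[cc]])
  }
  for (cc in p_cols) {
    result[[paste0(cc, "_display")]] <- format_p_display(result[[cc]])
  }
  readr::write_tsv(result, path, progress = FALSE)
  invisible(path)
}
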