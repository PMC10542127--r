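#' Median-of-ratios size factors
#'
#' Per-unit normalization factors computed as the median, over genes
#' nonzero in every unit, of the ratio of the unit's count to the gene's
#' geometric mean across units. Falls back to total-count ratios
#' (normalized to geometric mean 1) when no gene is nonzero everywhere.
#'
#' @param pb Genes x units count matrix.
#' @return Numeric vector of size factors, one per unit.
#' @export
size_factors <- function(pb) {
  pb <- as.matrix(pb)
  if (ncol(pb) == 1) return(stats::setNames(1, colnames(pb)))
  all_pos <- rowSums(pb > 0) == ncol(pb)
  if (!any(all_pos)) {
    message("no gene nonzero in every unit; using total-count ratios")
    tot <- colSums(pb)
    return(tot / exp(mean(log(tot))))
  }
  sub <- pb[all_pos, , drop = FALSE]
  geo <- exp(rowMeans(log(sub)))
  apply(sub / geo, 2, stats::median)
}

## Per-gene NB dispersion by profile maximum likelihood given fitted means.
nb_ml_dispersion <- function(y, mu, interval = c(1e-8, 50)) {
  nll <- function(a) {
    -sum(stats::dnbinom(y, mu = mu, size = 1 / a, log = TRUE))
  }
  stats::optimize(nll, interval = interval)$minimum
}

#' Pseudobulk negative-binomial Wald differential expression
#'
#' Simplified pseudobulk case-vs-control test: per gene, an NB log-link
#' GLM `gene ~ case` with `log(size factor)` offset; gene-wise ML
#' dispersions shrunk toward the trimmed-mean log-dispersion with a
#' log-normal prior whose weight comes from the spread of the gene-wise
#' estimates; Wald z on the case coefficient with two-sided normal p and
#' BH FDR. No outlier replacement, independent filtering, or fold-change
#' shrinkage is performed.
#'
#' @param pb Genes x units pseudobulk count matrix.
#' @param case Logical/0-1 vector per unit (TRUE = case).
#' @param sf Size factors (default [size_factors()]).
#' @param fdr_threshold Significance rule on BH FDR (default 0.1).
#' @param subset_label Annotation copied into the result (e.g. the cell
#'   subset or a pooled-lineage label).
#' @return `myo_de` tibble: gene, subset, log2fc, wald_z, p, fdr,
#'   significant, dispersion.
#' @export
nb_wald_de <- function(pb, case, sf = NULL, fdr_threshold = 0.1,
                       subset_label = NA_character_) {
  pb <- as.matrix(pb)
  case <- as.numeric(case)
  stopifnot(length(case) == ncol(pb))
  if (min(table(case)) < 2) stop("need >= 2 units per group", call. = FALSE)
  if (is.null(sf)) sf <- size_factors(pb)
  off <- log(sf)
  design_x <- case
  nz <- rowSums(pb) > 0
  genes <- rownames(pb) %||% as.character(seq_len(nrow(pb)))
  ## pass 1: gene-wise dispersions from a Poisson-fitted mean
  fit_gene <- function(y, alpha) {
    fam <- MASS::negative.binomial(theta = 1 / alpha)
    f <- suppressWarnings(
      stats::glm(y ~ design_x + offset(off), family = fam))
    ## dispersion pinned at 1: extra-Poisson variance lives in theta
    sm <- summary(f, dispersion = 1)$coefficients
    c(beta = sm[2, 1], se = sm[2, 2], mu_ok = as.numeric(f$converged))
  }
  disp <- rep(NA_real_, nrow(pb))
  for (i in which(nz)) {
    y <- pb[i, ]
    mu0 <- suppressWarnings(stats::glm(y ~ design_x + offset(off),
                                       family = stats::poisson()))$fitted
    disp[i] <- nb_ml_dispersion(y, pmax(mu0, 1e-8))
  }
  ## shrink log-dispersions toward the trimmed mean; with a single usable
  ## gene there is no spread to estimate, so its own estimate stands
  ld <- log(disp[nz])
  disp_shrunk <- disp
  if (sum(nz) >= 3) {
    center <- mean(ld, trim = 0.2)
    spread2 <- stats::var(ld)
    samp2 <- min(spread2, trigamma(max(ncol(pb) - 2, 1) / 2))
    prior2 <- max(spread2 - samp2, 0.05)
    w <- prior2 / (prior2 + samp2)
    disp_shrunk[nz] <- pmax(exp(w * ld + (1 - w) * center), 1e-8)
  } else {
    disp_shrunk[nz] <- pmax(exp(ld), 1e-8)
  }
  rows <- purrr::map(seq_len(nrow(pb)), function(i) {
    if (!nz[i]) return(NULL)  # all-zero gene skipped
    est <- tryCatch(fit_gene(pb[i, ], disp_shrunk[i]),
                    error = function(e) NULL)
    if (is.null(est) || !is.finite(est[["se"]]) || est[["se"]] <= 0) {
      return(tibble::tibble(gene = genes[i], log2fc = NA_real_,
                            wald_z = NA_real_, p = NA_real_,
                            dispersion = disp_shrunk[i]))
    }
    z <- est[["beta"]] / est[["se"]]
    tibble::tibble(gene = genes[i], log2fc = est[["beta"]] / log(2),
                   wald_z = z, p = 2 * stats::pnorm(-abs(z)),
                   dispersion = disp_shrunk[i])
  })
  out <- dplyr::bind_rows(rows)
  out$fdr <- bh_fdr(out$p)
  out$significant <- !is.na(out$fdr) & out$fdr < fdr_threshold
  out <- dplyr::mutate(out, subset = subset_label, .after = "gene")
  class(out) <- c("myo_de", class(out))
  out
}

#' Case-vs-control DE across subsets and pooled lineages
#'
#' Runs [nb_wald_de()] per cluster on the sample x cluster pseudobulk and
#' optionally on pooled lineage groupings (for example "All T").
#'
#' @param pseudobulk Output of [pseudobulk_sum()].
#' @param sample_meta Tibble mapping `sample_id` to `group`.
#' @param pooled Named list of cluster vectors to pool, e.g.
#'   `list("All T" = c("C2","C3"))`.
#' @param case_level Case label in `sample_meta$group`.
#' @param min_units_per_group Minimum pseudobulk units per group (subsets
#'   below it are skipped with a warning).
#' @return Combined `myo_de` tibble.
#' @export
de_by_subset <- function(pseudobulk, sample_meta, pooled = NULL,
                         case_level = "case", min_units_per_group = 2L) {
  units <- pseudobulk$units
  units$group <- sample_meta$group[match(units$sample_id,
                                         sample_meta$sample_id)]
  run_one <- function(cols, label) {
    u <- units[cols, ]
    case <- u$group == case_level
    if (sum(case) < min_units_per_group ||
        sum(!case) < min_units_per_group) {
      warning("subset ", label, " has too few units; skipped")
      return(NULL)
    }
    nb_wald_de(pseudobulk$counts[, cols, drop = FALSE], case,
               subset_label = label)
  }
  per_cluster <- purrr::map(sort(unique(units$cluster)), function(k) {
    run_one(which(units$cluster == k), k)
  })
  per_pool <- purrr::imap(pooled %||% list(), function(cls, label) {
    idx <- which(units$cluster %in% cls)
    ## pool by summing units of the same sample
    sub <- pseudobulk$counts[, idx, drop = FALSE]
    sid <- factor(units$sample_id[idx])
    pooled_pb <- sub %*% Matrix::t(Matrix::fac2sparse(sid))
    pooled_pb <- as.matrix(pooled_pb)
    colnames(pooled_pb) <- levels(sid)
    grp <- sample_meta$group[match(levels(sid), sample_meta$sample_id)]
    case <- grp == case_level
    if (sum(case) < min_units_per_group ||
        sum(!case) < min_units_per_group) {
      warning("pooled group ", label, " has too few units; skipped")
      return(NULL)
    }
    nb_wald_de(pooled_pb, case, subset_label = label)
  })
  dplyr::bind_rows(c(per_cluster, unname(per_pool)))
}
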