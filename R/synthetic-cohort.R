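#' Configuration for the synthetic myocarditis cohort
#'
#' Bundles every ground-truth parameter of the simulated study: cohort
#' sizes, per-cluster composition effects, donor random-intercept scale,
#' negative-binomial expression parameters, repertoire shapes,
#' heart-blood clone-sharing rates, serum shifts, and the troponin link.
#' Identical configurations (same seed included) generate byte-identical
#' studies.
#'
#' Defaults mirror the study conditions: 12 pre-corticosteroid cases vs 8
#' controls, 4 fatal cases, 4 case donors with tumor/adjacent-normal
#' TCR-beta repertoires, a 71-analyte serum panel with 16 case-shifted
#' analytes.
#'
#' @param seed Integer RNG seed.
#' @param n_case_donors,n_control_donors Donor counts per group.
#' @param n_fatal Number of fatal case donors (must be <= `n_case_donors`).
#' @param cells_per_donor Cells simulated per donor per compartment.
#' @param n_clusters Number of cell subsets.
#' @param baseline_cluster_logits Length-`n_clusters` multinomial logits in
#'   controls.
#' @param case_log_odds Per-cluster abundance effect (log-odds added for
#'   case donors).
#' @param donor_sd Random-intercept SD (log-odds), drawn per donor per
#'   cluster.
#' @param n_genes Genes simulated (the first 13 carry the mitochondrial
#'   symbols so QC is exercised).
#' @param de_spec List of `list(cluster=, genes=, log2fc=)` case
#'   fold-changes.
#' @param nb_dispersion Per-gene NB dispersion (scalar recycled).
#' @param libsize_lognormal `c(meanlog, sdlog)` of per-cell library factors.
#' @param mito_fail_fraction,lowgene_fail_fraction Fractions of cells whose
#'   QC covariates are overwritten to fail filtering.
#' @param repertoire_spec Named list (`heart`, `tumor`, `control_tissue`)
#'   of `list(n_clones=, exponent=, total_reads=)` power-law repertoires.
#' @param n_tcr_donors Case donors with heart/tumor/control repertoires.
#' @param n_heart_enriched,n_tumor_enriched Truth enriched clones per donor.
#' @param heart_tumor_overlap_fraction Fraction of heart-enriched truth
#'   clones also tumor-enriched.
#' @param fatal_sharing_subset Blood subset concentrating heart-expanded
#'   clones in fatal donors.
#' @param fatal_sharing_rate,nonfatal_sharing_rate Per-cell probability a
#'   blood cell of that subset carries a heart-expanded clone key.
#' @param background_sharing_rate Same probability in every other subset.
#' @param serum_spec `list(n_analytes=, n_shifted=, log_mean=, log_shift=,
#'   log_sd=)`.
#' @param troponin_link `list(intercept=, slope=, noise_sd=, cluster=)` for
#'   `log(troponin) = intercept + slope * log(true cluster proportion) +
#'   noise` in case donors.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_case_donors = 12L,
                       n_control_donors = 8L,
                       n_fatal = 4L,
                       cells_per_donor = 400L,
                       n_clusters = 8L,
                       baseline_cluster_logits = NULL,
                       case_log_odds = NULL,
                       donor_sd = 0.5,
                       n_genes = 160L,
                       de_spec = NULL,
                       nb_dispersion = 0.1,
                       libsize_lognormal = c(0, 0.3),
                       mito_fail_fraction = 0.02,
                       lowgene_fail_fraction = 0.02,
                       repertoire_spec = NULL,
                       n_tcr_donors = 4L,
                       n_heart_enriched = 6L,
                       n_tumor_enriched = 7L,
                       heart_tumor_overlap_fraction = 0.25,
                       fatal_sharing_subset = "C3",
                       fatal_sharing_rate = 0.15,
                       nonfatal_sharing_rate = 0.01,
                       background_sharing_rate = 0.002,
                       serum_spec = NULL,
                       troponin_link = NULL) {
  if (is.null(baseline_cluster_logits)) {
    baseline_cluster_logits <- seq(1, -1, length.out = n_clusters)
  }
  if (is.null(case_log_odds)) {
    case_log_odds <- numeric(n_clusters)
    case_log_odds[1] <- log(4)
    case_log_odds[2] <- log(2)
    case_log_odds[n_clusters] <- log(0.5)
  }
  if (is.null(de_spec)) {
    de_spec <- list(list(cluster = "C1", genes = paste0("G", 30:49),
                         log2fc = 1))
  }
  if (is.null(repertoire_spec)) {
    repertoire_spec <- list(
      heart = list(n_clones = 120L, exponent = 1.0, total_reads = 3000L),
      tumor = list(n_clones = 150L, exponent = 1.0, total_reads = 3000L),
      control_tissue = list(n_clones = 200L, exponent = 1.0,
                            total_reads = 3000L)
    )
  }
  if (is.null(serum_spec)) {
    serum_spec <- list(n_analytes = 71L, n_shifted = 16L, log_mean = 2,
                       log_shift = 1.0, log_sd = 0.5)
  }
  if (is.null(troponin_link)) {
    troponin_link <- list(intercept = 6, slope = 1, noise_sd = 0.2,
                          cluster = "C1")
  }
  cfg <- list(
    seed = as.integer(seed),
    n_case_donors = as.integer(n_case_donors),
    n_control_donors = as.integer(n_control_donors),
    n_fatal = as.integer(n_fatal),
    cells_per_donor = as.integer(cells_per_donor),
    n_clusters = as.integer(n_clusters),
    baseline_cluster_logits = as.numeric(baseline_cluster_logits),
    case_log_odds = as.numeric(case_log_odds),
    donor_sd = donor_sd,
    n_genes = as.integer(n_genes),
    de_spec = de_spec,
    nb_dispersion = rep_len(nb_dispersion, n_genes),
    libsize_lognormal = libsize_lognormal,
    mito_fail_fraction = mito_fail_fraction,
    lowgene_fail_fraction = lowgene_fail_fraction,
    repertoire_spec = repertoire_spec,
    n_tcr_donors = as.integer(min(n_tcr_donors, n_case_donors)),
    n_heart_enriched = as.integer(n_heart_enriched),
    n_tumor_enriched = as.integer(n_tumor_enriched),
    heart_tumor_overlap_fraction = heart_tumor_overlap_fraction,
    fatal_sharing_subset = fatal_sharing_subset,
    fatal_sharing_rate = fatal_sharing_rate,
    nonfatal_sharing_rate = nonfatal_sharing_rate,
    background_sharing_rate = background_sharing_rate,
    serum_spec = serum_spec,
    troponin_link = troponin_link
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_case_donors < 1 || n_control_donors < 1 || cells_per_donor < 1 ||
        n_clusters < 1 || n_genes < 1) {
      stop("cohort counts must be positive", call. = FALSE)
    }
    if (n_fatal > n_case_donors) {
      stop("n_fatal must not exceed n_case_donors", call. = FALSE)
    }
    if (length(baseline_cluster_logits) != n_clusters ||
        length(case_log_odds) != n_clusters) {
      stop("cluster-effect vectors must have length n_clusters",
           call. = FALSE)
    }
    if (donor_sd < 0) stop("donor_sd must be >= 0", call. = FALSE)
    probs <- c(mito_fail_fraction, lowgene_fail_fraction,
               heart_tumor_overlap_fraction, fatal_sharing_rate,
               nonfatal_sharing_rate, background_sharing_rate)
    if (any(probs < 0 | probs > 1)) {
      stop("probabilities and fractions must lie in [0, 1]", call. = FALSE)
    }
    if (any(nb_dispersion <= 0)) {
      stop("nb_dispersion must be > 0", call. = FALSE)
    }
    invisible(NULL)
  })
}

cluster_names <- function(cfg) paste0("C", seq_len(cfg$n_clusters))

gene_names <- function(cfg) {
  g <- paste0("G", seq_len(cfg$n_genes))
  n_mt <- min(13L, cfg$n_genes)
  g[seq_len(n_mt)] <- MITO_GENES_13[seq_len(n_mt)]
  g
}

## Per-donor true cluster probabilities: softmax of
## baseline + case effect + donor-by-cluster random intercept.
donor_cluster_probs <- function(cfg, u, is_case) {
  logits <- matrix(cfg$baseline_cluster_logits, nrow = nrow(u),
                   ncol = cfg$n_clusters, byrow = TRUE) +
    outer(as.numeric(is_case), cfg$case_log_odds) + u
  p <- exp(logits)
  p / rowSums(p)
}

#' Generate the synthetic cohort table
#'
#' One row per donor per compartment sample (heart and blood for every
#' donor; tumor and adjacent-normal control tissue for the TCR-profiled
#' case donors). Troponin follows the configured log-linear link on the
#' designated cluster's true proportion; fatal flags are assigned to
#' exactly `n_fatal` case donors; case heart samples are labeled
#' pre-corticosteroid.
#'
#' @param config A [sim_config()].
#' @return `sample_meta` tibble; donor-level ground truth is attached as
#'   attribute `donor_truth`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  donors <- c(sprintf("case_%02d", seq_len(config$n_case_donors)),
              sprintf("ctrl_%02d", seq_len(config$n_control_donors)))
  is_case <- c(rep(TRUE, config$n_case_donors),
               rep(FALSE, config$n_control_donors))
  u <- matrix(stats::rnorm(length(donors) * config$n_clusters,
                           sd = config$donor_sd),
              nrow = length(donors),
              dimnames = list(donors, cluster_names(config)))
  props <- donor_cluster_probs(config, u, is_case)
  fatal_donors <- sample(donors[is_case], config$n_fatal)
  tl <- config$troponin_link
  k <- tl$cluster
  log_trop <- tl$intercept + tl$slope * unname(log(props[, k])) +
    stats::rnorm(length(donors), sd = tl$noise_sd)
  troponin <- ifelse(is_case, exp(log_trop), NA_real_)
  offsets <- sample(-3:3, length(donors), replace = TRUE,
                    prob = c(.05, .1, .2, .3, .2, .1, .05))
  base <- tibble::tibble(
    donor_id = donors,
    group = ifelse(is_case, "case", "control"),
    fatal = donors %in% fatal_donors,
    troponin = troponin,
    troponin_offset_days = ifelse(is_case, offsets, NA_integer_)
  )
  tcr_donors <- donors[is_case][seq_len(config$n_tcr_donors)]
  meta <- dplyr::bind_rows(
    dplyr::mutate(base, compartment = "heart",
                  steroid_timing = ifelse(.data$group == "case",
                                          "pre-corticosteroid", NA_character_)),
    dplyr::mutate(base, compartment = "blood", steroid_timing = NA_character_),
    dplyr::mutate(base[base$donor_id %in% tcr_donors, ],
                  compartment = "tumor", steroid_timing = NA_character_),
    dplyr::mutate(base[base$donor_id %in% tcr_donors, ],
                  compartment = "control_tissue",
                  steroid_timing = NA_character_)
  ) |>
    dplyr::mutate(sample_id = paste(.data$donor_id, .data$compartment,
                                    sep = "_"), .before = 1)
  attr(meta, "donor_truth") <- list(
    donors = donors, is_case = is_case, u = u, true_props = props,
    fatal_donors = fatal_donors, tcr_donors = tcr_donors
  )
  meta
}

#' Generate cells and UMI counts for the cohort
#'
#' Heart and blood cells per donor: cluster labels from the donor's
#' multinomial composition, UMI counts from a negative binomial with
#' cluster/gene base means, case fold-changes on the configured gene sets,
#' and log-normal per-cell library factors. A configured fraction of cells
#' has its QC covariates overwritten (mito fraction >= 20% or a low
#' unique-gene count) so the QC filter is exercised without disturbing the
#' count model.
#'
#' @param config A [sim_config()].
#' @param meta Output of [generate_cohort()].
#' @return List with `cell_table` and sparse `counts` (genes x cells).
#' @export
generate_cells_and_counts <- function(config, meta) {
  truth <- attr(meta, "donor_truth")
  stopifnot(!is.null(truth))
  set.seed(config$seed + 1L)
  genes <- gene_names(config)
  clusters <- cluster_names(config)
  ## base mean expression per gene per cluster
  base_mean <- matrix(exp(stats::rnorm(config$n_genes, mean = 0.5, sd = 1)),
                      nrow = config$n_genes, ncol = config$n_clusters,
                      dimnames = list(genes, clusters))
  ## cluster-distinguishing markers: each cluster gets a block of elevated
  ## genes so AUROC/OVA scans have signal
  block <- max(1L, config$n_genes %/% (2L * config$n_clusters))
  for (k in seq_len(config$n_clusters)) {
    idx <- ((k - 1L) * block + 1L):min(k * block, config$n_genes)
    base_mean[idx, k] <- base_mean[idx, k] * 6
  }
  case_fc <- matrix(1, nrow = config$n_genes, ncol = config$n_clusters,
                    dimnames = list(genes, clusters))
  for (d in config$de_spec) {
    gi <- intersect(d$genes, genes)
    case_fc[gi, d$cluster] <- 2^d$log2fc
  }
  samples <- meta[meta$compartment %in% c("heart", "blood"), ]
  per_sample <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples))) {
    s <- samples[i, ]
    d_idx <- match(s$donor_id, truth$donors)
    n_cells <- config$cells_per_donor
    cl <- sample(clusters, n_cells, replace = TRUE,
                 prob = truth$true_props[d_idx, ])
    lib <- stats::rlnorm(n_cells, config$libsize_lognormal[1],
                         config$libsize_lognormal[2])
    fc <- if (s$group == "case") case_fc else
      matrix(1, config$n_genes, config$n_clusters, dimnames = dimnames(case_fc))
    mu <- base_mean[, cl, drop = FALSE] * fc[, cl, drop = FALSE]
    mu <- sweep(mu, 2, lib, `*`)
    cnt <- matrix(stats::rnbinom(length(mu), mu = mu,
                                 size = rep(1 / config$nb_dispersion,
                                            times = n_cells)),
                  nrow = config$n_genes)
    barcodes <- sprintf("%s-%04d", s$sample_id, seq_len(n_cells))
    dimnames(cnt) <- list(genes, barcodes)
    ## QC covariates: most cells pass; configured fractions fail
    mito_frac <- stats::runif(n_cells, 0, 0.15)
    thr <- if (s$compartment == "blood") 400L else 300L
    n_genes_cov <- thr + 1L + stats::rpois(n_cells, 150)
    fail_m <- stats::runif(n_cells) < config$mito_fail_fraction
    fail_g <- stats::runif(n_cells) < config$lowgene_fail_fraction
    mito_frac[fail_m] <- stats::runif(sum(fail_m), 0.20, 0.6)
    n_genes_cov[fail_g] <- sample(seq_len(thr), sum(fail_g), replace = TRUE)
    per_sample[[i]] <- list(
      cells = tibble::tibble(
        barcode = barcodes,
        sample_id = s$sample_id,
        donor_id = s$donor_id,
        compartment = s$compartment,
        group = s$group,
        cluster = cl,
        mito_frac = mito_frac,
        n_genes = n_genes_cov,
        clone_key = NA_character_
      ),
      counts = cnt
    )
  }
  cell_table <- dplyr::bind_rows(lapply(per_sample, `[[`, "cells"))
  counts <- methods::as(
    Matrix::Matrix(do.call(cbind, lapply(per_sample, `[[`, "counts")),
                   sparse = TRUE), "CsparseMatrix")
  list(cell_table = cell_table, counts = counts,
       truth_expression = list(base_mean = base_mean, case_fc = case_fc))
}

## Truncated power-law rank-frequency distribution over n clones.
powerlaw_freqs <- function(n_clones, exponent) {
  f <- seq_len(n_clones)^(-exponent)
  f / sum(f)
}

#' Generate bulk TCR-beta repertoires and blood clonotype assignments
#'
#' Every case donor receives a power-law heart repertoire with boosted
#' (expansion-triggering) clones. The tumor-profiled subset additionally
#' gets tumor and adjacent-normal control repertoires drawn from a shared
#' bystander pool, where only the designated heart-enriched and
#' tumor-enriched truth clones (overlapping by the configured fraction)
#' differ in frequency from control; read counts are multinomial at the
#' configured depth.
#' Blood cells of fatal donors receive heart-expanded clone keys within
#' the designated subset at `fatal_sharing_rate` (non-fatal case donors at
#' `nonfatal_sharing_rate`, other subsets at `background_sharing_rate`);
#' heart T cells of those donors carry clone keys drawn from the heart
#' repertoire.
#'
#' @param config A [sim_config()].
#' @param meta Output of [generate_cohort()].
#' @param cell_table Output of [generate_cells_and_counts()] (used to
#'   attach per-cell clonotype keys).
#' @return List with `clone_tables` (tibble: donor, tissue, clone_key,
#'   count, frequency), `cell_table` (clone keys filled in), and `truth`
#'   (per-donor enriched sets and sharing assignments).
#' @export
generate_repertoires <- function(config, meta, cell_table) {
  truth <- attr(meta, "donor_truth")
  stopifnot(!is.null(truth))
  if (config$heart_tumor_overlap_fraction > 1) {
    stop("overlap fraction must be <= 1", call. = FALSE)
  }
  set.seed(config$seed + 2L)
  spec <- config$repertoire_spec
  clone_rows <- list()
  truth_rep <- list()
  cell_table <- tibble::as_tibble(cell_table)
  case_donors <- truth$donors[truth$is_case]
  sample_freqs <- function(freqs, total_reads) {
    cnt <- stats::rmultinom(1, total_reads, freqs)[, 1]
    cnt <- cnt[cnt > 0]
    tibble::tibble(clone_key = names(cnt), count = as.integer(cnt),
                   frequency = cnt / sum(cnt))
  }
  for (don in case_donors) {
    has_tumor <- don %in% truth$tcr_donors
    n_he <- config$n_heart_enriched
    if (!has_tumor) {
      ## heart-only donor: power-law repertoire with n_he clones boosted
      ## past the expansion threshold so a heart-expanded set exists
      n <- spec$heart$n_clones
      clones <- sprintf("TRBV%02d|%s_NT%04d",
                        sample(1:30, n, replace = TRUE), don, seq_len(n))
      f <- powerlaw_freqs(n, spec$heart$exponent)[sample(n)]
      names(f) <- clones
      f[seq_len(n_he)] <- stats::runif(n_he, 0.012, 0.05)
      f <- f / sum(f)
      clone_rows[[paste(don, "heart")]] <- dplyr::mutate(
        sample_freqs(f, spec$heart$total_reads),
        donor_id = don, tissue = "heart", .before = 1)
      next
    }
    ## tumor-profiled donor: heart/tumor/control share one bystander pool;
    ## only the designated clones differ in frequency from control
    n_ctrl <- spec$control_tissue$n_clones
    universe <- sprintf("TRBV%02d|%s_NT%04d",
                        sample(1:30, n_ctrl, replace = TRUE), don,
                        seq_len(n_ctrl))
    ctrl_f <- powerlaw_freqs(n_ctrl, spec$control_tissue$exponent)[
      sample(n_ctrl)]
    names(ctrl_f) <- universe
    n_sh <- round(config$heart_tumor_overlap_fraction * n_he)
    n_te <- config$n_tumor_enriched
    ## enriched truth clones are rare in control: pick from the tail
    rare <- names(sort(ctrl_f))[seq_len(n_he + n_te - n_sh)]
    heart_enr <- rare[seq_len(n_he)]
    tumor_enr <- c(heart_enr[seq_len(n_sh)],
                   rare[n_he + seq_len(n_te - n_sh)])
    boost <- function(enriched) {
      f <- ctrl_f
      f[enriched] <- stats::runif(length(enriched), 0.012, 0.05)
      f / sum(f)
    }
    tabs <- list(
      heart = sample_freqs(boost(heart_enr), spec$heart$total_reads),
      tumor = sample_freqs(boost(tumor_enr), spec$tumor$total_reads),
      control_tissue = sample_freqs(ctrl_f,
                                    spec$control_tissue$total_reads)
    )
    for (tis in names(tabs)) {
      clone_rows[[paste(don, tis)]] <- dplyr::mutate(
        tabs[[tis]], donor_id = don, tissue = tis, .before = 1)
    }
    truth_rep[[don]] <- list(heart_enriched = heart_enr,
                             tumor_enriched = tumor_enr,
                             shared_enriched = intersect(heart_enr, tumor_enr))
  }
  clone_tables <- dplyr::bind_rows(clone_rows)
  ## expanded heart clone sets per donor (the generator's own bookkeeping
  ## uses the same >0.5% & count>=2 rule as the pipeline)
  heart_expanded <- clone_tables |>
    dplyr::filter(.data$tissue == "heart",
                  .data$frequency > 0.005, .data$count >= 2) |>
    dplyr::group_by(.data$donor_id) |>
    dplyr::summarise(keys = list(.data$clone_key), .groups = "drop")
  exp_sets <- stats::setNames(heart_expanded$keys, heart_expanded$donor_id)
  ## blood cells: assign heart-expanded keys by subset and outcome
  is_blood <- cell_table$compartment == "blood"
  sharing <- list()
  for (don in names(exp_sets)) {
    keys <- exp_sets[[don]]
    rows <- which(is_blood & cell_table$donor_id == don)
    if (!length(rows) || !length(keys)) next
    fatal <- don %in% truth$fatal_donors
    in_subset <- cell_table$cluster[rows] == config$fatal_sharing_subset
    rate <- ifelse(in_subset,
                   if (fatal) config$fatal_sharing_rate else
                     config$nonfatal_sharing_rate,
                   config$background_sharing_rate)
    hit <- stats::runif(length(rows)) < rate
    cell_table$clone_key[rows[hit]] <- sample(keys, sum(hit), replace = TRUE)
    sharing[[don]] <- sum(hit)
  }
  ## heart cells of repertoire-bearing donors: clone keys drawn from the
  ## heart repertoire
  for (don in unique(clone_tables$donor_id)) {
    ht <- clone_tables[clone_tables$donor_id == don &
                         clone_tables$tissue == "heart", ]
    rows <- which(cell_table$compartment == "heart" &
                    cell_table$donor_id == don)
    if (!length(rows) || !nrow(ht)) next
    captured <- stats::runif(length(rows)) < 0.5
    cell_table$clone_key[rows[captured]] <-
      sample(ht$clone_key, sum(captured), replace = TRUE, prob = ht$frequency)
  }
  list(
    clone_tables = clone_tables,
    cell_table = cell_table,
    truth = list(enriched = truth_rep, heart_expanded = exp_sets,
                 n_shared_cells = sharing)
  )
}

#' Generate the serum analyte panel
#'
#' Log-normal analyte values per donor; the configured number of analytes
#' is shifted upward (on the log scale) in case donors.
#'
#' @param config A [sim_config()].
#' @param meta Output of [generate_cohort()].
#' @return List with `serum_table` (donor_id, group, analyte, value) and
#'   `truth` (names of shifted analytes).
#' @export
generate_serum <- function(config, meta) {
  truth <- attr(meta, "donor_truth")
  stopifnot(!is.null(truth))
  set.seed(config$seed + 3L)
  sp <- config$serum_spec
  analytes <- sprintf("analyte_%02d", seq_len(sp$n_analytes))
  shifted <- analytes[seq_len(sp$n_shifted)]
  grid <- tidyr::expand_grid(donor_id = truth$donors, analyte = analytes)
  grid$group <- ifelse(truth$is_case[match(grid$donor_id, truth$donors)],
                       "case", "control")
  shift <- ifelse(grid$analyte %in% shifted & grid$group == "case",
                  sp$log_shift, 0)
  grid$value <- exp(stats::rnorm(nrow(grid), sp$log_mean + shift, sp$log_sd))
  list(serum_table = grid, truth = list(shifted_analytes = shifted))
}

#' Simulate a full synthetic study
#'
#' Runs the cohort, cell/count, repertoire and serum generators in order
#' and bundles everything with the complete ground-truth record, which is
#' sufficient to score every downstream recovery test.
#'
#' @param config A [sim_config()].
#' @return A `sim_study` list: `sample_meta`, `cell_table`, `counts`,
#'   `clone_tables`, `serum_table`, `truth`, `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  meta <- generate_cohort(config)
  cc <- generate_cells_and_counts(config, meta)
  rep_out <- generate_repertoires(config, meta, cc$cell_table)
  ser <- generate_serum(config, meta)
  donor_truth <- attr(meta, "donor_truth")
  structure(list(
    sample_meta = meta,
    cell_table = rep_out$cell_table,
    counts = cc$counts,
    clone_tables = rep_out$clone_tables,
    serum_table = ser$serum_table,
    truth = list(
      donor = donor_truth,
      expression = cc$truth_expression,
      repertoire = rep_out$truth,
      serum = ser$truth,
      config = config
    ),
    config = config
  ), class = "sim_study")
}
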