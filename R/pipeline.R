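#' Default pipeline configuration
#'
#' All thresholds default to the study's published rules: QC mito < 20%
#' and unique genes > 300 (heart) / > 400 (blood); abundance FDR < 10%;
#' marker AUROC >= 0.75 and OVA FDR < 0.05; DE FDR < 0.1; expansion
#' > 0.5% with count >= 2; enrichment FDR < 0.05; sharing FDR < 0.05;
#' interaction filters > 10% expressed, >= 20 cells, empirical P < 0.001;
#' diversity minimum 100 sequences; troponin offset within 2 days.
#'
#' @param seed Integer seed used for every stochastic stage.
#' @param out_dir Output directory for result tables and the manifest.
#' @param stages Character vector of stages to run, in dependency order a
#'   subset of `c("simulate", "qc", "abundance", "markers", "de", "tcr",
#'   "sharing", "interactions", "serum")`.
#' @param sim Optional [sim_config()] (defaults to `sim_config(seed)`).
#' @param thresholds Named list of threshold overrides (recorded in the
#'   manifest).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("icimyo_run_"),
                            stages = c("simulate", "qc", "abundance",
                                       "markers", "de", "tcr", "sharing",
                                       "interactions", "serum"),
                            sim = NULL, thresholds = list()) {
  defaults <- list(
    abundance_fdr = 0.10, marker_auroc = 0.75, marker_fdr = 0.05,
    de_fdr = 0.1, expansion_freq = 0.005, expansion_count = 2L,
    enrichment_fdr = 0.05, sharing_fdr = 0.05,
    interaction_min_frac = 0.10, interaction_min_cells = 20L,
    interaction_p = 0.001, interaction_B = 1000L,
    diversity_min_sequences = 100L, troponin_offset_days = 2
  )
  thr <- utils::modifyList(defaults, thresholds)
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 stages = stages,
                 sim = sim %||% sim_config(seed = seed),
                 thresholds = thr,
                 overridden = names(thresholds)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with optional `seed`, `out_dir`, `stages`,
#'   `thresholds`, and `sim` (passed to [sim_config()]) entries.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$sim)) do.call(sim_config, y$sim) else NULL
  default_stages <- c("simulate", "qc", "abundance", "markers", "de",
                      "tcr", "sharing", "interactions", "serum")
  pipeline_config(seed = y$seed %||% 1L,
                  out_dir = y$out_dir %||% tempfile("icimyo_run_"),
                  stages = unlist(y$stages) %||% default_stages,
                  sim = sim,
                  thresholds = y$thresholds %||% list())
}

#' Run the analysis pipeline on a synthetic study
#'
#' Executes the requested stages in dependency order on a freshly
#' simulated study, writes one TSV per result table into `out_dir`, and
#' records a JSON manifest with the configuration hash and seed. Rerunning
#' with an identical configuration reproduces the outputs bit for bit.
#'
#' @param config A [pipeline_config()] or path to a YAML file.
#' @return Invisibly, a list of the in-memory result tables plus
#'   `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  thr <- config$thresholds
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list(out_dir = config$out_dir)
  log_path <- file.path(config$out_dir, "pipeline.log")
  log_line <- function(...) {
    cat(paste0(..., collapse = ""), "\n", file = log_path, append = TRUE)
  }
  run_stage <- function(name, fn) {
    if (!name %in% config$stages) return(invisible(NULL))
    log_line("stage ", name)
    tryCatch(fn(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  study <- NULL
  run_stage("simulate", function() {
    study <<- simulate_study(config$sim)
  })
  if (is.null(study)) {
    stop("non-simulated inputs are not configured; include the ",
         "'simulate' stage", call. = FALSE)
  }

  filtered <- NULL; logcpm <- NULL; pb <- NULL
  run_stage("qc", function() {
    filtered <<- qc_filter(study$cell_table, study$counts)
    logcpm <<- log_normalize(filtered$counts)
    if (!is.null(filtered$qc_report)) {
      readr::write_tsv(filtered$qc_report,
                       file.path(config$out_dir, "qc_report.tsv"),
                       progress = FALSE)
    }
  })
  need_cells <- function() {
    if (is.null(filtered)) stop("requires the 'qc' stage", call. = FALSE)
  }

  heart_idx <- function() filtered$cell_table$compartment == "heart"

  run_stage("abundance", function() {
    need_cells()
    cells <- filtered$cell_table[heart_idx(), ]
    ab <- diff_abundance(cells, fdr_threshold = thr$abundance_fdr)
    results$abundance <<- ab
    write_result_table(ab, file.path(config$out_dir, "abundance.tsv"))
    fr <- cluster_fractions(cells)
    sev <- severity_regression(fr, study$sample_meta,
                               max_offset_days = thr$troponin_offset_days)
    results$severity <<- sev
    write_result_table(sev, file.path(config$out_dir, "severity.tsv"))
  })

  run_stage("markers", function() {
    need_cells()
    hx <- which(heart_idx())
    cells <- filtered$cell_table[hx, ]
    pbh <- pseudobulk_sum(filtered$counts[, hx, drop = FALSE], cells)
    mk <- marker_scan(logcpm[, hx, drop = FALSE], cells, pbh,
                      auroc_threshold = thr$marker_auroc)
    results$markers <<- mk
    write_result_table(mk, file.path(config$out_dir, "markers.tsv"))
  })

  run_stage("de", function() {
    need_cells()
    hx <- which(heart_idx())
    cells <- filtered$cell_table[hx, ]
    pb <<- pseudobulk_sum(filtered$counts[, hx, drop = FALSE], cells)
    de <- de_by_subset(pb, study$sample_meta)
    results$de <<- de
    write_result_table(de, file.path(config$out_dir, "de.tsv"))
  })

  run_stage("tcr", function() {
    ct <- study$clone_tables
    donors <- unique(ct$donor_id)
    enr <- purrr::map(donors, function(don) {
      ctrl <- ct[ct$donor_id == don & ct$tissue == "control_tissue", ]
      if (nrow(ctrl) == 0) return(NULL)
      purrr::map(c("heart", "tumor"), function(tis) {
        tt <- ct[ct$donor_id == don & ct$tissue == tis, ]
        if (nrow(tt) == 0) return(NULL)
        dplyr::mutate(
          tissue_enrichment(tt, ctrl, tissue = tis,
                            fdr_threshold = thr$enrichment_fdr),
          donor_id = don, .before = 1)
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
    results$enrichment <<- enr
    write_result_table(enr, file.path(config$out_dir, "enrichment.tsv"))
    results$overlap <<- heart_tumor_overlap(
      enr[enr$tissue == "heart", ], enr[enr$tissue == "tumor", ])
    write_result_table(results$overlap,
                       file.path(config$out_dir, "overlap.tsv"))
    div <- purrr::map(donors, function(don) {
      tt <- ct[ct$donor_id == don & ct$tissue == "heart", ]
      if (sum(tt$count) < thr$diversity_min_sequences) return(NULL)
      dplyr::mutate(hill_diversity(
        tt, min_sequences = thr$diversity_min_sequences),
        donor_id = don, .before = 1)
    }) |> dplyr::bind_rows()
    results$diversity <<- div
    write_result_table(div, file.path(config$out_dir, "diversity.tsv"))
  })

  run_stage("sharing", function() {
    need_cells()
    ct <- study$clone_tables
    expanded <- ct |>
      dplyr::filter(.data$tissue == "heart") |>
      dplyr::group_by(.data$donor_id) |>
      dplyr::group_modify(~ call_expanded(.x)) |>
      dplyr::ungroup() |>
      dplyr::filter(.data$expanded)
    exp_sets <- split(expanded$clone_key, expanded$donor_id)
    blood <- filtered$cell_table[filtered$cell_table$compartment ==
                                   "blood", ]
    flagged <- suppressMessages(
      mark_heart_expanded_in_blood(blood, exp_sets))
    sh <- subset_sharing_test(flagged, fdr_threshold = thr$sharing_fdr)
    results$sharing <<- sh
    write_result_table(sh, file.path(config$out_dir, "sharing.tsv"))
  })

  run_stage("serum", function() {
    ser <- serum_compare(study$serum_table)
    results$serum <<- ser
    write_result_table(ser, file.path(config$out_dir, "serum.tsv"))
  })

  run_stage("interactions", function() {
    need_cells()
    if (is.null(results$de)) stop("requires the 'de' stage", call. = FALSE)
    hx <- which(heart_idx())
    genes <- rownames(logcpm)
    pairs <- tibble::tibble(ligand = genes[31:34], receptor = genes[41:44])
    pt <- permutation_test(logcpm[, hx, drop = FALSE],
                           filtered$cell_table[hx, ], pairs,
                           B = thr$interaction_B, seed = config$seed,
                           min_frac = thr$interaction_min_frac,
                           min_cells = thr$interaction_min_cells,
                           p_threshold = thr$interaction_p)
    enriched <- if (!is.null(results$abundance)) {
      results$abundance$cluster[results$abundance$significant]
    } else character()
    fi <- filter_interactions(pt, results$de, enriched, pairs,
                              de_fdr = thr$de_fdr)
    results$interactions <<- fi
    write_result_table(fi, file.path(config$out_dir, "interactions.tsv"))
  })

  manifest <- list(
    seed = config$seed,
    stages = config$stages,
    thresholds = thr,
    overridden_thresholds = config$overridden,
    config_hash = rlang::hash(config[c("seed", "stages", "sim",
                                       "thresholds")]),
    package_version = as.character(utils::packageVersion("icimyo"))
  )
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(results, list(manifest = manifest)))
}
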