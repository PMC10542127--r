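# icimyo

Statistical machinery for multi-compartment single-cell and TCR-beta
repertoire studies of immune-checkpoint-inhibitor (ICI) myocarditis — a
rare, often fatal autoimmune toxicity of cancer immunotherapy in which
T cells infiltrate the myocardium.

Studies of this condition profile heart tissue, blood, tumor, adjacent
normal tissue, and serum from the same patients. `icimyo` implements the
full analysis chain connecting those compartments:

* **Differential cell-subset abundance** — for each subset, a
  mixed-effects logistic regression
  `cluster ~ 1 + outcome + (1|donor)` fit by 25-node adaptive
  Gauss–Hermite quadrature on donor-collapsed binomial counts, compared
  to the null model by likelihood-ratio test with BH FDR (< 10%
  significant); plus the severity regression
  `log(troponin) ~ log(abundance)` with a ±2-day matching window.
* **Marker genes** — per-subset AUROC (≥ 0.75 rule) and one-versus-all
  moderated-t on `log2(CPM + 0.5)` pseudobulk with an empirical-Bayes
  variance prior `s²_g ~ s₀² F(d, d₀)` (FDR < 0.05 and log2FC > 0).
* **Case–control DE** — pseudobulk negative-binomial Wald test with
  median-of-ratios size factors and trimmed-mean dispersion shrinkage
  (FDR < 0.1).
* **TCR-beta repertoire analytics** — clonal expansion (> 0.5% of the
  repertoire and ≥ 2 reads/cells), control-tissue-normalized enrichment
  (one-sided Fisher exact, FDR < 5%), Hill diversity profiles
  `qD = (Σ pᵢ^q)^(1/(1−q))` over orders 0–4 (≥ 100 sequences), and
  heart–tumor overlap summaries.
* **Heart–blood clone sharing** — per-donor logistic LRT
  `in_subset ~ 1 + myo_clone` over blood subsets (FDR < 5%) and the
  fatal-outcome Fisher test.
* **Receptor–ligand interactions** — permutation-based mean-of-means
  scoring with the > 10% / ≥ 20-cell expression filters, strict
  empirical P < 0.001, and DE/abundance/curation filters.
* **Serum statistics** — Welch t on `ln(x + 1)` per analyte; IHC density
  fold comparisons.
* **Synthetic cohort generator** — donor-clustered multinomial
  composition, negative-binomial expression, power-law repertoires with
  planted enriched clones, configurable heart–blood sharing, log-normal
  serum — with a complete ground-truth record, so every stage above is
  testable end to end.

Everything is tibble-in / tibble-out and pipe-friendly; fitted objects
have `tidy()`/`glance()` methods and result tables have `autoplot()`
methods.

## Worked example

```r
library(icimyo)

cfg   <- sim_config(seed = 42)          # 12 cases vs 8 controls, 4 fatal
study <- simulate_study(cfg)

qc    <- qc_filter(study$cell_table, study$counts)
heart <- qc$cell_table[qc$cell_table$compartment == "heart", ]
diff_abundance(heart)
#> # A tibble: 8 × 7
#>   cluster    OR ci_low ci_high           p        fdr significant
#>   <chr>   <dbl>  <dbl>   <dbl>       <dbl>      <dbl> <lgl>
#> 1 C1      6.06  3.61    10.2   0.000000890 0.00000330 TRUE
#> 2 C2      0.985 0.629    1.54  0.947       0.947      FALSE
#> 3 C3      0.277 0.157    0.488 0.000192    0.000383   TRUE
#> 4 C4      0.435 0.280    0.674 0.00113     0.00181    TRUE
#> ...
```

The generator plants a four-fold abundance increase on subset C1 in
cases; the fit recovers it (OR 6.1, CI 3.6–10.2, significant at
FDR < 10%). Because compositions sum to one, a strong increase in one
subset depresses the measured odds of the others — visible above and
inherent to compositional data, not an artifact of the model.

Published-input statistics are one call away:

```r
fatal_association_test(
  sharing = c(rep(TRUE, 3), FALSE, TRUE, rep(FALSE, 8)),
  fatal   = c(rep(TRUE, 4), rep(FALSE, 9)))$p
#> 0.05174825   # prints as p = 0.052

overlap_from_counts(n_heart = 19, n_tumor = 28, n_shared = 5)
#>   n_shared pct_of_heart_display pct_of_tumor_display
#> 1        5                  26%                  18%
```

The first reproduces the fatal-vs-non-fatal sharing comparison (3 of 4
fatal vs 1 of 9 non-fatal patients with significant sharing of
heart-expanded clones in the cycling blood CD8 subset); the second, the
heart–tumor enriched-clone overlap percentages.

A full configuration-driven run (`simulate → qc → abundance → markers →
de → tcr → sharing → interactions → serum`) with per-stage TSV outputs
and a JSON manifest:

```r
res <- run_pipeline(pipeline_config(seed = 1))
list.files(res$out_dir)
```

## Package layout

| Module | Contents |
| --- | --- |
| `R/synthetic-cohort.R` | `sim_config()`, `simulate_study()`, per-stage generators |
| `R/io-formats.R` | MTX/TSV count matrices, AIRR/immunoSEQ clone tables, contig CSVs, result writers |
| `R/preprocess.R` | QC filter, logCPM, pseudobulk, expression summaries |
| `R/abundance.R` | mixed logistic fit, `diff_abundance()`, severity regression |
| `R/markers.R` | AUROC scan, variance prior, OVA moderated t |
| `R/case-control-de.R` | size factors, NB Wald DE |
| `R/tcr-repertoire.R` | expansion, enrichment, Hill diversity, overlap |
| `R/sharing.R` | clone flagging, subset sharing tests, fatal association |
| `R/interactions.R` | interaction statistic, permutation test, filters |
| `R/serum-misc.R` | serum comparison, density folds |
| `R/pipeline.R` | YAML config, staged `run_pipeline()` |

The methods vignette (`vignettes/icimyo-methods.Rmd`) documents the
models, the generator's assumptions, numerical choices, and known
limitations.
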