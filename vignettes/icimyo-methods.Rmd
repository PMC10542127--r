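---
title: "Statistical methods for multi-compartment single-cell and TCR studies of checkpoint-inhibitor myocarditis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for multi-compartment single-cell and TCR studies of checkpoint-inhibitor myocarditis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icimyo)
```

# The setting

Immune-checkpoint-inhibitor (ICI) myocarditis is a rare, frequently fatal
autoimmune toxicity of cancer immunotherapy. Studies of this condition
profile several compartments of the same patients — heart tissue
(scRNA-seq and bulk TCR-beta sequencing), peripheral blood (scRNA-seq with
single-cell TCR), tumor and adjacent normal tissue (bulk TCR-beta), and
serum — and ask a linked set of questions: which cell subsets expand in
the inflamed heart, what those subsets express, whether the infiltrating
T-cell clones are the anti-tumor clones or a distinct population, whether
heart-expanded clones can be monitored in blood, which receptor–ligand
circuits connect the expanded subsets, and which serum proteins shift.

`icimyo` implements that analysis chain as reusable, tested components,
together with a synthetic-cohort generator whose ground truth makes every
stage verifiable end to end without patient data.

# Models and procedures

## Differential cell-subset abundance

For each cell subset $k$, every cell is a Bernoulli outcome
("in subset $k$" or not) and the model is a mixed-effects logistic
regression

$$\mathrm{logit}\,P(\text{cell} \in k)
  = \beta_0 + \beta_1\,\mathrm{case} + u_d,\qquad
  u_d \sim \mathcal N(0, \sigma^2),$$

with a random intercept per donor $d$. Significance is a likelihood-ratio
test against the model without $\beta_1$, with Benjamini–Hochberg FDR
across subsets and significance declared at FDR < 10%.

Because the covariate is constant within donor, the cell-level Bernoulli
likelihood collapses exactly to donor-level binomial counts
$(y_d, n_d)$; `fit_mixed_logistic()` maximizes the marginal likelihood

$$L = \prod_d \int \mathrm{Bin}\!\left(y_d \mid n_d,
  \mathrm{logit}^{-1}(\beta_0 + \beta_1 x_d + u)\right)
  \varphi(u; 0, \sigma^2)\, du$$

with the integral evaluated by 25-node adaptive Gauss–Hermite quadrature
centered at each donor's conditional mode. Twenty-five nodes make the
quadrature essentially exact for binomial random-intercept models (the
test suite verifies agreement with brute-force numerical integration and
with an independent mixed-model implementation to three decimals or
better). The variance is parameterized as $\log\sigma$ and bounded; when
the estimate hits the lower boundary ($\hat\sigma \approx 0$) the model
degenerates to pooled logistic regression, which is then refit directly
and its likelihood used in the LRT — without this the LRT statistic picks
up optimizer noise at the boundary. The Wald 95% CI on
$\mathrm{OR} = e^{\beta_1}$ uses the observed-information standard error;
complete separation is flagged `unstable` rather than hidden.

Severity is linked to composition by per-subset ordinary least squares of
$\log(\text{troponin}) \sim \log(\text{abundance})$, using each donor's
troponin measurement taken within ±2 days of tissue collection; samples
with zero fractions (log undefined) are excluded with a message, and
perfect or constant-response fits are resolved deterministically rather
than through the 0/0 t-statistic.

## Quality control and normalization

Droplet QC keeps a cell iff its mitochondrial UMI fraction is strictly
below 20% and its unique-gene count strictly exceeds 300 (heart tissue)
or 400 (blood). The mitochondrial fraction is computed from a fixed
13-gene list (`MITO_GENES_13`) even if the annotation carries other MT-
features. Expression is normalized to
$\mathrm{logCPM} = \log(1 + 10^5\, c_{gj} / \mathrm{total}_j)$ (natural
log); zeros map to zeros so sparse structure is preserved. "Unique genes"
counts all annotated features with nonzero UMIs, a choice that matters
only for near-threshold cells.

## Marker genes

Two complementary scans per subset:

* **AUROC** of each gene's logCPM as a classifier of subset membership,
  computed from the Mann–Whitney U statistic with mid-rank ties; genes
  with AUROC ≥ 0.75 are markers. The statistic is invariant to monotone
  transforms of expression.
* **One-versus-all moderated t** on pseudobulk: UMI counts are summed
  over each sample-by-subset unit, transformed as
  $\log_2(\mathrm{CPM} + 0.5)$, and fit with the two-group model
  `gene ~ in_clust`. Gene variances are shrunk toward an empirical-Bayes
  prior: the scaled-F model $s_g^2 \sim s_0^2 F(d, d_0)$ is fit by
  matching the mean and variance of $\log s_g^2$ (the trigamma-inverse
  method), giving posterior variances
  $\tilde s_g^2 = (d_0 s_0^2 + d\, s_g^2)/(d_0 + d)$ and a t-statistic
  on $d + d_0$ degrees of freedom. Markers are FDR < 0.05 with positive
  log2 fold change.

The transform uses a 0.5 offset and unweighted fits; precision weighting
of units by depth (voom-style) is deliberately omitted for parsimony,
since the downstream use of the scan is marker ranking rather than
effect-size estimation. When all gene variances are exactly equal the
prior df is reported as infinite with $s_0^2$ equal to the common value
(no sampling-noise correction is applied to data that show none).

## Case–control differential expression

Pseudobulk counts per subset are tested with a negative-binomial Wald
test: per gene, an NB log-link GLM `gene ~ case` with
$\log s_j$ offsets, where size factors $s_j$ are median-of-ratios over
genes nonzero in every unit (total-count ratios as fallback). Gene-wise
dispersions are estimated by profile maximum likelihood around
Poisson-fitted means, then shrunk on the log scale toward the 20%
trimmed mean, with shrinkage weight from the decomposition of the
observed spread of log-dispersions into sampling noise (bounded by the
trigamma of the residual df) and biological spread (floored at 0.05 so
shrinkage never becomes total); dispersions are floored at $10^{-8}$.
Significance is FDR < 0.1 on the two-sided normal Wald p.

This is a deliberate simplification of the full DESeq2 procedure: no
Cook's-distance outlier replacement, no independent filtering, no
fold-change shrinkage. Those refinements matter for effect-size ranking
in large designs; the scientific content consumed downstream is the Wald
p and the FDR < 0.1 rule. The Wald test is asymptotic: at very small unit
counts (around 6 per group) it is mildly anticonservative, and the
calibration suite therefore measures it at 10 units per group, the
regime of the emulated study (12 cases vs 8 controls).

## TCR-beta repertoire analytics

* **Expansion**: a clone is expanded if it exceeds 0.5% of the specimen
  repertoire (strict) *and* has ≥ 2 reads (bulk) or ≥ 2 cells
  (single-cell).
* **Enrichment**: expanded clones are tested against the matched
  adjacent-normal ("control") tissue by Fisher's exact test on
  $[(c_t, N_t - c_t), (c_c, N_c - c_c)]$, one-sided (greater in tissue)
  because enrichment is a directional claim and the purpose of the
  control tissue is to exclude ubiquitous bystander clones; a two-sided
  option exists. BH FDR over the candidates, enriched at FDR < 5%.
  Frequencies, not absolute counts, carry the comparison — sequencing
  recovery differs across tissues. For plotting, the normalized
  proportion divides tissue frequency by control frequency with a
  pseudo-denominator $0.5/N_c$ when the clone is absent from control;
  the test itself always uses the true zero.
* **Diversity**: Hill numbers
  $^qD = \left(\sum_i p_i^q\right)^{1/(1-q)}$ over orders 0–4, with the
  Shannon limit at $q = 1$, refused for specimens under 100 sequences.
  Optional rarefaction resamples the repertoire multinomially to a fixed
  depth (200 seeded bootstraps by default) and averages the profile.
* **Overlap**: heart-enriched and tumor-enriched clone sets are
  intersected; percentages are kept exact and rounded to whole percent
  for display.

Clone identity is V gene (allele stripped) plus CDR3 nucleotide
junction, with an amino-acid fallback key available behind a switch —
nucleotide matching is the stricter default for joining bulk and
single-cell data from different platforms.

## Heart–blood clone sharing

Per donor, blood cells are flagged `myo_clone = 1` when their clone key
lies in that donor's union of bulk- and single-cell-expanded heart clone
sets (bulk and single-cell data are analyzed together; cross-donor
matches are never flagged). Each blood subset is then tested with a
plain logistic model `in_subset ~ 1 + myo_clone` against the
intercept-only null by LRT — per donor, exactly as specified, with BH
FDR across that donor's subsets and significance at FDR < 5%. A pooled
variant with a donor random intercept (reusing the abundance machinery)
is available for across-patient claims, clearly labeled, because the
per-donor formula does not define that pooled model. The fatal-outcome
association is the two-sided Fisher exact test on the 2×2 of donors
(significant sharing in the designated subset × fatal outcome). Shared
clones are also mapped back onto heart T subsets, with donors
contributing ≤ 10 qualifying intracardiac cells flagged low-evidence.

## Receptor–ligand interactions

For each curated (ligand, receptor) pair and each ordered (sender,
receiver) subset pair, the statistic is the mean of the two cluster mean
expressions, computed only when each gene is expressed in strictly more
than 10% of its cluster and both clusters have at least 20 cells. The
null shuffles subset labels over cells; one shared set of $B$
permutations (default 1000) serves all pairs, and the add-one estimator
$p = (1 + \#\{T_b \ge T_{obs}\})/(1 + B)$ avoids zero p-values. The
significance rule is strict ($p < 0.001$), so at $B = 999$ the smallest
attainable p (0.001) does not pass — $B$ must exceed 999. Final calls
additionally require a differentially expressed ligand or receptor
(FDR < 0.1) in the corresponding cluster, a disease-enriched sender or
receiver, and membership of the curated literature list, which is a
mandatory input. Heteromeric complexes are not modeled — pairs only.
Case and control cell sets are scored in separate runs.

## Serum and density statistics

Serum analytes are compared case vs control on $\ln(x+1)$ with a
two-sided Welch t-test — the unequal-variance form is the safer default
when the variance assumption is unstated; a pooled-variance option
exists. Raw p-values are reported with a p < 0.05 flag and no
multiplicity adjustment, matching the reporting convention of the
emulated analysis (noted in output metadata). Immunohistochemistry
density comparisons report the ratio of region means (cells per $10^5$
total cells) with a one-sided two-sample t-test.

# The synthetic cohort

`sim_config()` fixes the study conditions; `simulate_study()` draws a
full study from them. Defaults mirror the emulated design: 12
pre-corticosteroid case donors vs 8 controls, 4 fatal cases, 4 case
donors with tumor and adjacent-normal TCR repertoires, a 71-analyte
serum panel with 16 analytes shifted in cases.

* **Composition**: each donor's cells are multinomial over subsets with
  logits (baseline) + (case effect) + (random intercept drawn per donor
  *per cluster*). Per-cluster draws make each per-cluster abundance fit
  exactly correctly specified, matching the fitted model.
* **Expression**: per-cell UMI counts are negative binomial with
  cluster-and-gene base means, configured case fold-changes, and
  log-normal library factors independent of cluster (so depth effects
  cannot masquerade as abundance effects). Cells failing QC are injected
  by overwriting the QC covariates, not the counts, keeping the count
  model clean.
* **Repertoires**: truncated power-law rank-frequency clone
  distributions per tissue (the shape is a modeling choice — the
  emulated study reports no repertoire distribution), with designated
  enriched clones boosted well past the expansion threshold while
  bystander clones share the control-tissue frequency distribution; the
  heart- and tumor-enriched truth sets overlap by a configured fraction.
  Blood cells of fatal donors carry heart-expanded clone keys in a
  designated subset at a high rate (default 0.15), non-fatal case donors
  at a low rate (0.01), other subsets at a background rate (0.002).
* **Serum**: log-normal analytes with a one-unit log shift on the
  configured subset; **troponin** follows
  $\log T = a + b \log p_{dk} + \varepsilon$ on the designated subset's
  true proportion.

What the generator does **not** emulate: sequence-level realism (no
V(D)J recombination or sequencing-error model), doublets, ambient RNA,
batch effects, or compartment-specific expression programs. Passing
recovery tests on this generator therefore demonstrates correctness of
the statistical machinery under its stated assumptions, not robustness
to those artifacts.

One compositional caveat worth knowing: because subset proportions sum
to one, planting a large abundance increase in one subset necessarily
depresses the others, and planting case fold-changes on a large fraction
of a small gene panel (a third or more) degrades median-of-ratios
normalization for any implementation. Calibration tests therefore use
dedicated null configurations, and DE recovery tests keep the planted
fraction realistic.

# Numerical choices

* Quadrature: 25 adaptive Gauss–Hermite nodes; Newton mode-finding with
  step clamping (the conditional log-density is strictly concave but
  nearly flat far from the mode at large $\sigma$).
* $\hat\sigma < 10^{-3}$ is treated as the boundary and refit as plain
  logistic; LRT statistics are clamped at zero.
* BH adjustment delegates to `stats::p.adjust` with NA pass-through;
  Fisher tests delegate to `stats::fisher.test` (two-sided =
  minimum-likelihood convention). Both are verified against brute-force
  oracles in the suite.
* Dispersion estimates are floored at $10^{-8}$; degenerate OLS fits
  (zero residual variance) are resolved by rule rather than left as 0/0.
* All stochastic stages (generator, permutations, rarefaction) are
  seeded; rerunning a pipeline configuration reproduces outputs byte for
  byte.

# Problem sizes

The test suite and the acceptance script run at deliberately compact
sizes chosen to make the Monte-Carlo answers stable: 1000 replicates for
LRT type-I error (20 donors × 500 cells each), 200 replicates for
effect recovery (40 donors × 1000 cells), 25 simulated cohorts for
clone-enrichment recovery (4 repertoire donors each, 3000 reads per
tissue), 300 genes at 10 units per group for DE null calibration, and
150–400 cells per donor for integration tests. These sizes reproduce the
published summary statistics and calibration targets; they are smaller
than a real cohort's cell counts, which only tightens, not changes, the
asymptotics being checked.

# Known limitations

* The NB Wald DE is a simplification (see above); exact concordance with
  DESeq2 output is a non-goal.
* The per-donor sharing model is a plain logistic by construction and
  can separate in small subsets; such rows are flagged, not suppressed.
* Enrichment requires a matched control-tissue repertoire; donors
  without one contribute expansion calls (for sharing) but no
  enrichment calls.
* The interaction scan models simple pairs only and shares one
  permutation null across pairs, which is exact for exchangeable labels
  but ignores between-pair correlation when interpreting joint results.
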