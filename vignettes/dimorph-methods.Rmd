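---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimorph)
```

`dimorph` re-implements, as tested and reusable functions, the statistical
pipeline of a perinatal low-protein-diet (LPD) study of sex-specific brain
gene regulation: a replication-validated dual-model microarray differential
expression (DE) screen, an m-of-n consensus definition of ChIP-seq peaks,
repeated-measures mixed models for per-CpG bisulfite pyrosequencing
methylation, ΔCt qPCR fold-change analysis, and the factorial GLM /
estimated-marginal-means (EMM) machinery with Newman–Keuls and Bonferroni
post-hoc procedures that all of these share. A synthetic-data module
generates inputs with the statistical structure each analysis assumes, with
ground truth recorded, so every stage can be validated without any external
download. This vignette documents the models, the tunable parameters, and
the decisions taken where the design was genuinely open.

## The dual-model DE screen

The screen operates on a probe × sample matrix of log2 intensities from a
2×2×2 factorial (Sex × Diet × Stress) of 16 pooled arrays plus a male-only
technical replication batch of 8 arrays. Stages, in order:

1. **Quantile normalization** (`quantile_normalize`, via
   `limma::normalizeQuantiles`): every array is mapped onto the row-wise
   mean of the sorted columns; ranks within arrays are preserved.
2. **Low-signal filtering** (`low_signal_filter`): a probe is kept when its
   intensity exceeds the per-array `background_quantile` (default 0.10) in
   at least `min_fraction` (default 0.5) of arrays. The thresholds are not
   dictated by the underlying study and are exposed as arguments; the
   defaults remove probes that sit at array background on at least half the
   arrays, i.e. the unexpressed-probe population.
3. **PC1 extraction** (`pc1_scores`): per-sample scores on the first
   principal component of the probe-centered **main-batch** matrix, used as
   a technical nuisance covariate. Sign is fixed so the first sample scores
   ≥ 0. Replication arrays get no PC1 term: the technical axis is a property
   of the original hybridization batch.
4. **Per-probe least squares** (`probe_lm`) under two models — A:
   `~ Sex + Diet + Stress` and B: `~ PC1 + Sex + Diet + Stress` — with
   treatment coding and reference levels F / CTRL / none, so coefficients
   read "M vs F", "LPD vs CTRL", "swim vs none". A separate
   `~ Diet + Stress` model is fitted to the replication batch.
5. **Empirical-Bayes moderation** (`ebayes_moderate`): the hierarchical
   model takes per-probe residual variances as scaled-χ² about a
   scaled-inverse-χ²(d₀, s₀²) prior. (d₀, s₀²) are estimated by matching
   the first two moments of log s² to the implied log-F distribution
   (digamma/trigamma inversion); posterior variances
   s̃² = (d₀s₀² + d·s²)/(d₀ + d) give a moderated t on d₀ + d df. The
   B-statistic (log posterior odds of DE) uses a two-component prior with
   DE proportion `p_de` (default 0.01 — a conventional choice; only the
   *ranking* feeds the screen) and a prior coefficient variance estimated
   from the top tail of the moderated t.
6. **Top-K intersection** (`consensus_top_k`): candidates are probes in the
   top K = 1000 of *both* models, ranked by descending B for the stress
   coefficient, ties broken by ascending p then probe id (deterministic).
   The ranking coefficient defaults to the acute-stress term, since the
   screen targets stress-responsive transcription; an omnibus ranking is
   not implemented.
7. **Replication validation** (`replication_validate`): a candidate is kept
   when the replication batch shows p < `alpha_rep` (default 0.1) *and* the
   same log2 fold-change sign as the main experiment.

**Replication p-values use the exact per-probe t, not moderated p.** This
is a deliberate choice. The classical t statistic is pivotal — exactly
t-distributed on its residual df whatever the probe's true variance — so
under the null the filter passes exactly `alpha_rep`/2 of candidates
(p < 0.1 two-sided ∧ agreeing sign). Moderated replication p-values share
the global variance prior: because top-B candidates are enriched for
high-variance probes whose s̃² under-shrinks, the same probes receive
anticonservative moderated p in the replication, coupling selection to
validation and inflating the null pass rate. With only 5 residual df in the
replication batch the calibration of a lenient 0.1 filter matters more than
the modest power gain from moderation.

## Consensus peak definition

Replicate peak-call interval sets (BED, 0-based half-open) are first
normalized (sorted, overlapping intervals merged). `support_profile`
computes the per-base number of supporting samples by a boundary sweep;
`call_consensus` takes maximal runs with support ≥ m (default 14 of 18) as
candidates and moves any candidate sharing ≥ 1 bp with an input-control
interval to an `excluded` set. "Overlap" is interpreted base-wise — a
consensus region is the locus where at least m samples simultaneously
overlap, the strictest reading — and the overlap threshold is 1 bp for both
support and input exclusion, since no finer rule is stated by the study.
Sub-threshold gaps are not bridged by default (`merge_gap = 0`). Raising m
can only shrink the consensus; with m = 1 the result is the merged union of
all calls minus input-overlapping runs; both properties are tested, and the
sweep is checked base-for-base against a naive per-base counting oracle on
randomized 10-kb instances.

## Repeated-measures CpG methylation model

Neighbouring CpGs within one pyrosequencing assay are never independent, so
all CpGs of an assay are tested jointly in a linear mixed model
(`fit_cpg_mixed_model`):

    pct ~ Sex + Diet + Sex:Diet + CpG  (fixed)  + (1 | animal)

fitted by REML via `lme4`. The per-animal random intercept (compound
symmetry across CpGs) is the simplest structure consistent with "repeated
measures"; richer covariances are out of scope. Fixed effects are tested
with Type-III Wald F statistics under sum-to-zero coding; denominator df
follow the **containment rule**: animals − cells for between-animal terms
(Sex, Diet, Sex:Diet) and the within-animal stratum's residual df for the
CpG term. Containment is simple, deterministic and exact in the balanced
case; Satterthwaite approximation would be the natural alternative but is
not needed for balanced designs. CpG enters as a fixed effect by default
(toggleable with `cpg_fixed = FALSE`). Percent methylation is analyzed on
the raw percent scale, matching how such assays are reported; values are
clamped to [0, 100] only at generation. With one CpG per assay the model's
fixed-effect tests coincide with the two-way factorial GLM, and with zero
animal variance the fit is flagged singular and reduces to OLS — both are
tested. Within-sex LPD−CTRL contrasts on the model's Sex × Diet marginal
means (`pairwise_cells`) are Bonferroni-corrected over the two declared
contrasts. Retrotransposon assays (B1, IAP) are checked for global shifts
with the factorial GLM on per-animal mean methylation
(`global_methylation_check`).

## ΔCt qPCR analysis

`delta_ct` subtracts the arithmetic mean of the two housekeeping Cts
(equivalently the geometric mean on the linear scale — the standard
multi-reference rule) from each target Ct. `fold_change` computes
FC = 2^−(ΔCt − reference mean ΔCt); the reference is the control-diet group
within each gene × region (configurable), so control means sit at 1 by
construction. `analyze_gene` runs the Sex × Diet factorial GLM on the FC
scale by default — mirroring how such marginal means are reported — with a
`log2_scale` option; analysis on log2 FC is algebraically identical to
analysis on sign-flipped centered ΔCt, which is tested numerically. The
whole pipeline is invariant to a global Ct shift.

## The factorial GLM engine

"Generalized linear model (normal, identity)" is ordinary least squares
with Wald/F tests — exactly that model family; no IRLS machinery is
involved. `factorial_glm` uses sum-to-zero factor coding so that dropping a
term's columns yields Type-III-style tests and EMMs keep their
averaged-over-other-factors meaning in unbalanced data; EMMs and their
pooled-variance SEs come from the normal equations and are cross-checked
against `car::Anova(type = 3)` and `emmeans` to 1e-10 in the tests.
`newman_keuls` implements the stepwise studentized-range (SNK) procedure:
cell means are ordered; each span of r means is tested with
q = (max − min)/√(MSE/n_h) against `qtukey(1 − α, r, df)` (the studentized
range distribution computed numerically by R, not hard-coded tables — the
published 5% table values serve as test oracles); a non-significant span
blocks every pair inside it; unequal cell sizes use the harmonic-mean n.
The pooled residual is the error term for all comparisons, including
interaction cells. `repeated_measures_glm` delegates to `aov` with an
`Error(subject)` stratum — the classical univariate split-plot analysis,
with no sphericity correction, matching how growth-curve F tests with df
like F[6, 324] and F[18, 324] are reported for 58 subjects in 4 groups over
7 time points.

## What the generators emulate — and what they do not

* `simulate_expression` reproduces the pooled factorial array design: 2
  arrays per cell × 8 cells, each array the average of 2 animal-level draws
  (pooling halves biological variance, `bio_sd` = 0.25 log2 units per
  animal), plus an 8-array male-only replication batch. Per-probe technical
  variances are drawn from scaled-inverse-χ²(d₀ = 4, s₀² = 0.04) — a
  heavy-tailed variance distribution typical of arrays, and the same family
  the moderation assumes. A rank-1 (array score × probe loading) term
  injects a dominant technical component (`batch_frac` = 0.4 of array-level
  variance) so PC1 is the technical axis *by construction*, with recorded
  scores; it applies to the main batch only, since the replication ran on
  separate hardware and the screen gives it no PC1 term. Five percent of
  probes are "dead" (at background level 2): these are the population the
  low-signal filter exists to remove, and omitting them would make the
  filter trim the dimmest real probes instead. Probe count defaults to
  60,000 — configurable, not a claim about any platform. The generator does
  **not** model probe-level spatial artifacts, dye chemistry, or
  correlated probe blocks within genes, so passing tests demonstrate
  statistical behaviour under the declared noise model, not robustness to
  every array pathology.
* `simulate_peaksets` draws each true locus into each of n replicate
  samples with probability `presence_prob`, jitters boundaries with
  Gaussian noise (clamped at 0, width kept ≥ 1 bp), and adds Poisson noise
  peaks along a toy contig; the input track is passed through as given.
  There is no read-level or fragment-level model.
* `simulate_methylation` gives each animal × assay a shared random
  intercept (the repeated measure), adds a Sex × Diet interaction effect
  confined to intron assays (the LPD-female cell), and clamps to [0, 100].
  Defaults (baseline 5%, animal and residual sd 1%, interaction +3%,
  n = 12/cell) reflect low-methylation intronic assays where an effect of a
  few percentage points is biologically meaningful.
* `simulate_ct` and `simulate_behavior` produce Gaussian Ct tables with two
  stable housekeeping genes (sd 0.05 cycles) and factorial behavioral
  responses with declared cell means.

Every generator is a pure function of its arguments and seed (the global
RNG state is saved and restored), and every generator emits the truth
needed to score recovery downstream.

## Problem sizes used in the checks

The packaged statistical checks run at the design's native scale: 60,000
probes × 24 arrays for the DE screen (50 seeds for null calibration of the
validated fraction, 10 seeds × 100 spiked probes at |log2FC| = 1 for
recovery), 5,000 probes for variance-prior recovery, 100 random 10-kb
instances for the sweep-line/oracle equivalence, 200 seeds at n = 12
animals/cell for methylation power and null calibration, and 200 seeds for
behavioral crossover power. These sizes give Monte-Carlo standard errors
small enough that the pass criteria are meaningful without being
seed-sensitive.

## Known limitations

* The screen consumes normalized single-channel intensities; raw
  Agilent Feature-Extraction files and probe-to-gene annotation are out of
  scope.
* The B-statistic's prior DE proportion is fixed rather than estimated;
  only ranks are consumed downstream.
* The mixed model offers a random intercept only; autoregressive or
  unstructured CpG covariances are not available.
* SNK uses the pooled residual error for every span; a cell-pair error term
  is not offered.
* No sphericity correction for repeated measures, by design (matching the
  uncorrected df convention of the analyses it reproduces).
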