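---
title: "Methods: transcriptome and methylome screening for wood-dust-associated sinonasal adenocarcinoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcriptome and methylome screening for wood-dust-associated sinonasal adenocarcinoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem this package addresses

Intestinal-type adenocarcinoma of the sinonasal tract (ITAC) is a rare,
wood-dust-associated tumor of the olfactory cleft. Because the olfactory
cleft is hard to inspect and biopsy, a screening strategy based on
noninvasive brush cytology is attractive: sample the nasal mucosa, profile
the transcriptome, and ask whether the profile looks like that of a tumor
patient. The cohort structure this package works with has four sample
groups: **N** (normal, unexposed mucosa), **E** (wood-dust-exposed mucosa
without tumor), **C** (the contralateral, non-tumor side of a tumor
patient) and **T** (tumor). The methylome side compares a small set of
tumor methylomes against a large external panel of non-tumor nasal
methylomes.

`itacscreen` implements the full analysis chain as tested, reusable
functions: preprocessing, gene-profile clustering with group testing, a
correlation-threshold diagnostic predictor, a β-value EWAS with
hemimethylation calling and smoothed P-values, cross-dataset sign
concordance, and a synthetic-data generator with planted truth so every
stage can be exercised end to end without any external download.

# Preprocessing

Raw intensities are normalized per sample against a cohort reference by
LOWESS, then log2-transformed and median-centered per gene.

* **Reference**: `median_reference()` is the per-gene median over all
  samples. Normalizing every sample against one common reference (rather
  than pairwise) means corrections are comparable across the cohort.
* **LOWESS fit**: for sample *s*, `lowess_normalize()` fits
  M = log2(s) − log2(ref) against an intensity abscissa and subtracts the
  fitted trend; corrected intensities are 2^(log2(ref) + M − M̂), positive
  by construction.
* **Abscissa**: the default is the *reference* intensity log2(ref), not
  the classic A = (log2(s) + log2(ref))/2. The reason is a measurable
  artifact, not taste: with a large fraction of genuinely regulated genes
  (the synthetic default plants 40% of genes in differential archetypes),
  a regulated gene shifts its own A coordinate by half its effect, the
  local M trend becomes asymmetric, and the smoother absorbs part of the
  biology it should preserve. The reference abscissa is identical in all
  samples, so regulation cannot drag the curve. `x_axis = "ma"` restores
  the classic behavior.
* **Span**: default 0.3 — a window wide enough (600 genes of 2000) that
  planted archetype structure cannot masquerade as a trend, narrow enough
  to track a smooth intensity-dependent bias. Configurable.
* **Degenerate input**: if a sample's abscissa values are numerically
  constant the fit is undefined; the sample falls back to subtracting
  median(M) and says so.
* **Idempotence** is approximate, not exact: re-running the smoother on
  already-corrected data refits residual noise of order the local smoother
  error (the suite asserts a 0.05 log2 bound on a pure-bias sample), not
  machine zero.

`log_median_center()` is exact arithmetic: value = log2(x) − per-gene
median of log2(x). Clustering, group tests and the predictor all operate
on this scale. **Fold changes do not**: FC(T/N) is the ratio of unlogged
group means computed from the *unlogged original data* (the convention the
source cohort used), so `gene_stats()` takes the unlogged matrix as an
explicit argument; passing the LOWESS-normalized unlogged matrix instead
gives the post-normalization convention.

# Gene-profile clustering

`kmeans_profiles()` is restarted Lloyd-type k-means under correlation
distance d(x, c) = 1 − Pearson(x, c), defaults k = 10 with 100 random
restarts, each run capped at 100 iterations or assignment stability.

Design choices worth knowing:

* **Update rule.** Pearson correlation only sees the standardized shape
  of a profile, so the update operates on row-standardized profiles
  (centered, unit norm): the new centroid direction is the normalized mean
  of the member genes' standardized profiles. This is the spherical
  k-means update, and it makes the within-run objective provably
  non-increasing — a property the test suite asserts per iteration. The
  *reported* `centroids` are per-cluster mean profiles on the input scale
  (what you want to plot); the objective is the summed correlation
  distance to the centroid direction.
* **Mixed metric in the source description.** The procedure this
  reimplements is described once with Pearson distance and once with
  Euclidean nearest-centroid assignment. On log-centered rows the two
  nearly coincide; correlation is the default here because profile shape
  is the stated intent, and `method = "euclidean"` provides the literal
  alternative (classic Lloyd, squared-distance objective).
* **Determinism.** Ties in the assignment step go to the lowest cluster
  id; restarts are driven by R's RNG, so (seed, runs, k) reproduces the
  clustering bit for bit. Constant-profile genes (undefined correlation)
  are excluded with a warning. An emptied cluster is reseeded with the
  gene farthest from its centroid.
* **Restarts in practice.** On the default synthetic world the four
  differential archetypes are recovered identically with 10, 25 or 100
  restarts (the extra restarts only re-shuffle how pure-noise genes are
  split), which is why the leave-one-out evaluation and the acceptance
  script use 25 restarts to stay inside their compute budgets.

`cluster_group_profiles()` summarizes each cluster per group and tests
E, C, T against N with a two-sided pooled-variance Student t-test on the
**per-sample cluster means** — samples, not genes, are the independent
units; member genes are correlated and pooling them would overstate
significance. Bonferroni uses m = k × 3 (three group contrasts per
cluster). Groups with fewer than two samples report NA.

# The diagnostic predictor

The predictor asks one question per sample: does its profile on a small
discriminant gene set correlate with the mean C/T profile?

1. **Source clusters** (`select_predictor_clusters()`): each cluster's
   per-sample mean is tested C∪T vs N∪E; the smallest-p cluster is taken,
   then the smallest-p cluster with the opposite effect sign. Selecting by
   behavior rather than by cluster number makes the pipeline robust to
   cluster renumbering across k-means runs.
2. **Genes** (`select_discriminant_genes()`): within each source cluster,
   genes ranked by |t| of the C/T-vs-N/E contrast, top 100 per cluster
   (ties broken by gene id; a short cluster contributes everything, with a
   warning).
3. **Reference** (`build_model()`): per-gene mean of the centered log2
   values over the C and T samples of the *training* set.
4. **Call** (`score_and_classify()`): Pearson r between the sample and the
   reference across the model genes; r > 0.25 → `tumor_like`,
   r < −0.25 → `healthy_like`, the band in between (including undefined r)
   → `unpredictable`.

`evaluate_predictor()` reports sensitivity (true-positive rate over truth
C/T), specificity (true-negative rate over truth N/E) and a two-sided
Fisher exact test on the 2×2 of truth vs `tumor_like`. How the abstention
band enters the published operating point is not stated in the source, so
both policies are implemented: `count_as_error` (default, conservative —
an unpredictable positive is a miss, an unpredictable negative a false
alarm) and `exclude`.

`loo_evaluate()` rebuilds everything per held-out sample — clustering,
contrast statistics, source-cluster choice, gene choice, reference — and
scores the held-out sample against the rebuilt model. Preprocessing is
done once on the full matrix: the LOWESS step is per-sample against a
median reference and carries no class information; the per-gene median
centering is the one (mild, class-blind) quantity shared across the split,
accepted for tractability and noted here deliberately.

# β-value EWAS

* **QC** (`qc_samples()`): a clean methylome is bimodal (most probes near
  0 or 1). The visual criterion "consistent with a beta distribution" is
  quantified as: fraction of probes with β in the open interval
  (0.25, 0.75) must be < 0.35 (configurable). Failed tumor samples are not
  discarded — they are routed to the secondary locus-specific analysis, as
  in the source design.
* **Test** (`ewas()`): per probe, a two-sided pooled-variance Student
  t-test on the β values themselves (not M-values — matching the source),
  Bonferroni over the number of probes, Δβ = mean(tumor) − mean(control).
  A probe with zero variance in both arms and equal means gets t = 0,
  p = 1.
* **Calibration caveat.** With *balanced* arms the β-scale t-test holds
  its family-wise level under the global null (asserted by the suite at
  8 vs 8). With the heavily unbalanced design the method is actually used
  on (4 tumor vs 72 controls), the small arm's skewness does not cancel
  and the far tail is anticonservative — the suite does not assert
  calibration there, and top-hit claims should lean on the locus-level
  consistency (contiguous probes, state concordance) rather than the raw
  Bonferroni p alone. The planted-signal recovery tests are unaffected:
  the planted effects sit orders of magnitude above the inflated tail.
* **Smoothing** (`smooth_pvalues()`): the window radius of 3 is read as a
  *probe-index* radius (a ≤7-probe window) within each chromosome — probe
  spacing on arrays is too irregular for a base-pair reading — and the
  smoothed score is the arithmetic mean of −log10(p) over the window
  (equivalently the geometric mean of p), transformed back to a P-value.
  Chromosome boundaries truncate the window; probes without manifest
  coordinates get NA and are skipped, not imputed.
* **States** (`call_state()`): β < 0.2 unmethylated, 0.2 ≤ β ≤ 0.6
  hemimethylated, β > 0.6 methylated. The interval is closed on both ends:
  0.2 is stated as the unmethylated/hemimethylated boundary and the
  hemimethylated band as "between 0.2 and 0.6", so both boundary values
  call hemimethylated.
* **Loci** (`locus_analysis()`, `rank_loci()`): an island is
  `concordant_hemimethylation` iff every probe is hemimethylated in tumor
  and unmethylated in control; `null` if no tumor probe is hemimethylated;
  `mixed` otherwise. QC-failed samples can be supplied as an extra arm and
  are summarized per probe alongside. Islands rank by their minimum
  smoothed P-value.

# Cross-dataset replication

`concordance()` intersects two per-gene tables by symbol, counts genes
whose tumor-vs-normal direction (sign of t) agrees — a zero sign is
always discordant — and repeats the count restricted to genes with nominal
p < α in both datasets (α = 0.05 by default; the source's exact
significance rule behind its printed subset is unstated, so this is a
declared choice). Duplicate symbols collapse to the row with the largest
|t|. The report is symmetric in its two arguments.

# The synthetic world

`generate_expression()` / `generate_methylation()` produce the data every
test runs on. Their defaults *are* the stated world, chosen once:

* **Cohort**: 13 N / 16 E / 13 C / 13 T samples; 2000 genes in ten
  archetypes of which four are differential (up in C+T, down in C+T, up in
  T only, down in T only; ±1 log2), six null; residual log2 noise sd 0.3;
  baseline intensities log-normal (log2 mean 8, sd 1); a per-sample
  sinusoidal intensity-dependent bias with amplitude drawn in (−0.3, 0.3)
  gives the LOWESS step something real to remove.
* **Planted fold changes**: gene `CDX2` with T/N = 2.46 (also elevated in
  a random half of C samples, echoing its behavior in contralateral
  mucosa) and `CACNA1C` with T/N = 1.52, planted as log2 offsets. Because
  the noise is homoscedastic log-normal across groups, the log-normal mean
  factor cancels in the ratio of unlogged group means, so the *expected*
  unlogged-mean ratio equals the planted value exactly — no ad-hoc
  correction factor is needed, and the pipeline's FC estimator is what is
  being measured.
* **Methylomes**: 4 good tumor samples, 7 QC-failing tumor samples
  (flattened Beta(2, 2) profiles, intermediate fraction ≈ 0.69 ≫ 0.35), 72
  controls; background probes are a 50/50 mixture of Beta(1, 10) and
  Beta(10, 1) shared between arms; two planted islands (6 probes "CpG:84"
  / CACNA1C-AS1 and 9 probes "CpG:41" / SLC26A10, contiguous on chr12)
  with tumor β ≈ 0.4 ± 0.05 and control β ≈ 0.05 ± 0.02; 100 null islands
  of 8 contiguous background probes form the locus-ranking null. QC-bad
  samples keep the planted hemimethylation (poor global quality does not
  erase a locus signal), which is what the secondary locus analysis is
  for.
* **What it does not emulate**: probe chemistry, batch effects beyond the
  single bias term, realistic genome annotation, cell-type composition,
  cross-platform probe mapping. A green test therefore establishes that
  the *pipeline* recovers what was planted under its stated statistical
  assumptions — not that those assumptions hold on any particular real
  cohort.

# Numerical and policy decisions, in one place

* Tabular dialect: UTF-8 TSV, "." decimal, no quoting, first header cell
  `id`, NA written "NA"; readers never reorder rows or columns;
  out-of-range β is an error, never clipped.
* NA policy: correlations pairwise-complete; t-tests listwise within a
  gene/probe.
* Bonferroni is min(1, p·m) with m = genes (gene tests), probes (EWAS), or
  k × 3 (cluster-group tests); Bonferroni is applied to raw EWAS p-values,
  smoothing is reported separately (order not stated in the source —
  declared here).
* Zero-variance cases: constant gene excluded from clustering (warning);
  zero-variance sample on the predictor gene set → r = NA →
  `unpredictable`; zero pooled variance with equal means → p = 1, with
  unequal means → p = 0.
* Fisher's exact test and the t CDF come from base R; the test suite
  verifies both against brute-force enumeration and numerically integrated
  t densities to 1e-12 / 1e-9.
* Seeds: generators take an explicit `seed` and are byte-reproducible;
  k-means takes a seed for its restarts; leave-one-out derives per-fit
  seeds as seed + holdout index.

# Known limitations

* The β-scale t-test anticonservatism under heavy arm imbalance, above.
* The smoothed-P definition (windowed mean of −log10 p) is an
  interpretation of a procedure whose exact formula is not printed in the
  source; it is isolated in `smooth_pvalues()`.
* Normalization is not re-run inside the leave-one-out loop (see above).
* The concordance module matches genes by symbol only; cross-platform
  probe remapping is out of scope.
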