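---
title: "Methods: bootstrapped evaluation of SRS radiomics outcome models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bootstrapped evaluation of SRS radiomics outcome models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`radboot` evaluates per-lesion progression models for brain metastases (BMs)
treated with stereotactic radiosurgery, with explicit accounting for three
confounders of radiomics accuracy: primary cancer site, lesion volume, and
MR scanner model. This vignette documents the statistical machinery, the
synthetic world the tests run in, and the design decisions taken where the
methodology left choices open.

## 1. The evaluation design

**Patient-level bootstrap.** Each of `n_reps` (250 in the full design)
repetitions draws patients *with replacement* until the training multiset
has as many entries as there are patients; patients never drawn form the
test set. All of a patient's lesions travel with the patient, so no lesion
of a training patient can appear in testing — the design's defence against
intra-patient leakage. The expected held-out fraction is
$(1 - 1/n)^n \approx 0.369$ for $n = 99$ patients. A draw that leaves the
test set empty is redrawn on the next seed substream and logged.

**Per-repetition pipeline.** On the training partition only: (i) a greedy
inter-feature correlation filter (default cutoff $|r| > 0.95$, visiting
features by decreasing univariate training AUC) removes near-duplicate
features; (ii) the forest's hyper-parameters are selected by out-of-bag AUC
over the grid `mtry` $\in \{\sqrt p, p/3\}$ $\times$ `min_leaf`
$\in \{1, 3, 5\}$ with 500 trees; (iii) the chosen forest records test-set
probabilities, out-of-bag probabilities (each training lesion scored only by
trees whose internal bootstrap excluded it), resubstitution probabilities,
and impurity-decrease importances. The hyper-parameter grid and the 0.95
cutoff are package defaults standing in for unavailable supplementary
detail; both are exposed in `engine_config()`.

**The internal forest.** No random-forest package is assumed: the forest is
a compact Rcpp implementation (Gini CART, bagging, random feature subsets,
minimum leaf size) whose out-of-bag contract is auditable — `keep_inbag`
returns the per-tree in-bag counts and per-tree training predictions, and
the test suite recomputes every OOB probability from that bookkeeping. The
forest uses its own splitmix64 RNG stream, so results are identical across
platforms and independent of R's global RNG.

## 2. Error metrics

Point estimates come from probabilities *pooled* across repetitions'
test partitions; confidence intervals are percentile intervals (type-7
quantiles, 2.5th–97.5th) over per-repetition statistics. The banded curve
display uses vertical averaging on a fixed FPR grid instead; both
implementations are exported because pooling drives the numbers while the
bands illustrate the spread.

**AUC and .632+.** AUC is the Mann–Whitney statistic with midpoint tie
handling. The .632+ correction is applied in error space $e = 1-\mathrm{AUC}$
with the no-information rate fixed at $\gamma = 0.5$ (a random ranking):
$e_1 \leftarrow \min(e_1, \gamma)$,
$R = (e_1 - e_{app})/(\gamma - e_{app})$ clamped to $[0,1]$ (0 when
$e_{app} \ge \gamma$), $w = 0.632/(1 - 0.368R)$, and
$\mathrm{AUC}_{.632+} = 1 - [(1-w)e_{app} + w e_1]$. The apparent term pools
resubstitution probabilities across repetitions, symmetric with the pooling
of the bootstrap term. The corrected value always lies between the (clamped)
bootstrap and apparent AUCs.

**Operating point.** The threshold for MCR/FNR/FPR is the point of the
pooled *out-of-bag* ROC curve closest (Euclidean) to the corner
$(\mathrm{FPR}, \mathrm{TPR}) = (0, 1)$, ties broken toward lower FPR;
"upper-left" is read literally rather than as Youden's J (which remains
available). OOB probabilities derive from training data only, so the
threshold transfers to the pooled test predictions without optimistic bias.
For stratified reporting the default recomputes the operating point from
each stratum's own OOB pool; a global-threshold mode exists, and with it
stratified confusion counts sum exactly to the overall counts.

## 3. Volume decorrelation

Categorical clinical features are tested for volume dependence with the
two-sided Wilcoxon rank-sum test (binary) or Kruskal–Wallis test
(multi-category); continuous features get two Pearson tests, against volume
and against its cubic root (a diameter analogue). Significance is
Bonferroni-controlled at $\alpha = 0.05/118$ — the 119 features other than
GTV volume itself, which is the confounder and is always removed at any
threshold below 1. A continuous feature is removed when either correlation
is significant *and* $\max(|r_{vol}|, |r_{diam}|)$ exceeds the threshold;
either coefficient's p-value may establish significance. The sweep covers
$\{1, 0.85, 0.70, 0.55, 0.40, 0.25, 0.10, 0\}$ (1 = baseline, nothing
removed) on shared bootstrap partitions so that differences across
thresholds are attributable to the feature sets alone. Removal sets are
nested by construction as the threshold falls.

The filter is computed once on the full cohort before bootstrapping,
matching the fixed published removal counts; this leaks the filter (not the
model) across partitions, and a per-training-set mode is available for the
leakage-free variant. The primary-site analogue (Kruskal–Wallis for
continuous, chi-squared for categorical features, site itself always
removed) implements the site-decorrelation variant explored in the source
study's discussion.

Rank-sum p-values use the `wilcox.test` default: exact for small untied
samples, normal approximation with tie correction otherwise. Chi-squared
tests are Pearson's $\sum (O-E)^2/E$ *without* continuity correction —
verified to reproduce all printed per-feature p-values of the study tables.

## 4. The synthetic world

The generator's defaults restate the study sample rather than tune to any
test outcome: 99 patients; 1–3 lesions each with probabilities
(0.79, 0.18, 0.03), giving ≈123 lesions in expectation (the per-patient
distribution beyond "up to three" is unpublished, so only the mean is
pinned); categorical clinical features drawn at the published per-lesion
frequencies; log-normal volumes with median 3.07 cc, log-SD 1.3, clamped to
[0.02, 30.23] cc; scanner models at the published frequencies; the dose
rule (21 Gy / 1 fraction below 7.5 cc, 95% adherence) generating the one
volume-dependent clinical feature; 107 radiomic-like columns of which 79
(74%) are volume-correlated.

**Feature construction.** Radiomic columns mix a standardised log-volume
term with independent Gaussian noise at the weight that yields the target
correlation exactly in expectation: 8 volume-independent *signal* columns,
16 pure-noise columns, 4 *mediator* columns at $\rho = 0.55$, and 79 plain
proxies with targets evenly spaced on $[0.35, 0.9]$. Scanner effects are
additive per-model, per-feature offsets (SD = `scanner_shift`) plus a
variance scale — the simplest domain-shift mechanism that lets pairing
experiments expose a scanner in a different data domain. Offsets slightly
attenuate realised correlations; the default shifts are small enough that
targets are still recovered within ±0.05 at $n \ge 5000$.

**Outcome model.** Progression is logistic. Following the source study's
own interpretation of its volume effect (size as a correlate of
hypoxia/vascularisation rather than a direct cause), the volume dependence
is mostly *mediated*: a small direct term ($\beta_v = 0.1$ on standardised
log-volume) plus the four mediator columns (weight 0.4 each), with the
volume-independent signal carried by the 8 signal columns at geometrically
declining weights $2.0 \times 0.65^{j}$ and per-site attenuation
(colorectal 1.4, skin 1.2, renal/other 1.0, lung 0.8, breast 0 — ordering
the sites as in the published per-site accuracy table, breast at chance).
The intercept is solved per cohort by root finding so the mean progression
probability equals the 22.0% prevalence. The mediator weights were
calibrated once, at $n = 6000$, so the marginal progression split matches
the printed 17.0% (< 7.5 cc) vs 37.9% (> 7.5 cc); the concentrated signal
weights were likewise calibrated so that a forest at $n \approx 123$ can
actually learn the volume-independent signal — radiomics importance
analyses, including the source study's, find importance concentrated in a
few dominant features, and a uniformly diffuse signal of the same total
strength is unlearnable at this sample size (forest out-of-bag AUC at
chance), which would contradict the published post-filter stability.

**What a green test does and does not establish.** The generator reproduces
marginal structure (frequencies, volumes, prevalence, correlation targets)
and the qualitative mechanisms (volume-coupled baseline predictions,
scanner domain shift, per-site predictability differences). It does not
emulate real radiomic inter-feature correlation structure beyond the shared
volume term, image texture, pseudo-progression dynamics, censoring patterns
(label-flip censoring exists but is off by default), or survival time. A
passing volume-blinding test shows the pipeline can detect and remove a
volume confound of realistic strength — not that any particular clinical
model generalises.

## 5. Numerical and degenerate-input choices

- Z-score normalisation requires a non-empty mask and positive in-mask
  variance; "at three standard deviations" is implemented as clipping the
  standardised scan to ±3 (the normalisation-literature reading), with the
  unclipped variant behind `clip = Inf`. Normalisation is applied before
  resampling; the two are independent operations, so a caller can swap the
  order (whether the original statistics were taken before or after
  interpolation is unstated).
- Resampling anchors the output grid at the input origin (corner-aligned,
  half-open extent, `ceil(extent/spacing)` voxels per axis) and clamps at
  edge voxel centres — no extrapolation.
- Discretisation is fixed-bin-count over the region's `[min, max]`; the
  maximum lands in the top bin; constant input collapses to one bin with a
  warning.
- Constant features: removable with a warning in the inter-feature filter;
  an error in correlation tests; skipped with a warning in univariate
  association tables.
- Single-class strata yield explicitly undefined metrics (with a message)
  while the surrounding analysis continues; a single-class *training* draw
  is redrawn on the next substream.
- All seeds derive from one master seed through a multiplicative hash
  (31-bit), so every repetition, arm, and generator stage has an
  independent, reproducible stream.

## 6. Scaling in the test suite

The full design (250 repetitions, tuned 500-tree forests, 8 sweep
thresholds) runs in minutes but exceeds a CI budget when repeated across
criteria. The acceptance suite therefore runs the volume-blinding criterion
at its stated scale (123 lesions, 50 repetitions, default tuned engine,
fixed seed) and the scanner-pairing criterion with a reduced forest
(250 trees, fixed `mtry = sqrt(p)`, `min_leaf = 3`, 30 repetitions); unit
tests use a 30-patient, 20-feature cohort. Scaling reduces runtime, not
what is measured.

## 7. Known limitations

- The within-volume-group AUC of a 123-lesion cohort rests on ~29 large
  lesions; its sampling standard deviation (~0.1) is comparable to the
  published group gap, so single-seed group-gap comparisons are noisy by
  nature — the acceptance criterion is met at the stated fixed seed, and
  the direction of the effect is stable across seeds while its magnitude
  fluctuates.
- Clinical categorical features enter the forest integer-coded (ordinal
  splits), not one-hot; with the shallow category counts here the practical
  difference is small.
- The probability-table schema mirrors the published data share, but the
  share itself is not fetched: `replicate_error_metrics()` accepts any
  table in that schema.
- NIfTI I/O is out of scope in this build (no NIfTI reader in the
  dependency budget); preprocessing operates on in-memory arrays.
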