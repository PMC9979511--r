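---
title: "Methods: quantifying and discriminating OA and RA synovial inflammation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying and discriminating OA and RA synovial inflammation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(synovkit)
```

This vignette is the package's own account of its models, parameters and
numerical choices. It states no empirical result beyond what the test suite
and `scripts/acceptance.R` themselves compute.

## The problem

Synovium explanted at total knee replacement is stained with hematoxylin
(nuclei, dark blue-purple) and eosin (cytoplasm and stroma, pink) and
assessed by a pathologist. Osteoarthritic synovium tends toward fibrosis
and mast cells with sparse lymphocytic infiltrates; rheumatoid synovium
toward lining hyperplasia, dense lymphocytic and plasma-cell infiltrates,
neutrophils and fibrin. `synovkit` quantifies this contrast along two
routes — an automated whole-slide nuclei density and fourteen
semi-quantitative pathologist scores — and measures the discriminative
power of each feature and their combination.

## Cell density by classical computer vision

`compute_density()` implements a deliberately classical (non-learned)
pipeline so every step is auditable:

1. **Tiling.** The slide is partitioned row-major into `tile_px`-square
   tiles. At the 20× scan convention of 0.5 µm/px, the default 1000 px tile
   covers 0.25 mm². Edge tiles keep their true (smaller) pixel dimensions
   and contribute their true area; no pixel belongs to two tiles.
2. **Tissue detection.** Grayscale is Rec. 709 luma
   (0.2125 R + 0.7154 G + 0.0721 B). A pixel is tissue when its luma falls
   below `tissue_intensity_cutoff` (default 0.9 — low enough that bare
   slide, ≥ 0.94, is excluded; high enough that faint eosin counts as
   tissue). Tiles with tissue fraction below `min_tissue_fraction`
   (default 0.05) are excluded from both the nucleus count and the area
   denominator, so empty border tiles cannot dilute the density.
3. **Nucleus segmentation.** Candidate pixels must be dark under *both* a
   per-tile global Otsu threshold and a local adaptive mean threshold
   (window `adaptive_window_px` = 51 px, offset 0.02). The conjunction is
   our reading of combining global and local thresholding: Otsu separates
   chromatin from stroma tile-wide, while the local test suppresses broad
   dark regions (folds, dense stroma) that pass a global cut. Both the
   window and the offset are configurable.
4. **Watershed splitting.** Connected components larger than
   `nucleus_area_max_um2` are split. Seeds are local maxima of the
   Euclidean distance transform, kept at least
   `watershed_min_distance_px` (default 7 px ≈ 3.5 µm) apart by a
   disc-dilation maximum filter; regions then grow by gradient propagation
   on the negated distance map. Only oversized components are split —
   well-formed single nuclei are never fragmented.
5. **Shape filtering.** Detections survive if their area lies within
   8–120 µm² (roughly lymphocyte through stromal nuclei at 0.5 µm/px) and
   their circularity `4πA/P²` is at least 0.25. Digital perimeters make
   circularity an upper-bounded estimate (compact blobs saturate at 1), so
   the floor mainly rejects ragged debris.

Per-tile Otsu (rather than one slide-wide threshold) is a deliberate
choice: staining intensity drifts across a slide, and the tile is the unit
at which the tissue metric is defined anyway. Nuclei crossing tile borders
are counted in whichever tile their component centroid falls; the
partition-invariance tests allow 1% for this.

## The synthetic ground truth

Because no patient images ship with the package, `generate_tile()` renders
H&E-like tiles with *known* truth: eosin-pink tissue (luma ≈ 0.80) inside
the mask, near-white slide (≥ 0.945) outside, and dark elliptical nuclei
(major axis 10–16 px, minor 0.65–0.95 of that, random orientation, soft
edge with α = 0.5 exactly on the ellipse boundary, mild per-nucleus
intensity jitter). Counts are Poisson at the target density times the
tissue area; placement is uniform in the mask, with optional rejection
sampling keeping bounding-circle boundaries ≥ 2 px apart. The truth table
has exactly one row per rendered nucleus, which is what lets the suite
assert count recovery within 5% per tile across 1000–6000 cells/mm².

What the generator does *not* emulate — and hence what passing tests do
not show about real slides: staining artifacts, folds, cautery, nuclear
texture and chromatin patterns, overlapping nuclei in 3D section, color
deconvolution issues, pyramidal WSI containers. The imaging tests validate
the *mechanics* of the quantifier, not its field performance.

## Synthetic cohorts and the density calibration

`sample_cohort()` draws patients from per-disease categorical marginals
(defaults: the bundled 147 OA / 60 RA reference cross-tabulation, with
proportions over non-missing scores for the three features that have
missing entries). Cross-feature dependence uses a one-factor Gaussian
copula: patient latent severity `z ~ N(0,1)`; feature *j* observes
`√ρ·z + √(1−ρ)·ε_j` through its group's marginal quantile function. ρ = 0
(the default) makes features independent, which preserves every published
univariate statistic exactly in expectation; ρ > 0 enables multivariate
experiments. The reference publishes only marginals, so any joint
structure is a modeling choice; the one-factor copula is the minimal one.

Cell density is lognormal with shared log-sd σ = 0.22 and log-means
back-computed from the published arithmetic means (2900 / 4196 cells/mm²)
via `m = exp(µ + σ²/2)`. The published source gives neither the density
variance nor its distribution shape; the lognormal form and σ are
stand-ins chosen once so that the closed-form two-lognormal AUC
`Φ(Δµ/(σ√2)) = 0.882` matches the published density AUC of 0.88, which
then *implies* an equal-variance optimal threshold
`exp((µ_OA + µ_RA)/2) ≈ 3405` cells/mm² with sensitivity = specificity
`Φ(Δµ/2σ) ≈ 0.80` — close to the published rule (3400 cells/mm², 0.82 /
0.82) without having been fit to it. The acceptance suite verifies these
as sampling properties at 50,000 patients per group.

## The discrimination engine

**AUC with ties.** Ordinal scores tie heavily, so the AUC is the
Mann–Whitney probability with ties counted half, computed from midranks;
it equals the trapezoidal area under the ROC through every distinct cut
(an identity the tests assert). Curves are oriented so the reported AUC is
≥ 0.5, with the direction (higher ⇒ RA or higher ⇒ OA) carried alongside —
fibrosis and mast cells run toward OA, everything else toward RA.

**Youden threshold.** `youden_threshold()` scans every ROC point for
maximal J = sensitivity + specificity − 1. Ties in J break toward the more
specific cut (the higher oriented cutoff), a convention that matters only
for flat ROC stretches. For ordinal features the cut is also rendered as
the category partition it induces.

**Chi-square and logistic adjustment.** Group comparisons are Pearson
chi-square without continuity correction on the disease × category table,
missing scores excluded (they are tallied, never imputed, in crosstabs).
Zero-margin tables are an error — collapsing categories is the caller's
scientific decision. The adjusted analysis is a plain ML logistic fit of
disease on exposure + adjusters (indicator contrasts), with a
likelihood-ratio test for the exposure block and an explicit separation
flag rather than silent divergence.

**Nested cross-validated random forest.** Outer stratified 5-fold
evaluation; per outer fold an inner stratified 5-fold grid search over
tree count and depth picks the pair with best mean inner AUC, ties broken
toward fewer trees then shallower depth (the behavior of a first-best
grid scan). The naming of the two summaries follows the reference
analysis even though it is the reverse of common usage, and the docs say
so: *micro*-AUC is the mean ± SD of the five outer-fold AUCs (sample SD),
*macro*-AUC the AUC of all out-of-fold predictions concatenated. Ordinal
codes feed the trees directly — trees are invariant to monotone
recoding, and one-hot expansion would only dilute importances. Missing
scores are mode-imputed (density: median) from the training rows of each
split only, so no information leaks across folds.

One numerical shortcut: the tree-count dimension of the inner grid is
scored by evaluating the leading *t* trees of a single largest forest per
depth (cumulative per-tree probabilities), rather than refitting per tree
count. Forest trees are i.i.d., so the first *t* trees are
distributionally a *t*-tree forest; this cuts the inner search by a factor
of twenty with no change in what is being estimated.

## Problem sizes and determinism

The suite exercises the statistics at the reference size (147/60), the
marginal-recovery and calibration properties at 50,000 per group, the
permutation null at 500 patients × 20 repeats, and the imaging recovery on
twenty 1000 × 1000 px tiles spanning 1000–6000 cells/mm² — sizes at which
the binomial/Poisson error of each check is far below its asserted
tolerance. Every stochastic path (tile rendering, cohort sampling, fold
assignment, forest fitting) flows from explicit integer seeds through a
seed-derivation helper, and the RNG state of the caller is always
restored; identical spec + seed reproduces cohorts, images and CV reports
bit-for-bit, which the determinism tests assert.

## Known limitations

* The reference joint distribution across features is unknown; only
  marginal statistics of the reference cohort are exactly reproducible.
  Multivariate results on synthetic cohorts (any ρ) are qualitative
  surrogates, not reproductions — under a one-factor copula the combined
  model separates more cleanly than real data would.
* The density σ and lognormal form are calibration stand-ins, as above.
* Circularity saturates at 1 for compact digital blobs; it is a debris
  filter, not a morphometric.
* The mucoid-change chi-square recomputes to p = 0.723 on the reference
  counts; the conventionally cited rounded value differs in the second
  decimal (0.73), consistent with a different test variant or rounding in
  the original tabulation. The package reports the exact Pearson value.
* No stain deconvolution, no pyramidal WSI formats, no probability
  calibration of the classifier, and no claim about cohorts beyond knees
  at arthroplasty.
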