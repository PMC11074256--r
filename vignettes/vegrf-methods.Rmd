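---
title: "Methods: object-based vegetation classification with a weighted-feature random forest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: object-based vegetation classification with a weighted-feature random forest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

vegrf is a toolkit for classifying vegetation in four-band (blue, green,
red, NIR) multispectral imagery at the level of image objects (segments),
with a focus on strongly imbalanced class problems such as scattered forest
patches inside extensive grassland. This vignette explains the models and
procedures the package implements, the parameters that matter, what the
synthetic-data generators do and do not emulate, and the numerical choices
made where the design was genuinely open.

## The classification model

### Gain-ratio decision trees

The base learner is a C5.0-style decision tree over numeric features. At a
node with per-class counts $n_1,\dots,n_k$ (total $n$), the entropy is
$H = -\sum_i (n_i/n)\log_2(n_i/n)$ bits. A binary split of the node into
children of sizes $n_L, n_R$ has information gain
$G = H - (n_L H_L + n_R H_R)/n$ and split information
$S = -(n_L/n)\log_2(n_L/n) - (n_R/n)\log_2(n_R/n)$; its gain ratio is
$G/S$. Candidate thresholds are midpoints between consecutive distinct
sorted values of each feature.

Raw gain-ratio maximization degenerates: a split that peels off one or two
rows has near-zero $S$ and can post an enormous ratio from a trivial gain.
The classic C4.5 guard is applied: only candidates whose gain is at least
the mean gain of all positive-gain candidates (pooled across the features
under consideration) compete on gain ratio. "Positive gain" is defined as
gain at or above `min_gain` ($10^{-6}$ bits) so that floating-point noise
near zero cannot perturb the guard. Ties on the ratio (within a $10^{-9}$
relative tolerance, which absorbs float-path differences between
mathematically identical partitions) break to the lower feature index in
manifest order, then the lower threshold, making induction fully
deterministic.

Growth recurses until a node is pure, smaller than `min_split`, at maximum
depth, or has no admissible split. Each leaf stores its class counts.
`min_leaf`, the smallest admissible child, defaults to 2 — the classic
C4.5/C5.0 "minimum cases per branch" setting. This default matters beyond
convention: with singleton leaves allowed, gain-ratio induction on
label-noise data produces "caterpillar" trees that peel off one pure row at
a time, and such trees are nearly immune to pessimistic pruning because
many tiny pure leaves carry a smaller summed error bound than any collapsed
node. With `min_leaf = 2` pruning behaves as intended (see below).

Multiway categorical splits, fractional routing of missing values,
winnowing and boosting are deliberately out of scope: all features here are
numeric and complete.

### Pessimistic pruning

Pruning is bottom-up. For a node with $n$ training rows of which $e$ are
errors under its majority label, the pessimistic error is $n\,U_{CF}(e,n)$,
where $U_{CF}$ is the upper binomial confidence bound at confidence
`prune_confidence` (default $CF = 0.25$), computed as the Clopper–Pearson
limit `qbeta(1 - CF, e + 1, n - e)`. A subtree is replaced by a leaf when
the leaf's pessimistic error does not exceed the sum of its leaves'
pessimistic errors. The node count never increases, and the tree's total
pessimistic bound never increases. On tables whose labels are pure noise
this collapses most of the spurious structure (the test suite checks a
strict node-count reduction in at least 90% of random-label replicates);
on cleanly separable data it is a no-op.

### The forest and weighted feature subsampling

The ensemble is a bagged forest of these trees: each of `n_trees` (default
100) trees is grown on a bootstrap resample of the training objects
(expected out-of-bag fraction $(1-1/n)^n \approx e^{-1}$) and restricted to
`m_features` features (default $\lceil\sqrt{F}\rceil$, i.e. 10 of 85).
Prediction is by majority vote; ties break by the larger summed leaf
probability, then lexicographic class label. Out-of-bag (OOB) accuracy is
estimated by predicting each training object only with trees that did not
see it in-bag; objects in-bag for every tree are excluded and counted.

The departure from the classical forest is *how* the per-tree feature
subsets are drawn. With heavy class imbalance, uniform feature subsampling
rarely hands a tree the few features that separate the minority (positive)
class, and the minority is simply voted away. Each feature $j$ is therefore
scored by $s_j$, its best single-split gain ratio on the one-vs-rest
problem (positive class against everything else), under the same pooled
mean-gain guard as tree induction; features with no admissible split score
zero. Sampling weights are the mixture

$$w_j = (1-\lambda)\frac{1}{F} + \lambda \frac{s_j}{\sum_i s_i},$$

and subsets are drawn without replacement by sequential weighted draws.
The score term concentrates sampling on features that help classify
positive objects; the uniform floor $(1-\lambda)/F$ guarantees every
feature — including those informative only for the negative class — remains
selectable, so useful negative-class features are never starved out.
`lambda_weight` (default 0.5) is the only new tuning constant: $\lambda=0$
recovers the classical uniform-feature forest exactly, and $\lambda=1$
trusts the one-vs-rest scores alone. Weights are computed once on the full
training table for determinism and cost (per-bootstrap reweighting is
available via `per_tree_weights`). Each tree draws from an RNG substream
derived from `(seed, tree index)`, so the model is a deterministic function
of `(seed, config, table)` and trees are order-insensitive.

Feature importance is the gain attributed at each internal node weighted by
the fraction of training rows reaching it, summed over trees and normalized
to 1.

## The 85-feature object inventory

Feature extraction turns a labelled segment raster into one row per object
with exactly 85 columns under the default manifest, covering four aspects:

| group | features | count |
|---|---|---|
| spectral | per-band mean and sd; brightness; max difference | 10 |
| geometric | area, perimeter, length–width ratio, density, rectangular fit | 5 |
| GLCM texture | homogeneity, variance, dissimilarity, ASM, entropy × 4 bands × 2 offsets | 40 |
| GLDV texture | mean, entropy, ASM × 4 bands | 12 |
| indices | NDVI, EVI, ARVI, water, built-up proxy (segment means) | 5 |
| distribution | per-band min, max, median; NIR range | 13 |

The decomposition itself is a package decision — the literature this
design follows states the total (85) without enumerating the inventory —
so the manifest is serialized alongside every feature table and any other
decomposition with the same contract is pluggable. The raw group total is
88; the three non-NIR band ranges are dropped as redundant with min/max to
keep the documented count.

Notable definitions:

* Standard deviations are population-form, so a single-pixel segment has
  sd 0.
* Geometry derives from the pixel-coordinate covariance matrix with
  Sheppard's correction ($+1/12$ per axis, treating pixels as unit
  squares): the length–width ratio $\sqrt{\lambda_1/\lambda_2}$ of a solid
  $a\times b$ rectangle is then exactly $a/b$. Density is
  $\sqrt{A}/(1+\sqrt{\lambda_1+\lambda_2})$ and rectangular fit is the area
  over the area of the principal-axis-oriented bounding rectangle, clipped
  to $(0,1]$ (the $+1$-per-axis extent slightly underestimates rotated
  boxes). These are the eCognition-style definitions common in object-based
  image analysis.
* Texture is computed per segment on its bounding box masked to the
  segment; pixel pairs crossing the mask are discarded. Each band is
  quantized linearly to 16 grey levels over the segment's own min–max range
  (bounded co-occurrence matrices, standard OBIA practice). Two symmetric,
  normalized co-occurrence offsets are used — $(0,1)$ and $(1,0)$ — and the
  grey-level difference vector pools both. The feature inventory's
  "heterogeneity" is implemented as GLCM dissimilarity
  $\sum P\,|i-j|$; contrast ($\sum P\,(i-j)^2$) is the other common reading
  and the choice is flagged here. GLCM and diversity entropies use the
  natural log; tree-induction entropies use bits, matching each formula's
  convention.
* The "building area index" is a visible/NIR proxy,
  $((\rho_{red}-\rho_{nir})/(\rho_{red}+\rho_{nir}) +
  (\rho_{red}-\rho_{green})/(\rho_{red}+\rho_{green}))/2$, because the
  standard NDBI requires a SWIR band that four-band imagery lacks; it is
  named `builtup` to avoid overclaiming.
* Every zero-denominator pixel in an index contributes 0 and raises a
  warning; every feature is finite on every valid scene.

## Vegetation metrics

Diversity indices for a plot with $N$ species, $X$ total individuals and
importance values $Z_M$ (summing to 1): Shannon diversity
$S_W = -\sum Z_M \ln Z_M$, richness $F = (N-1)/\ln X$ (requires
$X \ge 2$), and dominance $Y = 1 - \sum Z_M^2$.

The enhanced vegetation index is
$E = O\,(\rho_{nir}-\rho_{red}) / (\rho_{nir} + V_1\rho_{red} -
V_2\rho_{blue} + D)$ with MODIS-convention defaults $O = 2.5$, $V_1 = 6$,
$V_2 = 7.5$, $D = 1$ (all configurable). Pixels whose denominator falls at
or below `eps` are flagged `NA`, never silently zeroed. NDVI is
$(\rho_{nir}-\rho_{red})/(\rho_{nir}+\rho_{red})$, defined as 0 when both
bands are 0.

Fractional vegetation cover uses the dimidiate-pixel model — the universal
VI-to-cover unmixing — $f = (VI - VI_{soil})/(VI_{veg} - VI_{soil})$,
clipped to $[0,1]$. Endmembers come from user-supplied pure spectra when
available, otherwise from the 5th/95th percentiles of the VI grid.

Cover validation reports the determination coefficient
$K^2 = \sum(\hat J_p - \bar j)^2 / \sum(j_p - \bar j)^2$ — the
regression-SS over total-SS form; the conventional $1 - SSE/SST$ is
available via `method = "one_minus_sse"`, and the two coincide only for a
least-squares fit — and the RMSE $W = \sqrt{\sum(j_p - \hat J_p)^2/q}$.
Both are computed over $q$ *sample plots*, not pixels:
`estimate_cover_scene` averages truth and estimate over 8 px × 8 px tiles
by default (`validation_plot_size`). This mirrors how cover truth is
actually obtained (field quadrats) and measures estimator bias rather than
per-pixel band noise; with per-pixel validation (`validation_plot_size =
NULL`) the statistic is dominated by noise propagated through the index —
EVI's $V_1, V_2$ coefficients amplify red/blue noise several-fold — which
says little about the unmixing itself.

## Thematic accuracy

Predictions on held-out objects are assessed through a confusion matrix
with rows = predicted class and columns = true class (the orientation is
fixed and documented; symbol conventions in the surrounding literature are
ambiguous). Overall accuracy is $\sum_i m_{ii} / T$. A variant sometimes
printed in the source formulation subtracts $\sum_i m_{ii}/c$ from this
ratio; it cannot produce the accuracy levels reported alongside it and is
treated as a typographical artifact, but remains available
(`printed_variant = TRUE`) for auditability. Producer's (map) accuracy of a
class is its diagonal count over its column total, user's accuracy over its
row total; classes never present (or never predicted) report `NA` rather
than 0 so averages are not biased. The kappa coefficient is
$(T\sum_i m_{ii} - \sum_g r_g c_g)/(T^2 - \sum_g r_g c_g)$ over row totals
$r_g$ and column totals $c_g$, `NA` when the denominator vanishes.

## Synthetic scenes: what they emulate, and what they do not

The generators provide ground-truthed inputs shaped like the study design
the classifier targets:

* **Scenes** (`generate_scene`): segments are Voronoi cells of uniformly
  sampled points — irregular object shapes with a controllable count,
  standing in for a real segmentation step that is out of scope. Each
  segment gets a class (largest-remainder counts from the configured
  proportions, randomly permuted, every positive-proportion class
  guaranteed at least one segment), and each pixel is the class endmember
  spectrum plus independent per-band Gaussian noise, clipped to $[0,1]$.
  The default endmembers — grassland (0.06, 0.10, 0.08, 0.30), forest
  (0.04, 0.07, 0.05, 0.45), soil (0.15, 0.18, 0.20, 0.25) — are plausible
  synthetic reflectances chosen by the implementers, not measurements.
* **Feature tables** (`generate_feature_table`): 85 standard-normal
  features over 45 positive and 932 negative objects by default — the
  training imbalance of the motivating design — with 5
  positive-informative and 5 negative-informative features shifted by
  `effect_size` (default 1.5) for the respective class.
* **Cover fields** (`generate_cover_scene`): a smooth random cover field
  (uniform coarse grid, bilinear interpolation, correlation length
  `cover_field_smoothness` = 16 px) drives a linear vegetation/soil
  mixture per pixel; with zero noise the mixture is exactly invertible.

One master seed governs a named substream per generator, so consuming one
generator never shifts another's output.

What passing tests on these data show: correctness of the feature
inventory, induction, pruning, bagging, weighting, voting and accuracy
machinery, and the qualitative imbalance benefit of weighted subsampling.
What they do not show: performance on real imagery. The generators have no
atmospheric or sensor effects, no within-class spectral mixtures, no
spatially correlated noise, no mis-segmentation, and class separations are
set by the configured endmembers — on the default scenes the classes are
cleanly separable and the pipeline reaches perfect hold-out accuracy,
which is a property of the simulation, not a performance claim.

## Problem sizes and experiment design

The end-to-end pipeline (`run_pipeline`) simulates a 256 × 256 px training
scene with 977 objects (932 grassland / 45 forest) and an independent
validation scene with 1054 objects (1031 / 23), extracts both 85-feature
tables, trains a 100-tree forest at $\lambda = 0.5$, and reports hold-out
and OOB accuracy plus EVI cover recovery on a 128 × 128 px cover scene
(256 validation plots). Segment sizes average roughly 65 pixels so texture
statistics have support.

The paired imbalance experiment (`imbalance_experiment`) draws 20
independent feature tables at the 932/45 design with 5
positive-informative features at effect size 1.5, trains one forest at
$\lambda = 0.5$ and one at $\lambda = 0$ per table (50 trees each — enough
for stable votes at desk scale), and compares the median OOB recall of the
positive class. Under these conditions weighted subsampling raises median
minority recall from near zero to roughly 0.4; the paired design makes the
comparison seed-for-seed.

## Numerical choices and edge cases

* Entropy terms $0\log 0$ are 0 throughout; `min_gain` = $10^{-6}$ bits
  absorbs floating-point noise in gains.
* Constant features yield no candidates; a table whose admissible
  candidates all fall below `min_gain` yields a leaf.
* Degenerate covariance (collinear pixel masks) is floored at
  $\lambda \ge 10^{-12}$; the Sheppard term keeps $\lambda_2 \ge 1/12$ for
  any non-empty mask.
* An all-`NA` co-occurrence window (single-pixel segment) maps to the
  constant-image statistics (homogeneity 1, ASM 1, others 0).
* Feature weights are floored at $10^{-12}$ before renormalization so no
  feature is ever unselectable, even at $\lambda = 1$ with zero scores.
* `estimate_cover` requires $VI_{veg} > VI_{soil}$ and errors otherwise;
  richness requires $X \ge 2$; accuracy metrics return `NA`, not 0, for
  empty rows/columns.
* Scene I/O uses plain multiband 32-bit float TIFF plus a JSON sidecar
  (band order, segment-id scale); geographic projection metadata is
  pass-through only and out of scope.

## Known limitations

* The tree grower handles numeric features only; categorical predictors
  would need encoding.
* Pessimistic pruning with leaf-summed binomial bounds is known to
  underprune very large noisy trees; the `min_leaf = 2` default mitigates
  the worst case but does not eliminate it.
* The one-vs-rest weighting targets a single positive class; multi-minority
  problems would need one weighting per minority class or a different
  score.
* Voronoi segments are convex-ish and equal-area on average — friendlier
  than real segmentations with sliver and mixed objects.
* The dimidiate-pixel model assumes two endmembers and a linear VI-cover
  relation; the EVI's rational form makes this only approximately true,
  which is visible as the ~0.02 plot-level bias in cover recovery.
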