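# vegrf

Object-based vegetation classification for four-band (blue, green, red,
NIR) multispectral imagery, built around a random forest of C5.0-style
gain-ratio decision trees with **positive-class-weighted feature
subsampling** for imbalanced classes — for example, scattered forest
patches inside extensive grassland, where a classical forest simply votes
the minority class away.

The package is a complete desk-scale toolkit for remote-sensing and
landscape-ecology work:

* **Synthetic scenes with ground truth** — Voronoi-segmented multispectral
  scenes, imbalanced labelled feature tables, and linear-mixture cover
  fields, so every stage is testable without satellite downloads.
* **An 85-feature object inventory** — per-segment spectral statistics,
  eCognition-style geometry, grey-level co-occurrence (GLCM) and
  difference-vector (GLDV) texture, and vegetation-index means
  (NDVI, EVI, ARVI, water, built-up proxy).
* **From-scratch tree induction** — entropy/information gain/gain ratio in
  bits, the C4.5 mean-gain guard, deterministic tie-breaks, and bottom-up
  pessimistic pruning with an upper binomial confidence bound.
* **The weighted-feature forest** — bagging with per-tree feature subsets
  drawn with probability `(1 - λ)/F + λ · s_j / Σs`, where `s_j` is feature
  `j`'s best one-vs-rest gain ratio for the positive class; `λ = 0` is the
  classical random forest. Out-of-bag scoring and gain-based feature
  importance included.
* **Vegetation metrics** — Shannon diversity `S_W = -Σ Z ln Z`, richness
  `F = (N-1)/ln X`, dominance `Y = 1 - Σ Z²`; EVI
  `E = O(ρ_nir - ρ_red)/(ρ_nir + V1·ρ_red - V2·ρ_blue + D)`;
  dimidiate-pixel fractional cover `f = (VI - VI_soil)/(VI_veg - VI_soil)`
  with K²/RMSE validation over sample plots.
* **Thematic accuracy** — confusion matrix, overall/producer's/user's
  accuracy and the kappa coefficient.

See `vignettes/vegrf-methods.Rmd` for the full model description, design
decisions and limitations.

## Worked example

```r
library(vegrf)

# a labelled synthetic scene: 80 objects, ~10% forest in grassland
sc <- generate_scene(scene_config(height = 96, width = 96, n_segments = 80,
                                  class_proportions = c(0.9, 0.1), seed = 1))
ft <- build_feature_table(sc)              # 80 objects x 85 features

model <- train_forest(ft, forest_config(n_trees = 50, lambda_weight = 0.5,
                                        positive_class = "forest", seed = 1))
oob <- oob_score(model, ft)
sort(feature_importance(model), decreasing = TRUE)[1:5]

# hold-out evaluation on an independent scene
val  <- generate_scene(scene_config(height = 96, width = 96, n_segments = 80,
                                    class_proportions = c(0.9, 0.1), seed = 2))
vft  <- build_feature_table(val)
pred <- predict_forest(model, vft)
accuracy_report(confusion_matrix(vft$label, pred$label))
```

prints

```
      arvi brightness    max_nir   max_diff        evi
     0.334      0.142      0.135      0.125      0.097
Thematic accuracy report
  n = 80, overall accuracy = 1.0000, kappa = 1.0000
  forest       producer's = 1  user's = 1
  grassland    producer's = 1  user's = 1
Confusion matrix (rows = predicted, cols = true):
           true
predicted   forest grassland
  forest         8         0
  grassland      0        72
```

The top-ranked features are exactly the NIR-driven ones that separate the
two synthetic endmember spectra, and the hold-out classification is
perfect — a property of the cleanly separable simulation, not a field
performance claim. Where the weighting earns its keep is under the severe
932/45 training imbalance with weak effects: there `imbalance_experiment()`
shows the weighted forest (λ = 0.5) lifting median out-of-bag forest recall
from roughly 0 to ~0.4 against the classical forest on identical data.

Fractional cover, diversity indices:

```r
cov <- generate_cover_scene(noise_sd = 0.01, seed = 1)
est <- estimate_cover_scene(cov$scene, index = "evi",
                            veg_spectrum = default_endmembers()$forest,
                            soil_spectrum = default_endmembers()$soil,
                            true_cover = cov$true_cover)
est$validation  # K2 = 0.990, RMSE = 0.024 over 256 sample plots

shannon_diversity(c(0.5, 0.3, 0.2))  # 1.0297
richness(5, 100)                     # 0.8686
dominance(c(0.5, 0.3, 0.2))          # 0.62
```

## Command line

`inst/cli/vegrf.R` wires the stages into a pipeline with reproducible
seeds (precedence: flags > YAML config > defaults):

```sh
Rscript inst/cli/vegrf.R simulate  --seed 1 --out sim
Rscript inst/cli/vegrf.R features  --scene sim/scene --out feats
Rscript inst/cli/vegrf.R train     --features feats/features.csv --out model
Rscript inst/cli/vegrf.R predict   --features feats/features.csv --model model/model.json --out preds
Rscript inst/cli/vegrf.R evaluate  --truth sim/scene_labels.csv --predictions preds/predictions.csv --out ev
Rscript inst/cli/vegrf.R cover     --scene sim/scene --out cov
Rscript inst/cli/vegrf.R end-to-end --seed 1 --out run
```

Scenes travel as multiband float TIFF + segment TIFF + label CSV, feature
tables as CSV with a JSON column manifest, models as JSON bundles, reports
as JSON; every artifact embeds the config hash.

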