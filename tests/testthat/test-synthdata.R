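# Scene, table and cover-field generators: determinism, ground-truth
# bookkeeping, and recoverable structure.

test_that("scene generation is deterministic and validates its config", {
  cfg <- scene_config(height = 48, width = 40, n_segments = 12, seed = 5)
  a <- generate_scene(cfg)
  b <- generate_scene(cfg)
  expect_identical(a, b)
  expect_error(scene_config(class_proportions = c(0.6, 0.3)), "sum to 1")
  expect_error(scene_config(noise_sd = -0.1), "noise_sd")
  expect_error(scene_config(n_segments = 1), "at least the number of classes")
})

test_that("zero-noise pixels equal their class endmember exactly", {
  cfg <- scene_config(height = 32, width = 32, n_segments = 8,
                      noise_sd = 0, seed = 2)
  sc <- generate_scene(cfg)
  for (id in sort(unique(as.integer(sc$segments)))) {
    cl <- sc$labels[[as.character(id)]]
    idx <- which(sc$segments == id)
    for (k in seq_along(vegrf:::BAND_NAMES)) {
      b <- vegrf:::BAND_NAMES[k]
      expect_equal(unique(sc$bands[[b]][idx]),
                   unname(cfg$endmember_spectra[[cl]][k]))
    }
  }
})

test_that("every segment id has exactly one label and counts match config", {
  cfg <- scene_config(height = 64, width = 64, n_segments = 25, seed = 11)
  sc <- generate_scene(cfg)
  ids <- sort(unique(as.integer(sc$segments)))
  expect_length(ids, 25)
  expect_setequal(names(sc$labels), as.character(ids))
  expect_false(anyDuplicated(names(sc$labels)) > 0)
  # largest-remainder class counts for 25 segments at (0.92, 0.08)
  expect_equal(unname(table(sc$labels)[c("grassland", "forest")]),
               c(23L, 2L), ignore_attr = TRUE)
})

test_that("per-class mean reflectance tracks the endmember spectrum", {
  cfg <- scene_config(height = 80, width = 80, n_segments = 20,
                      noise_sd = 0.02, seed = 3)
  sc <- generate_scene(cfg)
  for (cl in cfg$class_names) {
    ids <- names(sc$labels)[sc$labels == cl]
    idx <- which(sc$segments %in% as.integer(ids))
    for (k in seq_along(vegrf:::BAND_NAMES)) {
      tol <- 3 * cfg$noise_sd / sqrt(length(idx)) + 1e-3 # small clip bias
      expect_lt(abs(mean(sc$bands[[vegrf:::BAND_NAMES[k]]][idx]) -
                      cfg$endmember_spectra[[cl]][k]), tol)
    }
  }
})

test_that("per-segment mean NIR separates the two classes almost perfectly", {
  cfg <- scene_config(height = 96, width = 96, n_segments = 60,
                      class_proportions = c(0.5, 0.5),
                      noise_sd = 0.02, seed = 9)
  sc <- generate_scene(cfg)
  ids <- sort(unique(as.integer(sc$segments)))
  nir_mean <- vapply(ids, function(id)
    mean(sc$bands$nir[sc$segments == id]), numeric(1))
  truth <- sc$labels[as.character(ids)] == "forest"
  # best 1-D threshold accuracy
  acc <- max(vapply(sort(nir_mean), function(t)
    max(mean((nir_mean > t) == truth), mean((nir_mean <= t) == truth)),
    numeric(1)))
  expect_gt(acc, 0.99)
})

test_that("feature-table generator honours counts, effect structure, errors", {
  ft <- generate_feature_table(table_config(seed = 1))
  expect_equal(nrow(ft), 977) # 45 positive + 932 negative
  expect_length(feature_names(ft), 85)
  expect_equal(sum(ft$label == "forest"), 45)
  expect_identical(ft, generate_feature_table(table_config(seed = 1)))
  expect_error(table_config(n_pos = 0), "at least one object")
  expect_error(table_config(n_informative_pos = 50, n_informative_neg = 50),
               "exceed")
})

test_that("informative columns carry larger two-sample t statistics", {
  # over 100 seeds the mean |t| on positive-informative columns must exceed
  # the mean |t| on noise columns in >95% of seeds
  hits <- vapply(1:100, function(s) {
    ft <- generate_feature_table(table_config(
      n_pos = 45, n_neg = 200, n_feat_total = 20,
      n_informative_pos = 5, n_informative_neg = 0,
      effect_size = 2, seed = s))
    x <- feature_matrix(ft)
    pos <- ft$label == "forest"
    tstat <- abs(vapply(seq_len(ncol(x)), function(j)
      t.test(x[pos, j], x[!pos, j])$statistic, numeric(1)))
    info <- attr(ft, "informative_pos")
    mean(tstat[colnames(x) %in% info]) > mean(tstat[!colnames(x) %in% info])
  }, logical(1))
  expect_gt(mean(hits), 0.95)
})

test_that("effect_size 0 leaves positive and negative rows exchangeable", {
  ft <- generate_feature_table(table_config(
    n_pos = 200, n_neg = 200, n_feat_total = 10, effect_size = 0, seed = 4))
  x <- feature_matrix(ft)
  pos <- ft$label == "forest"
  p <- vapply(seq_len(ncol(x)), function(j)
    t.test(x[pos, j], x[!pos, j])$p.value, numeric(1))
  expect_gt(min(p), 0.001) # no column shows a systematic class shift
})

test_that("cover scene is an exact linear mixture (zero-noise inversion)", {
  em <- default_endmembers()
  out <- generate_cover_scene(height = 32, width = 32, noise_sd = 0, seed = 6)
  # invert per band: f = (x - soil) / (veg - soil)
  for (k in seq_along(vegrf:::BAND_NAMES)) {
    b <- vegrf:::BAND_NAMES[k]
    f <- (out$scene$bands[[b]] - em$soil[k]) / (em$forest[k] - em$soil[k])
    expect_equal(f, out$true_cover, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("constant-cover scenes reproduce the pure endmember spectra", {
  em <- default_endmembers()
  soil_only <- generate_cover_scene(height = 8, width = 8, noise_sd = 0,
                                    cover = 0, seed = 1)
  veg_only <- generate_cover_scene(height = 8, width = 8, noise_sd = 0,
                                   cover = 1, seed = 1)
  for (k in seq_along(vegrf:::BAND_NAMES)) {
    b <- vegrf:::BAND_NAMES[k]
    expect_equal(unique(as.vector(soil_only$scene$bands[[b]])),
                 unname(em$soil[k]))
    expect_equal(unique(as.vector(veg_only$scene$bands[[b]])),
                 unname(em$forest[k]))
  }
})

test_that("generators draw from independent named substreams", {
  # consuming one generator does not change another generator's output
  cfg <- table_config(n_pos = 5, n_neg = 5, n_feat_total = 4,
                      n_informative_pos = 1, n_informative_neg = 1,
                      seed = 42)
  t1 <- generate_feature_table(cfg)
  invisible(generate_scene(scene_config(height = 16, width = 16,
                                        n_segments = 4, seed = 42)))
  t2 <- generate_feature_table(cfg)
  expect_identical(t1, t2)
})
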