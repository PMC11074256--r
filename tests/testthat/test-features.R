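# Feature extraction: spectral statistics, geometry, GLCM/GLDV texture,
# index means, and the 85-column manifest contract.

constant_scene <- function(vals = c(0.2, 0.2, 0.2, 0.2), n = 4) {
  bands <- setNames(lapply(vals, function(v) matrix(v, n, n)),
                    vegrf:::BAND_NAMES)
  raster_scene(bands, matrix(1L, n, n))
}

test_that("spectral features: constant, hand-computed, single-pixel cases", {
  sc <- constant_scene()
  f <- spectral_features(sc, 1)
  expect_equal(unname(f[paste0("mean_", vegrf:::BAND_NAMES)]), rep(0.2, 4))
  expect_equal(unname(f[paste0("sd_", vegrf:::BAND_NAMES)]), rep(0, 4))
  expect_equal(unname(f["brightness"]), 0.2)
  expect_equal(unname(f["max_diff"]), 0)

  sc2 <- constant_scene(c(0.1, 0.2, 0.3, 0.4))
  f2 <- spectral_features(sc2, 1)
  expect_equal(unname(f2["brightness"]), 0.25)
  expect_equal(unname(f2["max_diff"]), (0.4 - 0.1) / 0.25) # = 1.2

  # single-pixel segment: population sd is 0 for every band
  seg <- matrix(1L, 3, 3); seg[2, 2] <- 2L
  sc3 <- raster_scene(setNames(lapply(1:4, function(k)
    matrix(runif(9), 3)), vegrf:::BAND_NAMES), seg)
  expect_equal(unname(spectral_features(sc3, 2)[paste0("sd_",
    vegrf:::BAND_NAMES)]), rep(0, 4))
  expect_error(spectral_features(sc3, 99), "not present")
})

test_that("geometric features match closed forms for rectangles and pixels", {
  sq <- geometric_features(matrix(TRUE, 10, 10))
  expect_equal(unname(sq["area"]), 100)
  expect_equal(unname(sq["perimeter"]), 40)
  expect_equal(unname(sq["length_width_ratio"]), 1.0)
  expect_equal(unname(sq["rect_fit"]), 1.0)

  # uniform a x b rectangle: sqrt(lambda1/lambda2) equals the side ratio
  rect <- geometric_features(matrix(TRUE, 20, 5))
  expect_equal(unname(rect["length_width_ratio"]), 4.0, tolerance = 1e-12)
  expect_equal(unname(rect["rect_fit"]), 1.0, tolerance = 1e-12)

  px <- geometric_features(matrix(TRUE, 1, 1))
  expect_equal(unname(px["area"]), 1)
  expect_equal(unname(px["perimeter"]), 4)
  expect_equal(unname(px["length_width_ratio"]), 1.0)
  expect_error(geometric_features(matrix(FALSE, 3, 3)), "empty")
})

test_that("geometric features are translation invariant; area and perimeter
          survive 90-degree rotation", {
  set.seed(21)
  for (rep in 1:10) {
    blob <- matrix(FALSE, 30, 30)
    blob[5:12, 4:9] <- TRUE
    blob[sample(900, 40)] <- TRUE
    base <- geometric_features(blob)
    shifted <- matrix(FALSE, 40, 40)
    shifted[7 + seq_len(30) - 1, 9 + seq_len(30) - 1] <- blob
    expect_equal(geometric_features(shifted), base, tolerance = 1e-10)
    rot <- t(blob[nrow(blob):1, ])
    rf <- geometric_features(rot)
    expect_equal(rf[c("area", "perimeter")], base[c("area", "perimeter")])
  }
})

test_that("GLCM counts, symmetry and normalization follow the definition", {
  const <- matrix(3L, 4, 4)
  P <- glcm(const, glcm_spec(levels = 8))
  expect_equal(P[4, 4], 1) # all mass on the (3,3) diagonal cell
  expect_equal(sum(P), 1)

  g <- matrix(c(0L, 0L, 1L, 1L), 2, 2) # [[0,1],[0,1]] row-wise
  P2 <- glcm(g, glcm_spec(levels = 2, offsets = list(c(0L, 1L))))
  expect_equal(P2[1, 2], 0.5)
  expect_equal(P2[2, 1], 0.5)
  expect_equal(P2[1, 1] + P2[2, 2], 0)

  expect_error(glcm(matrix(5L, 2, 2), glcm_spec(levels = 4)), "levels")

  set.seed(8)
  r <- matrix(sample(0:7, 64, replace = TRUE), 8)
  expect_equal(sum(glcm(r, glcm_spec(levels = 8,
                                     offsets = list(c(0L, 1L), c(1L, 0L))))), 1)
})

test_that("glcm_stats matches hand arithmetic and brute-force summation", {
  single <- matrix(0, 4, 4); single[2, 2] <- 1
  s <- glcm_stats(single)
  expect_equal(unname(s), c(1, 0, 0, 1, 0),
               ignore_attr = TRUE) # homog, var, dissim, asm, entropy

  two <- matrix(0, 3, 3); two[1, 2] <- 0.5; two[2, 1] <- 0.5
  s2 <- glcm_stats(two)
  expect_equal(unname(s2["dissimilarity"]), 1.0)
  expect_equal(unname(s2["asm"]), 0.5)
  expect_equal(unname(s2["entropy"]), log(2), tolerance = 1e-12)

  expect_error(glcm_stats(matrix(0.4, 2, 2)), "normalized")

  # brute-force double-loop oracle on random 8-level matrices
  set.seed(33)
  for (rep in 1:20) {
    P <- matrix(rexp(64), 8); P <- P / sum(P)
    s <- glcm_stats(P)
    L <- 8
    hom <- v <- dis <- asm <- ent <- 0
    mu <- 0
    for (i in 0:(L - 1)) for (j in 0:(L - 1)) mu <- mu + P[i + 1, j + 1] * i
    for (i in 0:(L - 1)) for (j in 0:(L - 1)) {
      p <- P[i + 1, j + 1]
      hom <- hom + p / (1 + (i - j)^2)
      v <- v + p * (i - mu)^2
      dis <- dis + p * abs(i - j)
      asm <- asm + p^2
      if (p > 0) ent <- ent - p * log(p)
    }
    expect_equal(unname(s), c(hom, v, dis, asm, ent), tolerance = 1e-12)
    expect_true(s["asm"] > 0 && s["asm"] <= 1)
    expect_gte(s["entropy"], 0)
  }
})

test_that("GLDV is the anti-diagonal marginal of the symmetric GLCM", {
  const <- matrix(2L, 5, 5)
  g0 <- gldv_stats(const, glcm_spec(levels = 4))
  expect_equal(unname(g0), c(0, 0, 1), ignore_attr = TRUE)

  g <- matrix(c(0L, 0L, 1L, 1L), 2, 2)
  g1 <- gldv_stats(g, glcm_spec(levels = 2, offsets = list(c(0L, 1L))))
  expect_equal(unname(g1["gldv_mean"]), 1.0)

  set.seed(12)
  for (rep in 1:10) {
    img <- matrix(sample(0:7, 100, replace = TRUE), 10)
    spec <- glcm_spec(levels = 8, offsets = list(c(0L, 1L)))
    gd <- gldv_stats(img, spec)
    P <- glcm(img, spec)
    marg <- vapply(0:7, function(k) {
      tot <- 0
      for (i in 0:7) for (j in 0:7) if (abs(i - j) == k)
        tot <- tot + P[i + 1, j + 1]
      tot
    }, numeric(1))
    expect_equal(unname(gd["gldv_mean"]), sum((0:7) * marg), tolerance = 1e-12)
    expect_equal(unname(gd["gldv_asm"]), sum(marg^2), tolerance = 1e-12)
  }
})

test_that("index features match scalar hand arithmetic and guards", {
  # NIR == red -> NDVI 0; green == NIR -> water index 0
  sc <- constant_scene(c(0.05, 0.3, 0.3, 0.3))
  f <- suppressWarnings(index_features(sc, 1))
  expect_equal(unname(f["ndvi"]), 0)
  expect_equal(unname(f["water"]), 0)

  # ARVI = (0.4 - (2*0.1 - 0.05)) / (0.4 + (2*0.1 - 0.05)) = 0.4545...
  sc2 <- constant_scene(c(0.05, 0.2, 0.1, 0.4))
  f2 <- index_features(sc2, 1)
  expect_equal(unname(f2["arvi"]), 0.25 / 0.55, tolerance = 1e-12)
})

test_that("default manifest yields exactly 85 uniquely named features", {
  man <- default_manifest()
  expect_length(man$feature_names, 85)
  expect_false(anyDuplicated(man$feature_names) > 0)
  for (seed in c(1, 7)) {
    sc <- generate_scene(scene_config(height = 40, width = 40,
                                      n_segments = 10, seed = seed))
    ft <- suppressWarnings(build_feature_table(sc))
    expect_identical(feature_names(ft), man$feature_names)
    expect_equal(nrow(ft), 10)
    expect_true(all(is.finite(feature_matrix(ft))))
    expect_identical(ft$label, unname(sc$labels[as.character(ft$object_id)]))
  }
})

test_that("feature tables are deterministic and numbering-invariant", {
  sc <- generate_scene(scene_config(height = 36, width = 36, n_segments = 8,
                                    seed = 13))
  ft1 <- suppressWarnings(build_feature_table(sc))
  ft2 <- suppressWarnings(build_feature_table(sc))
  expect_identical(ft1, ft2)

  # permute the segment numbering: same rows up to reordering
  ids <- sort(unique(as.integer(sc$segments)))
  perm <- rev(ids)
  seg2 <- matrix(perm[match(as.integer(sc$segments), ids)],
                 nrow = nrow(sc$segments))
  lab2 <- setNames(unname(sc$labels[as.character(ids)]), as.character(perm))
  sc2 <- raster_scene(sc$bands, seg2, lab2)
  ft3 <- suppressWarnings(build_feature_table(sc2))
  # new id perm[k] carries the pixels of old id ids[k]
  m1 <- feature_matrix(ft1)[match(ids, ft1$object_id), ]
  m3 <- feature_matrix(ft3)[match(perm, ft3$object_id), ]
  expect_equal(m1, m3, tolerance = 1e-12, ignore_attr = TRUE)
})
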