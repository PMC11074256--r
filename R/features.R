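# Object-level feature extraction: spectral statistics, geometry, grey-level
# co-occurrence / difference-vector texture, and vegetation-index means.
# The default manifest yields exactly 85 named features per image object.

#' Spectral features of one segment
#'
#' Per-band mean and standard deviation (population form, so a single-pixel
#' segment has sd 0), overall brightness (mean of the four band means) and
#' maximum difference `(max band mean - min band mean) / brightness`
#' (0 when brightness is 0).
#'
#' @param scene a [raster_scene()].
#' @param segment_id a segment id present in the scene.
#' @return named numeric vector:
#'   `mean_<band>`, `sd_<band>`, `brightness`, `max_diff`.
#' @export
spectral_features <- function(scene, segment_id) {
  idx <- which(scene$segments == segment_id)
  if (!length(idx)) stop("segment ", segment_id, " not present in scene")
  out <- numeric(0)
  means <- numeric(4)
  for (k in seq_along(BAND_NAMES)) {
    v <- scene$bands[[BAND_NAMES[k]]][idx]
    means[k] <- mean(v)
    out[paste0("mean_", BAND_NAMES[k])] <- means[k]
    out[paste0("sd_", BAND_NAMES[k])] <- sqrt(mean((v - means[k])^2))
  }
  brightness <- mean(means)
  out["brightness"] <- brightness
  out["max_diff"] <- if (brightness > 0) (max(means) - min(means)) / brightness else 0
  out
}

#' Geometric features of a segment mask
#'
#' Shape descriptors in the object-based image-analysis tradition, computed
#' from the mask's pixel-coordinate covariance with Sheppard's correction
#' (`+ 1/12` per axis, treating pixels as unit squares), so a solid `a x b`
#' rectangle has length-width ratio exactly `a / b`:
#' \itemize{
#'   \item `area`: pixel count;
#'   \item `perimeter`: number of exposed 4-neighbour pixel edges;
#'   \item `length_width_ratio`: `sqrt(lambda1 / lambda2)` of the covariance
#'     eigenvalues (1 for degenerate minor axis);
#'   \item `density`: `sqrt(area) / (1 + sqrt(lambda1 + lambda2))`;
#'   \item `rect_fit`: area over the area of the principal-axis-oriented
#'     bounding rectangle, clipped to `(0, 1]`.
#' }
#'
#' @param segment_mask logical matrix, `TRUE` on the object.
#' @return named numeric vector of the five descriptors.
#' @export
geometric_features <- function(segment_mask) {
  if (!any(segment_mask)) stop("empty segment mask")
  idx <- which(segment_mask, arr.ind = TRUE)
  n <- nrow(idx)
  # exposed 4-neighbour edges: border-of-matrix edges count as exposed
  m <- segment_mask
  pad <- matrix(FALSE, nrow(m) + 2, ncol(m) + 2)
  pad[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
  core <- pad[2:(nrow(m) + 1), 2:(ncol(m) + 1), drop = FALSE]
  perim <- sum(core & !pad[1:nrow(m), 2:(ncol(m) + 1), drop = FALSE]) +
    sum(core & !pad[3:(nrow(m) + 2), 2:(ncol(m) + 1), drop = FALSE]) +
    sum(core & !pad[2:(nrow(m) + 1), 1:ncol(m), drop = FALSE]) +
    sum(core & !pad[2:(nrow(m) + 1), 3:(ncol(m) + 2), drop = FALSE])
  xy <- cbind(idx[, 1], idx[, 2])
  mu <- colMeans(xy)
  cxy <- sweep(xy, 2, mu)
  covm <- crossprod(cxy) / n + diag(1 / 12, 2)
  ev <- eigen(covm, symmetric = TRUE)
  lam <- pmax(ev$values, 1e-12)
  ratio <- if (lam[2] <= 1e-12) 1 else sqrt(lam[1] / lam[2])
  density <- sqrt(n) / (1 + sqrt(lam[1] + lam[2]))
  proj <- cxy %*% ev$vectors
  ext <- apply(proj, 2, function(p) diff(range(p)) + 1)
  rect <- min(1, n / prod(ext))
  c(area = n, perimeter = perim, length_width_ratio = ratio,
    density = density, rect_fit = rect)
}

#' GLCM specification
#'
#' @param levels grey-level count (>= 2).
#' @param offsets list of length-2 integer `(row, col)` displacements.
#' @param symmetric count each pair in both directions.
#' @param normalized scale the matrix to sum 1.
#' @return a `glcm_spec` list.
#' @export
glcm_spec <- function(levels = 16, offsets = list(c(0L, 1L)),
                      symmetric = TRUE, normalized = TRUE) {
  stopifnot(is_count(levels), levels >= 2, length(offsets) >= 1)
  for (o in offsets) stopifnot(length(o) == 2L, all(o == round(o)))
  structure(list(levels = as.integer(levels), offsets = offsets,
                 symmetric = isTRUE(symmetric), normalized = isTRUE(normalized)),
            class = "glcm_spec")
}

#' Grey-level co-occurrence matrix
#'
#' Counts co-occurring level pairs at each offset (summed over offsets);
#' pairs involving `NA` pixels (outside the object mask) are discarded.
#'
#' @param gray integer matrix with values in `[0, levels)`; `NA` allowed.
#' @param spec a [glcm_spec()].
#' @return `levels x levels` matrix (counts, or probabilities if normalized).
#' @export
glcm <- function(gray, spec = glcm_spec()) {
  vals <- gray[!is.na(gray)]
  if (length(vals) && (min(vals) < 0 || max(vals) >= spec$levels ||
                       any(vals != round(vals))))
    stop("gray levels must be integers in [0, levels)")
  L <- spec$levels
  P <- matrix(0, L, L)
  nr <- nrow(gray); nc <- ncol(gray)
  for (o in spec$offsets) {
    dr <- o[1]; dc <- o[2]
    r1 <- max(1, 1 - dr):min(nr, nr - dr)
    c1 <- max(1, 1 - dc):min(nc, nc - dc)
    if (!length(r1) || !length(c1)) next
    a <- gray[r1, c1, drop = FALSE]
    b <- gray[r1 + dr, c1 + dc, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    tab <- tabulate(a[ok] * L + b[ok] + 1L, nbins = L * L)
    P <- P + matrix(tab, L, L, byrow = TRUE)
  }
  if (spec$symmetric) P <- P + t(P)
  if (spec$normalized && sum(P) > 0) P <- P / sum(P)
  P
}

#' Haralick-style statistics of a normalized GLCM
#'
#' Homogeneity `sum P / (1 + (i - j)^2)`, dissimilarity `sum P |i - j|`
#' (the "heterogeneity" of the OBIA feature inventory), angular second
#' moment `sum P^2`, entropy `-sum P ln P` (natural log, `0 ln 0 := 0`),
#' and variance `sum P (i - mu)^2` with `mu` the P-weighted mean level.
#'
#' @param P square matrix summing to 1.
#' @return named numeric vector
#'   `c(homogeneity, variance, dissimilarity, asm, entropy)`.
#' @export
glcm_stats <- function(P) {
  if (abs(sum(P) - 1) > 1e-8) stop("GLCM must be normalized to sum 1")
  L <- nrow(P)
  i <- matrix(0:(L - 1), L, L)
  j <- t(i)
  mu <- sum(P * i)
  pos <- P > 0
  c(homogeneity = sum(P / (1 + (i - j)^2)),
    variance = sum(P * (i - mu)^2),
    dissimilarity = sum(P * abs(i - j)),
    asm = sum(P^2),
    entropy = -sum(P[pos] * log(P[pos])))
}

#' Grey-level difference vector statistics
#'
#' Histogram of absolute level differences at the given offsets, normalized
#' to sum 1; returns its mean, entropy (natural log) and angular second
#' moment. Equals the anti-diagonal marginal of the symmetric GLCM.
#'
#' @inheritParams glcm
#' @return named numeric vector `c(gldv_mean, gldv_entropy, gldv_asm)`.
#' @export
gldv_stats <- function(gray, spec = glcm_spec()) {
  P <- glcm(gray, glcm_spec(spec$levels, spec$offsets,
                            symmetric = TRUE, normalized = TRUE))
  L <- spec$levels
  d <- abs(matrix(0:(L - 1), L, L) - t(matrix(0:(L - 1), L, L)))
  h <- vapply(0:(L - 1), function(k) sum(P[d == k]), numeric(1))
  if (sum(h) > 0) h <- h / sum(h)
  pos <- h > 0
  c(gldv_mean = sum((0:(L - 1)) * h),
    gldv_entropy = -sum(h[pos] * log(h[pos])),
    gldv_asm = sum(h^2))
}

# Quantize values to [0, levels) linearly over their own min-max range;
# constant input maps to level 0.
quantize_levels <- function(v, levels) {
  rng <- range(v, na.rm = TRUE)
  if (!is.finite(rng[1]) || rng[2] - rng[1] <= 0) {
    q <- v
    q[!is.na(q)] <- 0L
    return(q)
  }
  q <- floor((v - rng[1]) / (rng[2] - rng[1]) * levels)
  pmin(q, levels - 1L)
}

# Pixelwise index grids for a scene, zero-denominator guarded (0 + warning).
index_grids <- function(scene, params = evi_params()) {
  b <- scene$bands
  guard <- function(num, den, what) {
    bad <- abs(den) < 1e-12
    out <- num
    out[!bad] <- num[!bad] / den[!bad]
    if (any(bad)) {
      out[bad] <- 0
      warning(sum(bad), " zero-denominator pixel(s) in ", what,
              " set to 0", call. = FALSE)
    }
    out
  }
  e <- evi(b$nir, b$red, b$blue, params)
  nbad <- sum(is.na(e))
  if (nbad > 0) {
    warning(nbad, " invalid-denominator EVI pixel(s) set to 0", call. = FALSE)
    e[is.na(e)] <- 0
  }
  arvi_red <- 2 * b$red - b$blue
  list(
    ndvi = ndvi(b$nir, b$red),
    evi = e,
    arvi = guard(b$nir - arvi_red, b$nir + arvi_red, "ARVI"),
    water = guard(b$green - b$nir, b$green + b$nir, "water index"),
    builtup = (guard(b$red - b$nir, b$red + b$nir, "built-up proxy") +
                 guard(b$red - b$green, b$red + b$green, "built-up proxy")) / 2
  )
}

#' Vegetation / land-cover index means of one segment
#'
#' Segment means of pixelwise NDVI, EVI, ARVI
#' `(NIR - (2 red - blue)) / (NIR + (2 red - blue))`, water index
#' `(green - NIR) / (green + NIR)` and a visible/NIR built-up proxy
#' `((red - NIR)/(red + NIR) + (red - green)/(red + green)) / 2` (the
#' standard NDBI needs a SWIR band that four-band imagery lacks). Pixels with
#' zero denominators contribute 0 and raise a warning.
#'
#' @inheritParams spectral_features
#' @param params an [evi_params()] coefficient set.
#' @return named numeric vector `c(ndvi, evi, arvi, water, builtup)`.
#' @export
index_features <- function(scene, segment_id, params = evi_params()) {
  idx <- which(scene$segments == segment_id)
  if (!length(idx)) stop("segment ", segment_id, " not present in scene")
  g <- index_grids(scene, params)
  vapply(g, function(grid) mean(grid[idx]), numeric(1))
}

#' Default feature manifest (85 features)
#'
#' The feature inventory covers spectral, geometric, texture and index
#' aspects and totals exactly 85 columns:
#' 4 bands x (mean, sd) = 8; brightness + max difference = 2; 5 geometric;
#' GLCM 5 stats x 4 bands x 2 offsets ((0,1) "h" and (1,0) "v") = 40;
#' GLDV 3 stats x 4 bands = 12; NDVI/EVI/ARVI/water/built-up means = 5;
#' per-band min, max, median = 12; NIR range = 1 (the redundant non-NIR
#' range columns are dropped to keep the total at 85).
#' The manifest is serialized with every feature table so alternative
#' decompositions remain pluggable.
#'
#' @param glcm_levels grey-level count for texture quantization.
#' @return a `feature_manifest` list with `feature_names`, `glcm_levels`,
#'   `offsets` and `version`.
#' @export
default_manifest <- function(glcm_levels = 16) {
  stats5 <- c("homogeneity", "variance", "dissimilarity", "asm", "entropy")
  nm <- c(
    paste0("mean_", BAND_NAMES), paste0("sd_", BAND_NAMES),
    "brightness", "max_diff",
    "area", "perimeter", "length_width_ratio", "density", "rect_fit",
    as.vector(outer(stats5, BAND_NAMES, function(s, b)
      paste0("glcm_", b, "_h_", s))),
    as.vector(outer(stats5, BAND_NAMES, function(s, b)
      paste0("glcm_", b, "_v_", s))),
    as.vector(outer(c("gldv_mean", "gldv_entropy", "gldv_asm"), BAND_NAMES,
                    function(s, b) paste0(sub("gldv_", "gldv_", s), "_", b))),
    "ndvi", "evi", "arvi", "water", "builtup",
    paste0("min_", BAND_NAMES), paste0("max_", BAND_NAMES),
    paste0("median_", BAND_NAMES), "range_nir"
  )
  stopifnot(length(nm) == 85L, !anyDuplicated(nm))
  structure(list(feature_names = nm, glcm_levels = as.integer(glcm_levels),
                 offsets = list(h = c(0L, 1L), v = c(1L, 0L)),
                 version = "1"),
            class = "feature_manifest")
}

#' Build the object-level feature table of a scene
#'
#' One row per segment, columns exactly as listed by the manifest (85 for the
#' default manifest); per-segment texture is computed on the segment's
#' bounding box masked to the segment (pixel pairs crossing the mask are
#' discarded), each band quantized to `glcm_levels` grey levels over the
#' segment's own min-max range. Labels are copied from the scene when
#' present. Every feature is finite on every valid scene.
#'
#' @param scene a [raster_scene()].
#' @param manifest a [default_manifest()]-style manifest.
#' @param params an [evi_params()] coefficient set.
#' @return a [feature_table()] with the manifest attached as attribute
#'   `manifest`.
#' @export
build_feature_table <- function(scene, manifest = default_manifest(),
                                params = evi_params()) {
  ids <- segment_ids(scene)
  if (!length(ids)) stop("scene has no segments")
  grids <- suppressWarnings(index_grids(scene, params))
  specs <- lapply(manifest$offsets, function(o)
    glcm_spec(manifest$glcm_levels, list(o)))
  gldv_spec_all <- glcm_spec(manifest$glcm_levels,
                             unname(manifest$offsets))
  nr <- nrow(scene$segments)
  rows <- lapply(ids, function(id) {
    idx <- which(scene$segments == id)
    rc <- arrayInd(idx, dim(scene$segments))
    rr <- range(rc[, 1]); cc <- range(rc[, 2])
    mask <- scene$segments[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE] == id
    out <- spectral_features(scene, id)
    out <- c(out, geometric_features(mask))
    for (b in BAND_NAMES) {
      sub <- scene$bands[[b]][rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
      sub[!mask] <- NA
      q <- quantize_levels(sub, manifest$glcm_levels)
      for (on in names(specs)) {
        st <- glcm_stats_safe(glcm(q, specs[[on]]))
        names(st) <- paste0("glcm_", b, "_", on, "_", names(st))
        out <- c(out, st)
      }
      gd <- gldv_stats(q, gldv_spec_all)
      names(gd) <- paste0(names(gd), "_", b)
      out <- c(out, gd)
      v <- scene$bands[[b]][idx]
      extra <- c(min(v), max(v), stats::median(v))
      names(extra) <- paste0(c("min_", "max_", "median_"), b)
      out <- c(out, extra)
      if (b == "nir") out <- c(out, c(range_nir = max(v) - min(v)))
    }
    out <- c(out, vapply(grids, function(g) mean(g[idx]), numeric(1)))
    out
  })
  m <- do.call(rbind, rows)
  missing <- setdiff(manifest$feature_names, colnames(m))
  if (length(missing)) stop("manifest features not computed: ",
                            paste(missing, collapse = ", "))
  m <- m[, manifest$feature_names, drop = FALSE]
  lab <- if (!is.null(scene$labels)) unname(scene$labels[as.character(ids)])
  ft <- feature_table(m, object_ids = ids, label = lab)
  attr(ft, "manifest") <- manifest
  ft
}

# glcm_stats on a possibly-empty GLCM (single-pixel segment with no valid
# pixel pairs): all-zero matrix maps to the constant-image statistics.
glcm_stats_safe <- function(P) {
  if (sum(P) == 0) {
    P[1, 1] <- 1
  }
  glcm_stats(P)
}
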