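# Synthetic multispectral scenes, feature tables and cover fields with known
# ground truth. These generators define the study conditions the rest of the
# package is tested under: a two-class (grassland vs forest) object-based
# classification problem with strong class imbalance (932 grassland vs 45
# forest training objects) and spectrally separable classes under Gaussian
# reflectance noise.

BAND_NAMES <- c("blue", "green", "red", "nir")

#' Default synthetic endmember spectra
#'
#' Plausible surface reflectances (blue, green, red, NIR) for grassland,
#' forest and bare soil. These are synthetic stand-ins chosen by the
#' implementers; they are not measurements from any particular sensor.
#'
#' @return a named list of length-4 numeric vectors in `[0, 1]`.
#' @export
default_endmembers <- function() {
  list(
    grassland = c(blue = 0.06, green = 0.10, red = 0.08, nir = 0.30),
    forest    = c(blue = 0.04, green = 0.07, red = 0.05, nir = 0.45),
    soil      = c(blue = 0.15, green = 0.18, red = 0.20, nir = 0.25)
  )
}

#' Scene generator configuration
#'
#' @param height,width scene size in pixels.
#' @param n_segments number of image objects (Voronoi cells).
#' @param class_names class labels, one per class.
#' @param class_proportions fractions of segments per class; must sum to 1.
#'   The default mirrors the training imbalance of roughly 95% grassland.
#' @param endmember_spectra named list (one entry per class) of length-4
#'   mean reflectances in band order blue, green, red, NIR, each in `[0, 1]`.
#' @param noise_sd per-band Gaussian reflectance noise, in reflectance units.
#' @param seed integer seed; the scene generator uses a named substream so
#'   other generators sharing the seed are unaffected.
#' @return a `scene_config` list, validated.
#' @export
scene_config <- function(height = 128, width = 128, n_segments = 60,
                         class_names = c("grassland", "forest"),
                         class_proportions = c(0.92, 0.08),
                         endmember_spectra = default_endmembers()[class_names],
                         noise_sd = 0.02, seed = 1L) {
  stopifnot(is_count(height), height >= 1, is_count(width), width >= 1,
            is_count(n_segments), n_segments >= 1, is_count(seed) || seed < 0)
  if (length(class_names) != length(class_proportions))
    stop("class_names and class_proportions must have equal length")
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stop("class_proportions must sum to 1")
  if (any(class_proportions < 0)) stop("class_proportions must be >= 0")
  if (!all(class_names %in% names(endmember_spectra)))
    stop("endmember_spectra must contain an entry for every class")
  for (cl in class_names) {
    sp <- endmember_spectra[[cl]]
    if (length(sp) != 4L || any(sp < 0) || any(sp > 1))
      stop("endmember spectra must be length-4 reflectances in [0, 1]")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_segments < length(class_names))
    stop("n_segments must be at least the number of classes")
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_segments = as.integer(n_segments),
                 class_names = class_names,
                 class_proportions = class_proportions,
                 endmember_spectra = endmember_spectra,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "scene_config")
}

#' Construct a raster scene
#'
#' A `raster_scene` bundles four reflectance bands (blue, green, red, NIR),
#' an integer segment-id grid of the same shape, and an optional per-segment
#' label map. Segment ids start at 1; every id present in the grid must have
#' exactly one label when labels are supplied.
#'
#' @param bands named list of equally-shaped numeric matrices, names
#'   `c("blue", "green", "red", "nir")`, values in `[0, 1]`.
#' @param segments integer matrix of positive segment ids, same shape.
#' @param labels optional named character vector mapping segment id to label.
#' @return an object of class `raster_scene`.
#' @export
raster_scene <- function(bands, segments, labels = NULL) {
  if (!identical(sort(names(bands)), sort(BAND_NAMES)))
    stop("bands must be named blue, green, red, nir")
  bands <- bands[BAND_NAMES]
  dm <- dim(segments)
  for (b in BAND_NAMES) {
    if (!identical(dim(bands[[b]]), dm)) stop("band grids must match segment grid shape")
    if (anyNA(bands[[b]]) || min(bands[[b]]) < 0 || max(bands[[b]]) > 1)
      stop("reflectances must be finite and in [0, 1]")
  }
  ids <- sort(unique(as.integer(segments)))
  if (any(ids < 1)) stop("segment ids must be positive")
  if (!is.null(labels)) {
    if (is.null(names(labels))) stop("labels must be named by segment id")
    missing <- setdiff(as.character(ids), names(labels))
    if (length(missing)) stop("every segment id needs exactly one label; missing: ",
                              paste(utils::head(missing, 5), collapse = ", "))
  }
  structure(list(bands = bands, segments = segments, labels = labels),
            class = "raster_scene")
}

#' @export
print.raster_scene <- function(x, ...) {
  dm <- dim(x$segments)
  cat(sprintf("raster_scene: %d x %d px, %d segments, labels: %s\n",
              dm[1], dm[2], length(unique(as.integer(x$segments))),
              if (is.null(x$labels)) "none" else
                paste(names(table(x$labels)), table(x$labels), collapse = ", ")))
  invisible(x)
}

segment_ids <- function(scene) sort(unique(as.integer(scene$segments)))

# Deterministic per-class segment counts by largest remainder, each class with
# positive proportion guaranteed at least one segment.
class_counts_from_proportions <- function(n, proportions) {
  raw <- n * proportions
  counts <- floor(raw)
  pos <- proportions > 0
  counts[pos & counts == 0] <- 1
  while (sum(counts) > n) {
    i <- which(counts > 1)[which.max(counts[counts > 1] - raw[counts > 1])]
    counts[i] <- counts[i] - 1
  }
  rem <- n - sum(counts)
  if (rem > 0) {
    ord <- order(raw - counts, decreasing = TRUE)
    for (i in ord[seq_len(rem)]) counts[i] <- counts[i] + 1
  }
  as.integer(counts)
}

# Voronoi tessellation of uniformly sampled seed points; every cell contains
# its own seed pixel so no segment is empty (coincident seeds are redrawn).
voronoi_segments <- function(height, width, n_segments) {
  for (attempt in 1:25) {
    sr <- stats::runif(n_segments, 0.5, height + 0.5)
    sc <- stats::runif(n_segments, 0.5, width + 0.5)
    pr <- rep(seq_len(height), times = width)
    pc <- rep(seq_len(width), each = height)
    d <- outer(pr, sr, "-")^2 + outer(pc, sc, "-")^2
    lab <- max.col(-d, ties.method = "first")
    if (length(unique(lab)) == n_segments)
      return(matrix(lab, nrow = height, ncol = width))
  }
  stop("failed to place ", n_segments, " non-empty Voronoi cells")
}

#' Generate a synthetic labelled multispectral scene
#'
#' Segments are Voronoi cells of uniformly sampled points; each segment is
#' assigned a class (counts follow `class_proportions` deterministically by
#' largest remainder, permuted at random), and each pixel's reflectance is its
#' class endmember plus independent per-band Gaussian noise, clipped to
#' `[0, 1]`. Deterministic for a fixed seed.
#'
#' @param config a [scene_config()].
#' @return a [raster_scene()] with labels.
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  with_seed(substream_seed(config$seed, "scene"), {
    seg <- voronoi_segments(config$height, config$width, config$n_segments)
    counts <- class_counts_from_proportions(config$n_segments,
                                            config$class_proportions)
    seg_class <- sample(rep(config$class_names, counts))
    names(seg_class) <- as.character(seq_len(config$n_segments))
    npix <- length(seg)
    bands <- list()
    for (k in seq_along(BAND_NAMES)) {
      b <- BAND_NAMES[k]
      mu <- vapply(config$endmember_spectra[seg_class], `[[`, numeric(1), k)
      base <- matrix(mu[as.integer(seg)], nrow = config$height)
      noise <- if (config$noise_sd > 0)
        matrix(stats::rnorm(npix, 0, config$noise_sd), nrow = config$height)
      else 0
      bands[[b]] <- clip01(base + noise)
    }
    raster_scene(bands, seg, seg_class)
  })
}

#' Feature-table generator configuration
#'
#' Defaults reproduce the imbalanced two-class design the classifier is
#' studied under: 45 positive (forest) vs 932 negative (grassland) objects,
#' 85 features of which 5 are informative for the positive class and 5 for
#' the negative class, the rest pure noise.
#'
#' @param n_pos,n_neg positive / negative object counts (>= 1 each).
#' @param n_feat_total total feature count (default 85).
#' @param n_informative_pos,n_informative_neg how many features carry a mean
#'   shift for positive (resp. negative) rows.
#' @param effect_size standardized mean shift of informative features.
#' @param positive_class,negative_class class labels.
#' @param seed integer seed (named substream `"table"`).
#' @return a `table_config` list.
#' @export
table_config <- function(n_pos = 45, n_neg = 932, n_feat_total = 85,
                         n_informative_pos = 5, n_informative_neg = 5,
                         effect_size = 1.5,
                         positive_class = "forest",
                         negative_class = "grassland", seed = 1L) {
  stopifnot(is_count(n_pos), is_count(n_neg), is_count(n_feat_total),
            is_count(n_informative_pos), is_count(n_informative_neg))
  if (n_pos < 1 || n_neg < 1) stop("need at least one object per class")
  if (n_informative_pos + n_informative_neg > n_feat_total)
    stop("informative feature counts exceed n_feat_total")
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 n_feat_total = as.integer(n_feat_total),
                 n_informative_pos = as.integer(n_informative_pos),
                 n_informative_neg = as.integer(n_informative_neg),
                 effect_size = effect_size,
                 positive_class = positive_class,
                 negative_class = negative_class,
                 seed = as.integer(seed)),
            class = "table_config")
}

#' Construct a feature table
#'
#' The classifier's substrate: one row per image object, named numeric
#' feature columns, an `object_id` column and an optional `label` column.
#'
#' @param values numeric matrix or data frame, objects x features, with
#'   unique column names.
#' @param object_ids object identifiers (default `1:n`).
#' @param label optional per-object class labels.
#' @return a `data.frame` of class `feature_table`.
#' @export
feature_table <- function(values, object_ids = seq_len(nrow(values)),
                          label = NULL) {
  values <- as.data.frame(values)
  if (anyDuplicated(names(values))) stop("duplicate feature names")
  if (anyNA(values)) stop("feature table must not contain missing values")
  if (length(object_ids) != nrow(values)) stop("object_ids length mismatch")
  out <- cbind(data.frame(object_id = object_ids), values)
  if (!is.null(label)) {
    if (length(label) != nrow(values)) stop("label length mismatch")
    out$label <- as.character(label)
  }
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Feature column names of a feature table
#' @param ft a [feature_table()].
#' @return character vector of feature names (excludes `object_id`, `label`).
#' @export
feature_names <- function(ft) setdiff(names(ft), c("object_id", "label"))

#' Numeric feature matrix of a feature table
#' @inheritParams feature_names
#' @return numeric matrix, objects x features.
#' @export
feature_matrix <- function(ft) {
  as.matrix(ft[, feature_names(ft), drop = FALSE])
}

#' Generate a synthetic labelled feature table
#'
#' All features are standard-normal noise; the first `n_informative_pos`
#' features additionally shift the mean of positive rows by `effect_size`,
#' and the next `n_informative_neg` shift negative rows. Positive rows come
#' first. The informative column names are recorded in the attributes
#' `informative_pos` / `informative_neg`.
#'
#' @param config a [table_config()].
#' @return a labelled [feature_table()].
#' @export
generate_feature_table <- function(config) {
  stopifnot(inherits(config, "table_config"))
  with_seed(substream_seed(config$seed, "table"), {
    n <- config$n_pos + config$n_neg
    f <- config$n_feat_total
    x <- matrix(stats::rnorm(n * f), nrow = n, ncol = f)
    colnames(x) <- sprintf("feat_%03d", seq_len(f))
    pos_rows <- seq_len(config$n_pos)
    ip <- seq_len(config$n_informative_pos)
    inn <- config$n_informative_pos + seq_len(config$n_informative_neg)
    if (length(ip)) x[pos_rows, ip] <- x[pos_rows, ip] + config$effect_size
    if (length(inn)) x[-pos_rows, inn] <- x[-pos_rows, inn] + config$effect_size
    lab <- c(rep(config$positive_class, config$n_pos),
             rep(config$negative_class, config$n_neg))
    ft <- feature_table(x, label = lab)
    attr(ft, "informative_pos") <- colnames(x)[ip]
    attr(ft, "informative_neg") <- colnames(x)[inn]
    ft
  })
}

# Bilinear upsampling of a coarse grid to height x width.
bilinear_field <- function(coarse, height, width) {
  nr <- nrow(coarse); nc <- ncol(coarse)
  r <- seq(1, nr, length.out = height)
  c <- seq(1, nc, length.out = width)
  r0 <- pmin(floor(r), nr - 1); c0 <- pmin(floor(c), nc - 1)
  fr <- r - r0; fc <- c - c0
  a <- coarse[cbind(rep(r0, times = width), rep(c0, each = height))]
  b <- coarse[cbind(rep(r0 + 1, times = width), rep(c0, each = height))]
  d <- coarse[cbind(rep(r0, times = width), rep(c0 + 1, each = height))]
  e <- coarse[cbind(rep(r0 + 1, times = width), rep(c0 + 1, each = height))]
  wr <- rep(fr, times = width); wc <- rep(fc, each = height)
  matrix((1 - wr) * (1 - wc) * a + wr * (1 - wc) * b +
           (1 - wr) * wc * d + wr * wc * e, nrow = height)
}

#' Generate a linear-mixture cover scene with known fractional cover
#'
#' A smooth random cover field `f` in `[0, 1]` is drawn (uniform values on a
#' coarse grid, bilinearly interpolated; `cover_field_smoothness` is the
#' coarse-cell size in pixels), and each pixel's reflectance is the linear
#' mixture `f * veg + (1 - f) * soil` plus Gaussian noise, clipped to
#' `[0, 1]`. With zero noise the mixture is exactly invertible per band.
#'
#' @param height,width scene size in pixels.
#' @param veg_spectrum,soil_spectrum length-4 endmember reflectances
#'   (blue, green, red, NIR) in `[0, 1]`.
#' @param cover_field_smoothness correlation length of the cover field, px.
#' @param noise_sd Gaussian reflectance noise sd.
#' @param seed integer seed (named substream `"cover"`).
#' @param cover optional fixed cover: a scalar in `[0, 1]` or a height x
#'   width matrix; when supplied, no random field is drawn.
#' @return list with elements `scene` (an unlabelled [raster_scene()], whole
#'   scene is one segment) and `true_cover` (height x width matrix in
#'   `[0, 1]`).
#' @export
generate_cover_scene <- function(height = 128, width = 128,
                                 veg_spectrum = default_endmembers()$forest,
                                 soil_spectrum = default_endmembers()$soil,
                                 cover_field_smoothness = 16,
                                 noise_sd = 0.01, seed = 1L, cover = NULL) {
  stopifnot(all(veg_spectrum >= 0), all(veg_spectrum <= 1),
            all(soil_spectrum >= 0), all(soil_spectrum <= 1),
            length(veg_spectrum) == 4L, length(soil_spectrum) == 4L,
            noise_sd >= 0, cover_field_smoothness >= 1)
  with_seed(substream_seed(seed, "cover"), {
    if (is.null(cover)) {
      nr <- max(2L, ceiling(height / cover_field_smoothness) + 1L)
      nc <- max(2L, ceiling(width / cover_field_smoothness) + 1L)
      coarse <- matrix(stats::runif(nr * nc), nr, nc)
      cover <- bilinear_field(coarse, height, width)
    } else {
      if (length(cover) == 1L) cover <- matrix(cover, height, width)
      stopifnot(identical(dim(cover), c(as.integer(height), as.integer(width))),
                min(cover) >= 0, max(cover) <= 1)
    }
    bands <- list()
    for (k in seq_along(BAND_NAMES)) {
      base <- cover * veg_spectrum[k] + (1 - cover) * soil_spectrum[k]
      noise <- if (noise_sd > 0)
        matrix(stats::rnorm(height * width, 0, noise_sd), height) else 0
      bands[[BAND_NAMES[k]]] <- clip01(base + noise)
    }
    seg <- matrix(1L, height, width)
    list(scene = raster_scene(bands, seg), true_cover = cover)
  })
}
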