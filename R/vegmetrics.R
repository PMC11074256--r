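# Formula layer: plant-diversity indices, vegetation indices (NDVI, EVI),
# dimidiate-pixel fractional vegetation cover, and cover-validation
# statistics (determination coefficient and RMSE).

check_abundance <- function(z) {
  if (!length(z)) stop("need at least one species")
  if (any(z < 0) || any(z > 1)) stop("importance values must lie in [0, 1]")
  if (abs(sum(z) - 1) > 1e-9) stop("importance values must sum to 1")
  invisible(z)
}

#' Shannon diversity index
#'
#' `S_W = -sum(Z ln Z)` over species importance values (natural log,
#' `0 ln 0 := 0`); ranges from 0 (single species) to `ln N` (uniform).
#'
#' @param z per-species importance values in `[0, 1]` summing to 1.
#' @return the diversity index.
#' @export
shannon_diversity <- function(z) {
  check_abundance(z)
  p <- z[z > 0]
  -sum(p * log(p))
}

#' Species richness index
#'
#' `F = (N - 1) / ln X` for `N` species among `X >= 2` total individuals.
#'
#' @param n_species species count `N` (>= 1).
#' @param n_individuals total individual count `X` (>= 2, and >= `N`).
#' @return the richness index.
#' @export
richness <- function(n_species, n_individuals) {
  stopifnot(is_count(n_species), n_species >= 1)
  if (n_individuals < 2) stop("need X >= 2 individuals (ln X must be > 0)")
  if (n_individuals < n_species) stop("X must be >= N")
  (n_species - 1) / log(n_individuals)
}

#' Simpson-type dominance index
#'
#' `Y = 1 - sum(Z^2)`; ranges from 0 (single species) to `1 - 1/N` (uniform).
#'
#' @inheritParams shannon_diversity
#' @return the dominance index.
#' @export
dominance <- function(z) {
  check_abundance(z)
  1 - sum(z^2)
}

#' EVI coefficient set
#'
#' Gain factor `O`, aerosol/soil adjustment coefficients `V1`, `V2`, and
#' background adjustment `D`. Defaults follow the MODIS convention
#' (`O = 2.5`, `V1 = 6`, `V2 = 7.5`, `D = 1`); all are configurable.
#'
#' @param O gain factor correcting spectral response.
#' @param V1,V2 atmospheric-scattering / soil-background coefficients.
#' @param D background-brightness adjustment.
#' @param eps smallest admissible denominator; pixels at or below it are
#'   flagged invalid.
#' @return an `evi_params` list.
#' @export
evi_params <- function(O = 2.5, V1 = 6, V2 = 7.5, D = 1, eps = 1e-6) {
  structure(list(O = O, V1 = V1, V2 = V2, D = D, eps = eps),
            class = "evi_params")
}

#' Enhanced vegetation index
#'
#' `E = O (R_nir - r) / (R_nir + V1 r - V2 b + D)` elementwise over grids or
#' scalars. Pixels whose denominator is `<= eps` are flagged invalid and
#' returned as `NA` rather than silently zeroed.
#'
#' @param nir,red,blue reflectance grids or scalars in `[0, 1]`.
#' @param params an [evi_params()] coefficient set.
#' @return EVI values, `NA` where the denominator is invalid.
#' @export
evi <- function(nir, red, blue, params = evi_params()) {
  den <- nir + params$V1 * red - params$V2 * blue + params$D
  out <- params$O * (nir - red) / den
  out[den <= params$eps] <- NA_real_
  out
}

#' Normalized difference vegetation index
#'
#' `(R_nir - r) / (R_nir + r)`, defined as 0 where both bands are 0.
#'
#' @param nir,red reflectance grids or scalars in `[0, 1]`.
#' @return NDVI values in `[-1, 1]`.
#' @export
ndvi <- function(nir, red) {
  den <- nir + red
  out <- nir - red
  zero <- den == 0
  out[!zero] <- out[!zero] / den[!zero]
  out[zero] <- 0
  out
}

#' Fractional vegetation cover by the dimidiate-pixel model
#'
#' Linear unmixing of a vegetation-index grid between a bare-soil and a
#' full-vegetation endmember: `(VI - VI_soil) / (VI_veg - VI_soil)`, clipped
#' to `[0, 1]`. When endmembers are not supplied they default to the 5th and
#' 95th percentiles of the grid.
#'
#' @param vi_grid vegetation-index grid (NDVI or EVI).
#' @param vi_soil,vi_veg endmember index values; `vi_veg > vi_soil` required.
#' @return cover grid in `[0, 1]`, same shape as `vi_grid`.
#' @export
estimate_cover <- function(vi_grid, vi_soil = NULL, vi_veg = NULL) {
  if (is.null(vi_soil)) vi_soil <- stats::quantile(vi_grid, 0.05, na.rm = TRUE)
  if (is.null(vi_veg)) vi_veg <- stats::quantile(vi_grid, 0.95, na.rm = TRUE)
  if (vi_veg <= vi_soil) stop("vi_veg must exceed vi_soil")
  clip01((vi_grid - vi_soil) / (vi_veg - vi_soil))
}

check_pairs <- function(observed, estimated, min_n = 1) {
  if (length(observed) != length(estimated)) stop("length mismatch")
  if (length(observed) < min_n) stop("need at least ", min_n, " pairs")
  invisible(NULL)
}

#' Determination coefficient of cover estimates
#'
#' `K^2 = sum((est - mean(obs))^2) / sum((obs - mean(obs))^2)`, the
#' regression-sum-of-squares over total-sum-of-squares reading; the
#' conventional `1 - SSE/SST` form is available with
#' `method = "one_minus_sse"`. Both are documented because the two coincide
#' only for a least-squares fit.
#'
#' @param observed,estimated paired cover values in `[0, 1]`, length >= 2.
#' @param method `"reg_ss"` (default) or `"one_minus_sse"`.
#' @return the determination coefficient.
#' @export
r_squared <- function(observed, estimated,
                      method = c("reg_ss", "one_minus_sse")) {
  method <- match.arg(method)
  check_pairs(observed, estimated, min_n = 2)
  sst <- sum((observed - mean(observed))^2)
  if (sst <= 0) stop("observed values are all equal: zero total SS")
  if (method == "reg_ss")
    sum((estimated - mean(observed))^2) / sst
  else
    1 - sum((observed - estimated)^2) / sst
}

#' Root mean square error of cover estimates
#'
#' `W = sqrt(sum((obs - est)^2) / q)`.
#'
#' @param observed,estimated paired cover values, length >= 1.
#' @return the RMSE.
#' @export
rmse <- function(observed, estimated) {
  check_pairs(observed, estimated, min_n = 1)
  sqrt(mean((observed - estimated)^2))
}

#' Sample-plot aggregation of a cover grid
#'
#' Ground truth for fractional cover comes from sample plots (quadrats), not
#' single pixels; validation therefore compares plot means. The scene is
#' tiled into `plot_size x plot_size` plots (edge plots may be smaller) and
#' the mean of each plot is returned, row-major.
#'
#' @param grid numeric matrix (cover or truth), `NA` allowed.
#' @param plot_size plot edge length in pixels.
#' @return numeric vector of plot means.
#' @export
plot_means <- function(grid, plot_size = 8) {
  stopifnot(plot_size >= 1)
  ri <- ceiling(row(grid) / plot_size)
  ci <- ceiling(col(grid) / plot_size)
  as.vector(tapply(as.vector(grid), list(as.vector(ri), as.vector(ci)),
                   mean, na.rm = TRUE))
}

#' End-to-end fractional-cover estimation for a scene
#'
#' Computes the chosen vegetation index from the scene's bands and unmixes it
#' with the dimidiate-pixel model. When endmember spectra are supplied the
#' endmember index values are computed from them; otherwise percentile
#' endmembers are used. When a truth grid is supplied a validation block
#' (`r_squared`, `rmse`) is attached, computed over sample-plot means
#' (`validation_plot_size` pixels per plot edge; set it to `NULL` for
#' per-pixel validation, which at typical band-noise levels is dominated by
#' pixel noise rather than estimation bias).
#'
#' @param scene a [raster_scene()].
#' @param index `"evi"` (default) or `"ndvi"`.
#' @param veg_spectrum,soil_spectrum optional length-4 endmember reflectances
#'   (blue, green, red, NIR).
#' @param true_cover optional truth grid for validation.
#' @param params an [evi_params()] coefficient set.
#' @param validation_plot_size sample-plot edge length in pixels (default 8),
#'   or `NULL` for per-pixel validation.
#' @return list with `vi` (index grid), `cover` (cover grid), `endmembers`
#'   (`c(soil, veg)` index values) and, when truth is supplied, `validation`
#'   (`r_squared`, `rmse`, `q` pair count).
#' @export
estimate_cover_scene <- function(scene, index = c("evi", "ndvi"),
                                 veg_spectrum = NULL, soil_spectrum = NULL,
                                 true_cover = NULL, params = evi_params(),
                                 validation_plot_size = 8) {
  index <- match.arg(index)
  b <- scene$bands
  vi_of <- function(nir, red, blue) {
    if (index == "evi") evi(nir, red, blue, params) else ndvi(nir, red)
  }
  vi <- vi_of(b$nir, b$red, b$blue)
  em <- c(soil = NA_real_, veg = NA_real_)
  if (!is.null(veg_spectrum) && !is.null(soil_spectrum)) {
    em["veg"] <- vi_of(veg_spectrum[4], veg_spectrum[3], veg_spectrum[1])
    em["soil"] <- vi_of(soil_spectrum[4], soil_spectrum[3], soil_spectrum[1])
    cover <- estimate_cover(vi, em["soil"], em["veg"])
  } else {
    em["soil"] <- stats::quantile(vi, 0.05, na.rm = TRUE)
    em["veg"] <- stats::quantile(vi, 0.95, na.rm = TRUE)
    cover <- estimate_cover(vi, em["soil"], em["veg"])
  }
  out <- list(vi = vi, cover = cover, endmembers = em)
  if (!is.null(true_cover)) {
    if (is.null(validation_plot_size)) {
      ok <- !is.na(cover)
      obs <- as.vector(true_cover[ok])
      est <- as.vector(cover[ok])
    } else {
      obs <- plot_means(true_cover, validation_plot_size)
      est <- plot_means(cover, validation_plot_size)
      keep <- !is.na(obs) & !is.na(est)
      obs <- obs[keep]
      est <- est[keep]
    }
    out$validation <- list(r_squared = r_squared(obs, est),
                           rmse = rmse(obs, est), q = length(obs))
  }
  out
}
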