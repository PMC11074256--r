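# File formats: multiband float TIFF scenes (band order blue, green, red,
# NIR) with a 16-bit segment-id TIFF and a segment_id,label CSV; feature
# tables as UTF-8 comma-separated CSV with a JSON column manifest.

SEGMENT_ID_SCALE <- 65535

#' Write a raster scene to disk
#'
#' Writes `<prefix>_bands.tif` (four 32-bit float directories, band order
#' blue, green, red, NIR), `<prefix>_segments.tif` (segment ids stored as
#' `id / 65535` at 16 bits) and, when the scene is labelled,
#' `<prefix>_labels.csv` (`segment_id,label`). A `<prefix>_meta.json`
#' sidecar records the band order, id scale and tool version.
#'
#' @param scene a [raster_scene()].
#' @param prefix path prefix for the output files.
#' @return invisibly, the paths written.
#' @export
write_scene <- function(scene, prefix) {
  paths <- c(bands = paste0(prefix, "_bands.tif"),
             segments = paste0(prefix, "_segments.tif"),
             meta = paste0(prefix, "_meta.json"))
  tiff::writeTIFF(unname(scene$bands[BAND_NAMES]), paths["bands"],
                  bits.per.sample = 32L, compression = "none")
  if (max(scene$segments) > SEGMENT_ID_SCALE)
    stop("segment ids above ", SEGMENT_ID_SCALE, " are not supported")
  tiff::writeTIFF(scene$segments / SEGMENT_ID_SCALE, paths["segments"],
                  bits.per.sample = 16L, compression = "none")
  meta <- list(format = "vegrf_scene", version = "1",
               band_order = BAND_NAMES, segment_id_scale = SEGMENT_ID_SCALE,
               labelled = !is.null(scene$labels))
  jsonlite::write_json(meta, paths["meta"], auto_unbox = TRUE)
  if (!is.null(scene$labels)) {
    paths["labels"] <- paste0(prefix, "_labels.csv")
    utils::write.csv(
      data.frame(segment_id = as.integer(names(scene$labels)),
                 label = unname(scene$labels)),
      paths["labels"], row.names = FALSE, quote = FALSE)
  }
  invisible(paths)
}

#' Read a raster scene written by [write_scene()]
#'
#' @param prefix the path prefix used when writing.
#' @return a [raster_scene()].
#' @export
read_scene <- function(prefix) {
  bands <- tiff::readTIFF(paste0(prefix, "_bands.tif"), all = TRUE)
  names(bands) <- BAND_NAMES
  seg_raw <- tiff::readTIFF(paste0(prefix, "_segments.tif"))
  segments <- matrix(as.integer(round(seg_raw * SEGMENT_ID_SCALE)),
                     nrow = nrow(seg_raw))
  labels <- NULL
  lab_path <- paste0(prefix, "_labels.csv")
  if (file.exists(lab_path)) {
    df <- utils::read.csv(lab_path, colClasses = c("integer", "character"))
    labels <- stats::setNames(df$label, as.character(df$segment_id))
  }
  raster_scene(lapply(bands, clip01), segments, labels)
}

#' Write a feature table as CSV (plus its manifest as JSON)
#'
#' CSV dialect: UTF-8, comma-separated, header row, one object per row,
#' `.` decimal mark, label column named `label`. When the table carries a
#' manifest attribute it is written next to the CSV as
#' `<path without .csv>_manifest.json` listing the feature names in column
#' order.
#'
#' @param ft a [feature_table()].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_feature_csv <- function(ft, path) {
  utils::write.csv(as.data.frame(ft), path, row.names = FALSE, quote = FALSE)
  manifest <- attr(ft, "manifest")
  if (!is.null(manifest)) {
    mpath <- paste0(sub("\\.csv$", "", path), "_manifest.json")
    jsonlite::write_json(unclass(manifest), mpath, auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read a feature table written by [write_feature_csv()]
#'
#' @param path CSV path.
#' @return a [feature_table()] (with manifest attribute when the JSON
#'   sidecar is present).
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  lab <- if ("label" %in% names(df)) as.character(df$label)
  ids <- if ("object_id" %in% names(df)) df$object_id else seq_len(nrow(df))
  vals <- df[, setdiff(names(df), c("object_id", "label")), drop = FALSE]
  ft <- feature_table(vals, object_ids = ids, label = lab)
  mpath <- paste0(sub("\\.csv$", "", path), "_manifest.json")
  if (file.exists(mpath)) {
    m <- jsonlite::fromJSON(mpath, simplifyVector = TRUE,
                            simplifyMatrix = FALSE)
    m$offsets <- lapply(m$offsets, as.integer)
    attr(ft, "manifest") <- structure(m, class = "feature_manifest")
  }
  ft
}
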