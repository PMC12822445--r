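#' Construct a tile bag
#'
#' A `tile_bag` holds one slide's instances for multiple instance learning:
#' an `n x c` matrix of per-tile feature vectors, the `n x 2` integer
#' tile-grid coordinates (column, row) at the tiling magnification, slide and
#' patient identifiers, and optionally the slide-level risk label on the
#' normalized \[0, 1\] scale.
#'
#' @param features numeric matrix, `n` tiles by `c` channels.
#' @param coords integer matrix, `n x 2`, non-negative tile-grid
#'   (column, row) positions; duplicate rows are rejected.
#' @param slide_id,patient_id character scalars.
#' @param tile_size_px tile edge length in pixels (default 256).
#' @param magnification free-text magnification tag (default `"20x"`).
#' @param label_normalized optional risk label in \[0, 1\] (`NULL` if absent).
#' @return An object of class `tile_bag`.
#' @export
tile_bag <- function(features, coords, slide_id, patient_id,
                     tile_size_px = 256L, magnification = "20x",
                     label_normalized = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  dimnames(features) <- NULL
  coords <- as.matrix(coords)
  storage.mode(coords) <- "integer"
  dimnames(coords) <- NULL
  if (nrow(features) < 1L)
    stop_invalid("a tile bag needs at least one tile")
  if (nrow(features) != nrow(coords))
    stop_invalid("features and coords disagree on the number of tiles (",
                 nrow(features), " vs ", nrow(coords), ")")
  if (ncol(coords) != 2L)
    stop_invalid("coords must have two columns (column, row)")
  if (any(coords < 0L))
    stop_invalid("tile coordinates must be non-negative")
  if (anyDuplicated(coords))
    stop_invalid("duplicate tile coordinates within a bag")
  if (!is.null(label_normalized)) {
    label_normalized <- as.numeric(label_normalized)
    if (length(label_normalized) != 1L || is.na(label_normalized) ||
        label_normalized < 0 || label_normalized > 1)
      stop_invalid("label_normalized must be a single value in [0, 1]")
  }
  if (tile_size_px < 1L) stop_invalid("tile_size_px must be positive")
  structure(
    list(features = features, coords = coords,
         slide_id = as.character(slide_id),
         patient_id = as.character(patient_id),
         tile_size_px = as.integer(tile_size_px),
         magnification = as.character(magnification),
         label_normalized = label_normalized),
    class = "tile_bag")
}

#' @export
print.tile_bag <- function(x, ...) {
  cat(sprintf("<tile_bag> slide %s (patient %s): %d tiles x %d channels%s\n",
              x$slide_id, x$patient_id, nrow(x$features), ncol(x$features),
              if (is.null(x$label_normalized)) ", unlabeled"
              else sprintf(", label %.3f", x$label_normalized)))
  invisible(x)
}

#' Cell type vocabulary
#'
#' The five nucleus classes used throughout the cell-graph module.
#' @export
CELL_TYPES <- c("neoplastic", "inflammatory", "necrotic", "connective",
                "non-neoplastic-epithelial")

#' Construct a cell map
#'
#' Typed cell centroids for one region of interest: positions in pixels,
#' one of five cell categories per cell (neoplastic/tumor, inflammatory,
#' necrotic, connective/stroma, non-neoplastic epithelial), and the region
#' geometry needed to convert to physical units.
#'
#' @param centroids numeric matrix `m x 2` of (x, y) pixel positions.
#' @param cell_types character vector of length `m`, values in [CELL_TYPES].
#' @param region_width_px,region_height_px region extent in pixels.
#' @param microns_per_px physical pixel size (default 0.5, i.e. 20x).
#' @return An object of class `cell_map`.
#' @export
cell_map <- function(centroids, cell_types,
                     region_width_px, region_height_px,
                     microns_per_px = 0.5) {
  centroids <- as.matrix(centroids)
  storage.mode(centroids) <- "double"
  if (ncol(centroids) != 2L) stop_invalid("centroids must be m x 2")
  if (length(cell_types) != nrow(centroids))
    stop_invalid("one cell type per centroid required")
  cell_types <- as.character(cell_types)
  bad <- setdiff(unique(cell_types), CELL_TYPES)
  if (length(bad))
    stop_invalid("unknown cell type(s): ", paste(bad, collapse = ", "))
  if (region_width_px <= 0 || region_height_px <= 0)
    stop_invalid("region dimensions must be positive")
  if (microns_per_px <= 0) stop_invalid("microns_per_px must be positive")
  if (nrow(centroids) &&
      (any(centroids[, 1] < 0) || any(centroids[, 1] >= region_width_px) ||
       any(centroids[, 2] < 0) || any(centroids[, 2] >= region_height_px)))
    stop_invalid("centroids must lie inside the region")
  structure(
    list(centroids = centroids, cell_types = cell_types,
         region_width_px = as.integer(region_width_px),
         region_height_px = as.integer(region_height_px),
         microns_per_px = as.numeric(microns_per_px)),
    class = "cell_map")
}

#' @export
print.cell_map <- function(x, ...) {
  tab <- table(factor(x$cell_types, levels = CELL_TYPES))
  cat(sprintf("<cell_map> %d cells in %d x %d px (%.2f um/px)\n",
              nrow(x$centroids), x$region_width_px, x$region_height_px,
              x$microns_per_px))
  print(tab)
  invisible(x)
}

#' Area of a cell map region in square millimeters
#' @param cm a [cell_map()].
#' @return area in mm^2.
#' @export
cellmap_area_mm2 <- function(cm) {
  (cm$region_width_px * cm$microns_per_px / 1000) *
    (cm$region_height_px * cm$microns_per_px / 1000)
}
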