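#' Normalized per-tile attention scores
#'
#' The class-token row of the head-averaged rollout matrix restricted to
#' tile columns, min-max normalized to \[0, 1\]. If all raw scores are equal
#' (e.g. a single-tile bag) every score is 0.5: "no salient region" still
#' renders as a flat mid-scale map.
#'
#' @param bag a [tile_bag()].
#' @param params,config trained model state.
#' @return numeric vector of length `n` in \[0, 1\].
#' @export
tile_attention_scores <- function(bag, params, config) {
  raw <- forward_bag(bag, params, config)$tile_scores_raw
  rng <- range(raw)
  if (diff(rng) < .Machine$double.eps * max(1, abs(rng[2])))
    return(rep(0.5, length(raw)))
  (raw - rng[1]) / diff(rng)
}

#' Assemble an attention raster from tile scores
#'
#' Each tile paints its score over its `tile_size_px` square footprint at
#' stride `tile_size_px * (1 - overlap)`; pixels covered by several tiles
#' receive the arithmetic mean of the contributing scores, and uncovered
#' pixels carry `NA`. Painting is linear in the scores, so pre-normalized
#' rasters can be rescaled downstream.
#'
#' @param scores numeric vector of per-tile scores.
#' @param coords `n x 2` non-negative tile-grid (column, row) positions.
#' @param tile_size_px tile edge length in pixels (default 256).
#' @param overlap tile overlap fraction in \[0, 1) (default 0.1, the
#'   visualization tiling; training bags use 0).
#' @return list of class `attention_raster`: `canvas` (matrix, `NA` =
#'   uncovered), `tile_size_px`, `stride_px`, `overlap`.
#' @export
assemble_raster <- function(scores, coords, tile_size_px = 256L,
                            overlap = 0.1) {
  coords <- as.matrix(coords)
  if (length(scores) != nrow(coords))
    stop_invalid("scores and coords must align")
  if (any(coords < 0)) stop_invalid("tile coordinates must be non-negative")
  if (overlap < 0 || overlap >= 1) stop_invalid("overlap must lie in [0, 1)")
  stride <- tile_size_px * (1 - overlap)
  x0 <- round(coords[, 1L] * stride)
  y0 <- round(coords[, 2L] * stride)
  W <- max(x0) + tile_size_px
  H <- max(y0) + tile_size_px
  ssum <- matrix(0, H, W)
  cnt <- matrix(0L, H, W)
  for (i in seq_along(scores)) {
    rows <- (y0[i] + 1L):(y0[i] + tile_size_px)
    cols <- (x0[i] + 1L):(x0[i] + tile_size_px)
    ssum[rows, cols] <- ssum[rows, cols] + scores[i]
    cnt[rows, cols] <- cnt[rows, cols] + 1L
  }
  canvas <- ssum / cnt                     # 0/0 -> NaN for uncovered
  canvas[cnt == 0L] <- NA_real_
  structure(list(canvas = canvas, tile_size_px = as.integer(tile_size_px),
                 stride_px = stride, overlap = overlap),
            class = "attention_raster")
}

#' Top-k tiles by attention score
#'
#' Descending by score; ties broken by row-major coordinate order (row,
#' then column). `k > n` returns all `n` tiles.
#'
#' @param scores numeric per-tile scores.
#' @param coords `n x 2` tile coordinates.
#' @param k number of tiles to return (>= 1).
#' @return data frame with `col`, `row`, `score`, `index` (original tile
#'   index), ordered.
#' @export
top_k_tiles <- function(scores, coords, k = 10L) {
  if (k < 1L) stop_invalid("k must be at least 1")
  coords <- as.matrix(coords)
  o <- order(-scores, coords[, 2L], coords[, 1L])
  o <- o[seq_len(min(k, length(scores)))]
  data.frame(col = coords[o, 1L], row = coords[o, 2L],
             score = scores[o], index = o)
}

#' Concordance between an attention raster and a binary region mask
#'
#' Over covered pixels: pixelwise ROC AUC of the raster values against the
#' mask; after binarizing the raster at `threshold`, recall
#' `TP / (TP + FN)`, Dice `2TP / (2TP + FP + FN)`, and the overlap ratio
#' `TP / (TP + FP)` (the fraction of the high-attention area lying inside
#' the mask).
#'
#' @param raster an [assemble_raster()] result (or a plain matrix).
#' @param mask binary matrix of the same dimensions (nonzero = region).
#' @param threshold binarization threshold (default 0.5).
#' @return list with `auc`, `recall`, `dice`, `overlap_ratio`.
#' @export
concordance <- function(raster, mask, threshold = 0.5) {
  canvas <- if (inherits(raster, "attention_raster")) raster$canvas
            else as.matrix(raster)
  mask <- as.matrix(mask) != 0
  if (!all(dim(canvas) == dim(mask)))
    stop_invalid("raster and mask must have the same shape")
  keep <- !is.na(canvas)
  v <- canvas[keep]; m <- mask[keep]
  auc <- if (length(unique(m)) < 2L) NA_real_ else auroc(v, m)
  hot <- v >= threshold
  tp <- sum(hot & m); fp <- sum(hot & !m); fn <- sum(!hot & m)
  list(auc = auc,
       recall = if (tp + fn) tp / (tp + fn) else NA_real_,
       dice = if (2 * tp + fp + fn) 2 * tp / (2 * tp + fp + fn) else NA_real_,
       overlap_ratio = if (tp + fp) tp / (tp + fp) else NA_real_)
}

#' Write an attention raster to PNG (plus lossless values)
#'
#' 8-bit colormapped PNG for viewing; uncovered pixels render black. When
#' `values_path` is given the raw canvas is also written as an HDF5 dataset
#' `/raster` for lossless downstream use.
#'
#' @param raster an [assemble_raster()] result.
#' @param path output PNG path.
#' @param values_path optional `.h5` path for the raw values.
#' @param palette a `grDevices::hcl.colors` palette name (default
#'   `"Viridis"`).
#' @export
write_raster_png <- function(raster, path, values_path = NULL,
                             palette = "Viridis") {
  canvas <- raster$canvas
  cols <- grDevices::hcl.colors(256L, palette)
  idx <- pmin(pmax(round(canvas * 255) + 1L, 1L), 256L)
  rgb <- grDevices::col2rgb(cols[idx]) / 255
  img <- array(0, c(nrow(canvas), ncol(canvas), 3L))
  na <- is.na(canvas)
  for (ch in 1:3) {
    plane <- matrix(rgb[ch, ], nrow(canvas), ncol(canvas))
    plane[na] <- 0
    img[, , ch] <- plane
  }
  png::writePNG(img, path)
  if (!is.null(values_path)) {
    if (file.exists(values_path)) unlink(values_path)
    rhdf5::h5createFile(values_path)
    suppressMessages(rhdf5::h5write(canvas, values_path, "raster"))
  }
  invisible(path)
}

#' Read a binary region mask from PNG
#'
#' Single-channel (or first-channel) PNG; nonzero pixels mark the region.
#'
#' @param path PNG path.
#' @return logical matrix.
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img > 0
}
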