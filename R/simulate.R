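#' Simulate a synthetic slide cohort with a planted risk signal
#'
#' Generates one bag per patient. Tiles live on a near-square grid; a
#' fraction `signal_fraction` of them ("tumor" tiles) form spatially
#' contiguous disc-shaped blobs seeded at random grid centers. Background
#' tiles are i.i.d. standard normal noise; signal tiles additionally carry
#' `signal_strength * (label - 0.5)` along a fixed unit direction in
#' feature space, where the bag label is drawn uniformly on \[0, 1\].
#' Features are snapped to single precision so that the HDF5 round trip is
#' an exact identity. The generator is a pure function of its arguments:
#' identical seeds give bit-identical cohorts.
#'
#' @param n_patients number of patients (one slide each).
#' @param tiles_per_slide tiles per bag.
#' @param n_channels feature channels per tile.
#' @param signal_strength non-negative signal amplitude (0 = pure noise).
#' @param signal_fraction fraction of tiles carrying signal, in (0, 1\].
#' @param seed RNG seed.
#' @param n_blobs number of signal blobs per slide (default 2, reduced to 1
#'   when fewer than 8 signal tiles are requested).
#' @return list of length `n_patients`; each element has `$bag` (a
#'   [tile_bag()]) and `$truth` (signal mask, direction, strength, blob
#'   centers, seed).
#' @export
simulate_cohort <- function(n_patients, tiles_per_slide, n_channels,
                            signal_strength = 4, signal_fraction = 0.2,
                            seed = 1L, n_blobs = 2L) {
  if (n_patients < 1L || tiles_per_slide < 1L || n_channels < 1L)
    stop_invalid("all counts must be positive")
  if (signal_fraction <= 0 || signal_fraction > 1)
    stop_invalid("signal_fraction must lie in (0, 1]")
  if (signal_strength < 0) stop_invalid("signal_strength must be non-negative")
  set.seed(seed)

  # one signal direction for the whole cohort
  u <- stats::rnorm(n_channels)
  u <- u / sqrt(sum(u^2))

  side <- ceiling(sqrt(tiles_per_slide))
  grid <- cbind(col = rep(seq_len(side) - 1L, side),
                row = rep(seq_len(side) - 1L, each = side))
  grid <- grid[seq_len(tiles_per_slide), , drop = FALSE]

  n_signal <- max(1L, round(signal_fraction * tiles_per_slide))
  if (n_signal < 8L) n_blobs <- 1L
  n_blobs <- min(n_blobs, n_signal)

  out <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    label <- stats::runif(1)
    feat <- matrix(stats::rnorm(tiles_per_slide * n_channels),
                   tiles_per_slide, n_channels)
    mask <- logical(tiles_per_slide)
    centers_idx <- sample(tiles_per_slide, n_blobs)
    per_blob <- rep(n_signal %/% n_blobs, n_blobs)
    per_blob[seq_len(n_signal %% n_blobs)] <-
      per_blob[seq_len(n_signal %% n_blobs)] + 1L
    for (b in seq_len(n_blobs)) {
      ctr <- grid[centers_idx[b], ]
      d2 <- (grid[, 1L] - ctr[1L])^2 + (grid[, 2L] - ctr[2L])^2
      d2[mask] <- Inf                      # grow into unassigned tiles only
      take <- order(d2, seq_along(d2))[seq_len(min(per_blob[b], sum(!mask)))]
      mask[take] <- TRUE
    }
    if (signal_strength > 0)
      feat[mask, ] <- feat[mask, ] +
        rep(signal_strength * (label - 0.5) * u, each = sum(mask))
    feat <- as_float32(feat)
    bag <- tile_bag(feat, grid,
                    slide_id = sprintf("S%04d", i),
                    patient_id = sprintf("P%04d", i),
                    label_normalized = label)
    out[[i]] <- list(
      bag = bag,
      truth = list(signal_tile_mask = mask, signal_direction = u,
                   signal_strength = signal_strength,
                   blob_centers = grid[centers_idx, , drop = FALSE],
                   seed = seed))
  }
  out
}

#' Simulate a typed cell map with group-dependent tumor spacing
#'
#' Tumor cells follow a Thomas-like clustered point process: uniformly
#' placed parents with Gaussian offspring dispersion `spacing_scale` pixels
#' for the low-risk group and `2 * spacing_scale` for the high-risk group
#' (high-risk tumors are more spatially dispersed). Offspring positions
#' wrap around the region edges (torus) so the planted spacing statistics
#' are not distorted at the boundary. Stromal (connective) and inflammatory
#' cells are uniform.
#'
#' @param group `"low"` or `"high"` risk group.
#' @param n_tumor number of neoplastic cells (>= 1).
#' @param n_stroma,n_inflammatory uniform background cell counts.
#' @param spacing_scale parent-offspring dispersion in pixels for the low
#'   group (default 10).
#' @param seed RNG seed.
#' @param region_px region edge length in pixels (square, default 1024).
#' @param microns_per_px physical pixel size (default 0.5).
#' @param cells_per_parent mean offspring per parent (default 20).
#' @return a [cell_map()].
#' @export
simulate_cellmap <- function(group = c("low", "high"), n_tumor,
                             n_stroma = 0L, n_inflammatory = 0L,
                             spacing_scale = 10, seed = 1L,
                             region_px = 1024L, microns_per_px = 0.5,
                             cells_per_parent = 20) {
  group <- match.arg(group)
  if (n_tumor < 1L) stop_invalid("at least one tumor cell is required")
  if (spacing_scale <= 0) stop_invalid("spacing_scale must be positive")
  set.seed(seed)
  sigma <- if (group == "high") 2 * spacing_scale else spacing_scale

  n_parents <- max(1L, round(n_tumor / cells_per_parent))
  parents <- matrix(stats::runif(2L * n_parents, 0, region_px), ncol = 2L)
  assign <- sample(n_parents, n_tumor, replace = TRUE)
  tumor <- parents[assign, , drop = FALSE] +
    matrix(stats::rnorm(2L * n_tumor, sd = sigma), ncol = 2L)
  tumor <- tumor %% region_px              # torus wrap

  unif_pts <- function(m) {
    if (m < 1L) return(matrix(numeric(0), 0L, 2L))
    matrix(stats::runif(2L * m, 0, region_px), ncol = 2L)
  }
  stroma <- unif_pts(n_stroma)
  inflam <- unif_pts(n_inflammatory)

  cell_map(rbind(tumor, stroma, inflam),
           c(rep("neoplastic", n_tumor),
             rep("connective", nrow(stroma)),
             rep("inflammatory", nrow(inflam))),
           region_width_px = region_px, region_height_px = region_px,
           microns_per_px = microns_per_px)
}

#' Write a cohort manifest CSV
#'
#' Columns: `patient_id,slide_id,mp_score_raw,mp_score_normalized,risk_group`.
#'
#' @param cohort list from [simulate_cohort()] (or list of bags).
#' @param path output CSV path.
#' @export
write_manifest <- function(cohort, path) {
  bags <- lapply(cohort, function(x) if (inherits(x, "tile_bag")) x else x$bag)
  norm <- vapply(bags, function(b) b$label_normalized %||% NA_real_, numeric(1))
  df <- data.frame(
    patient_id = vapply(bags, `[[`, character(1), "patient_id"),
    slide_id = vapply(bags, `[[`, character(1), "slide_id"),
    mp_score_raw = 2 * norm - 1,
    mp_score_normalized = norm,
    risk_group = assign_risk_group(norm, "normalized"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Read a cohort manifest CSV
#' @param path CSV path with the [write_manifest()] header.
#' @return data frame.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "slide_id", "mp_score_raw",
            "mp_score_normalized", "risk_group")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_invalid("manifest lacks column(s): ", paste(miss, collapse = ", "))
  df
}

#' Write / read a cell map CSV
#'
#' Columns: `x_px,y_px,cell_type`. Region geometry is not stored in the
#' CSV; supply it when reading.
#'
#' @param cm a [cell_map()].
#' @param path CSV path.
#' @export
write_cellmap <- function(cm, path) {
  df <- data.frame(x_px = cm$centroids[, 1L], y_px = cm$centroids[, 2L],
                   cell_type = cm$cell_types)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' @rdname write_cellmap
#' @param region_width_px,region_height_px,microns_per_px region geometry
#'   (defaults: tight bounding box, 0.5 um/px).
#' @export
read_cellmap <- function(path, region_width_px = NULL,
                         region_height_px = NULL, microns_per_px = 0.5) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("x_px", "y_px", "cell_type"), names(df))
  if (length(miss))
    stop_invalid("cell map CSV lacks column(s): ", paste(miss, collapse = ", "))
  w <- region_width_px %||% (floor(max(df$x_px)) + 1)
  h <- region_height_px %||% (floor(max(df$y_px)) + 1)
  cell_map(cbind(df$x_px, df$y_px), df$cell_type, w, h, microns_per_px)
}
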