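#' Write a tile bag to HDF5
#'
#' On-disk layout: datasets `/features` (float32, `n x c`) and `/coords`
#' (int32, `n x 2`, column-major order column,row); file attributes
#' `slide_id`, `patient_id`, `tile_size_px`, `magnification` and, when the
#' bag is labeled, `label_normalized`. [read_bag()] inverts the layout
#' exactly, so write-then-read is the identity on all fields (features are
#' single precision end to end).
#'
#' @param bag a [tile_bag()].
#' @param path output `.h5` path (overwritten if present).
#' @export
write_bag <- function(bag, path) {
  if (!inherits(bag, "tile_bag")) stop_invalid("bag must be a tile_bag")
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  n <- nrow(bag$features); ch <- ncol(bag$features)
  # HDF5 stores row-major; write transposed so the file shape is n x c.
  rhdf5::h5createDataset(path, "features", dims = c(ch, n),
                         H5type = "H5T_IEEE_F32LE", chunk = NULL, level = 0)
  rhdf5::h5write(t(bag$features), path, "features")
  rhdf5::h5createDataset(path, "coords", dims = c(2L, n),
                         H5type = "H5T_STD_I32LE", chunk = NULL, level = 0)
  rhdf5::h5write(t(bag$coords), path, "coords")
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  rhdf5::h5writeAttribute(bag$slide_id, fid, "slide_id")
  rhdf5::h5writeAttribute(bag$patient_id, fid, "patient_id")
  rhdf5::h5writeAttribute(as.integer(bag$tile_size_px), fid, "tile_size_px")
  rhdf5::h5writeAttribute(bag$magnification, fid, "magnification")
  if (!is.null(bag$label_normalized))
    rhdf5::h5writeAttribute(as.numeric(bag$label_normalized), fid,
                            "label_normalized")
  invisible(path)
}

#' Read a tile bag from HDF5
#'
#' @param path an `.h5` file in the [write_bag()] layout. Missing datasets
#'   or shape mismatches raise a format error naming the offending dataset;
#'   a missing `label_normalized` attribute round-trips as an unlabeled bag.
#' @return a [tile_bag()].
#' @export
read_bag <- function(path) {
  if (!file.exists(path)) stop_invalid("no such file: ", path)
  ls <- rhdf5::h5ls(path)
  have <- ls$name[ls$group == "/"]
  for (ds in c("features", "coords"))
    if (!ds %in% have)
      stop_invalid("malformed bag file: missing dataset '", ds, "' in ", path)
  feats <- t(rhdf5::h5read(path, "features"))
  coords <- t(rhdf5::h5read(path, "coords"))
  if (ncol(coords) != 2L)
    stop_invalid("malformed bag file: dataset 'coords' must be n x 2")
  if (nrow(coords) != nrow(feats))
    stop_invalid("malformed bag file: datasets 'features' and 'coords' ",
                 "disagree on the number of tiles")
  attrs <- rhdf5::h5readAttributes(path, "/")
  attr1 <- function(name, default = NULL) {
    v <- attrs[[name]]
    if (is.null(v)) default else if (is.array(v)) as.vector(v) else v
  }
  tile_bag(feats, coords,
           slide_id = attr1("slide_id", "unknown"),
           patient_id = attr1("patient_id", "unknown"),
           tile_size_px = attr1("tile_size_px", 256L),
           magnification = attr1("magnification", "20x"),
           label_normalized = attr1("label_normalized"))
}

#' Write a cohort of bags plus manifest to a directory
#'
#' @param cohort list from [simulate_cohort()].
#' @param dir output directory (created if needed); bags are written as
#'   `<slide_id>.h5` plus a `manifest.csv`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (x in cohort) {
    bag <- if (inherits(x, "tile_bag")) x else x$bag
    write_bag(bag, file.path(dir, paste0(bag$slide_id, ".h5")))
  }
  write_manifest(cohort, file.path(dir, "manifest.csv"))
  invisible(dir)
}
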