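#' Build a typed intercellular graph
#'
#' Delaunay triangulation over the centroids of the cell types involved in
#' `pair_class` (a single type for tumor-tumor), keeping only edges whose
#' endpoints match the pair class and whose physical length does not exceed
#' `max_edge_um`. Degenerate (collinear or < 3 cells) inputs fall back to a
#' nearest-neighbour chain; fewer than 3 usable cells yields an edgeless
#' graph with a warning flag rather than an error.
#'
#' @param cellmap a [cell_map()].
#' @param pair_class `"tumor-tumor"`, `"tumor-stroma"`, or
#'   `"tumor-inflammatory"`.
#' @param max_edge_um edge length cap in microns (default 50).
#' @return list of class `cell_graph`: `nodes` (data frame `cell_id`, `x`,
#'   `y`, `type`), `edges` (data frame `from`, `to`, `length_px`,
#'   `length_um`), `pair_class`, `microns_per_px`, `degenerate` flag.
#' @export
build_typed_graph <- function(cellmap,
                              pair_class = c("tumor-tumor", "tumor-stroma",
                                             "tumor-inflammatory"),
                              max_edge_um = 50) {
  pair_class <- match.arg(pair_class)
  if (max_edge_um <= 0) stop_invalid("max_edge_um must be positive")
  type_map <- c("tumor-tumor" = "neoplastic",
                "tumor-stroma" = "connective",
                "tumor-inflammatory" = "inflammatory")
  other <- type_map[[pair_class]]
  types_used <- unique(c("neoplastic", other))
  keep <- cellmap$cell_types %in% types_used
  xy <- cellmap$centroids[keep, , drop = FALSE]
  ty <- cellmap$cell_types[keep]
  ids <- which(keep)
  nodes <- data.frame(cell_id = ids, x = xy[, 1L], y = xy[, 2L], type = ty)
  empty <- data.frame(from = integer(0), to = integer(0),
                      length_px = numeric(0), length_um = numeric(0))
  mk <- function(edges, degenerate = FALSE)
    structure(list(nodes = nodes, edges = edges, pair_class = pair_class,
                   microns_per_px = cellmap$microns_per_px,
                   degenerate = degenerate), class = "cell_graph")

  if (nrow(xy) < 3L) {
    warning("fewer than 3 usable cells; returning an edgeless graph")
    return(mk(empty, degenerate = TRUE))
  }

  seg <- tryCatch({
    dd <- deldir::deldir(xy[, 1L], xy[, 2L], suppressMsge = TRUE)
    dd$delsgs[, c("ind1", "ind2")]
  }, error = function(e) NULL)
  degenerate <- is.null(seg)
  if (degenerate) {
    # collinear fallback: chain consecutive points along the dominant axis
    ax <- if (diff(range(xy[, 1L])) >= diff(range(xy[, 2L]))) 1L else 2L
    o <- order(xy[, ax], xy[, 3L - ax])
    seg <- data.frame(ind1 = o[-length(o)], ind2 = o[-1L])
  }

  i1 <- pmin(seg$ind1, seg$ind2)
  i2 <- pmax(seg$ind1, seg$ind2)
  dup <- duplicated(cbind(i1, i2)) | i1 == i2
  i1 <- i1[!dup]; i2 <- i2[!dup]
  # type constraint: tumor-tumor keeps same-type pairs, cross classes keep
  # exactly one tumor and one partner endpoint
  if (pair_class == "tumor-tumor") {
    ok <- ty[i1] == "neoplastic" & ty[i2] == "neoplastic"
  } else {
    ok <- (ty[i1] == "neoplastic" & ty[i2] == other) |
          (ty[i1] == other & ty[i2] == "neoplastic")
  }
  i1 <- i1[ok]; i2 <- i2[ok]
  len_px <- sqrt((xy[i1, 1L] - xy[i2, 1L])^2 + (xy[i1, 2L] - xy[i2, 2L])^2)
  len_um <- len_px * cellmap$microns_per_px
  keep_len <- len_um <= max_edge_um & len_px > 0
  # edges reference the original cell ids of the cell map
  i1 <- ids[i1]; i2 <- ids[i2]
  mk(data.frame(from = i1[keep_len], to = i2[keep_len],
                length_px = len_px[keep_len], length_um = len_um[keep_len]),
     degenerate = degenerate)
}

#' @export
print.cell_graph <- function(x, ...) {
  cat(sprintf("<cell_graph> %s: %d nodes, %d edges%s\n", x$pair_class,
              nrow(x$nodes), nrow(x$edges),
              if (x$degenerate) " (degenerate fallback)" else ""))
  invisible(x)
}

#' Per-cell MeanEdgeLength
#'
#' For each cell of the focus type with at least one incident edge, the
#' arithmetic mean of its incident edge lengths in microns. Degree-0 focus
#' cells are excluded (their count is reported in the `n_excluded`
#' attribute) rather than assigned zero.
#'
#' @param graph a [build_typed_graph()] result.
#' @param cell_type_focus focus type (default `"neoplastic"`).
#' @return named numeric vector (names = `cell_id`) with attribute
#'   `n_excluded`.
#' @export
mean_edge_length <- function(graph, cell_type_focus = "neoplastic") {
  nodes <- graph$nodes; edges <- graph$edges
  focus <- which(nodes$type == cell_type_focus)
  deg_sum <- numeric(nrow(nodes)); deg_n <- integer(nrow(nodes))
  if (nrow(edges)) {
    for (col in c("from", "to")) {
      idx <- match(edges[[col]], nodes$cell_id)
      agg <- tapply(edges$length_um, idx, sum)
      cnt <- tapply(rep(1L, nrow(edges)), idx, sum)
      ii <- as.integer(names(agg))
      deg_sum[ii] <- deg_sum[ii] + agg
      deg_n[ii] <- deg_n[ii] + cnt
    }
  }
  has <- focus[deg_n[focus] > 0L]
  excluded <- length(focus) - length(has)
  out <- deg_sum[has] / deg_n[has]
  names(out) <- nodes$cell_id[has]
  attr(out, "n_excluded") <- excluded
  out
}

#' Tumor cell density (TcD)
#'
#' Number of neoplastic cells per square millimeter.
#'
#' @param cellmap a [cell_map()].
#' @param area_mm2 analyzed area in mm^2 (default: the cell map region).
#' @return cells per mm^2.
#' @export
tumor_cell_density <- function(cellmap, area_mm2 = cellmap_area_mm2(cellmap)) {
  if (area_mm2 <= 0) stop_invalid("area_mm2 must be positive")
  sum(cellmap$cell_types == "neoplastic") / area_mm2
}

#' Mann-Whitney U comparison of two samples
#'
#' Exact two-sided p by full enumeration of rank assignments when
#' `min(n_a, n_b) <= 8` and `n_a + n_b <= 12` (midranks under ties;
#' two-sided p = 2 * min tail, capped at 1); otherwise the normal
#' approximation with tie and continuity correction.
#'
#' @param values_a,values_b numeric samples.
#' @return list with `U` (statistic of sample a), `p`, `method`.
#' @export
compare_groups <- function(values_a, values_b) {
  na <- length(values_a); nb <- length(values_b)
  if (na == 0L || nb == 0L) stop_invalid("both samples must be nonempty")
  pooled <- c(values_a, values_b)
  r <- rank(pooled)
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (min(na, nb) <= 8L && na + nb <= 12L) {
    sets <- utils::combn(na + nb, na)
    Us <- colSums(matrix(r[sets], nrow = na)) - na * (na + 1) / 2
    lo <- mean(Us <= U); hi <- mean(Us >= U)
    p <- min(1, 2 * min(lo, hi))
    method <- "exact enumeration"
  } else {
    mu <- na * nb / 2
    nt <- na + nb
    ties <- table(pooled)
    sig2 <- na * nb / 12 * (nt + 1 - sum(ties^3 - ties) / (nt * (nt - 1)))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(U = U, p = p, method = method)
}
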