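#' Collect top-attention tiles across slides into an embedding table
#'
#' Per slide, the `k` tiles with the highest attention scores are selected
#' (all tiles when the slide has fewer than `k`); each selected tile is
#' embedded with [embed_tile()] and scored with [forward_bag()] on its
#' singleton bag, giving a tile-level risk score. Slide-level risk group and
#' score come from the bag label.
#'
#' @param bags list of labeled [tile_bag()]s.
#' @param params,config trained model state.
#' @param k tiles per slide (default 100).
#' @return list of class `tile_embedding_table`: `embeddings`
#'   (`T x embed_dim`) and `meta` (data frame with `slide_id`, `col`,
#'   `row`, `risk_group`, `slide_score`, `tile_score`, `attention`).
#' @export
collect_top_tiles <- function(bags, params, config, k = 100L) {
  emb <- list(); meta <- list()
  for (bag in bags) {
    if (is.null(bag$label_normalized))
      stop_invalid("bag ", bag$slide_id, " has no label")
    sc <- tile_attention_scores(bag, params, config)
    top <- top_k_tiles(sc, bag$coords, k)
    slide_pred <- forward_bag(bag, params, config)$risk_probability
    e <- matrix(0, nrow(top), config$embed_dim)
    ts <- numeric(nrow(top))
    for (j in seq_len(nrow(top))) {
      i <- top$index[j]
      sb <- tile_bag(bag$features[i, , drop = FALSE],
                     bag$coords[i, , drop = FALSE],
                     slide_id = bag$slide_id, patient_id = bag$patient_id)
      r <- forward_bag(sb, params, config)
      e[j, ] <- r$embedding_cls
      ts[j] <- r$risk_probability
    }
    emb[[length(emb) + 1L]] <- e
    meta[[length(meta) + 1L]] <- data.frame(
      slide_id = bag$slide_id, col = top$col, row = top$row,
      risk_group = assign_risk_group(bag$label_normalized, "normalized"),
      slide_score = slide_pred, tile_score = ts, attention = top$score)
  }
  structure(list(embeddings = do.call(rbind, emb),
                 meta = do.call(rbind, meta)),
            class = "tile_embedding_table")
}

#' Leiden subclusters of tile embeddings
#'
#' Builds a cosine k-nearest-neighbour graph (symmetrized union of the
#' directed neighbour sets; edge weight = cosine similarity shifted to be
#' positive) and runs Leiden community detection (modularity objective) at
#' the given resolution. Labels are renumbered 0..C-1 by decreasing cluster
#' size.
#'
#' The default resolution is 0.5: at 1.0 the resolution limit of modularity
#' fragments large homogeneous tile populations into arbitrary shards,
#' whereas 0.5 recovers well-separated planted partitions exactly while
#' still producing fine-grained subclusters on real embedding tables.
#'
#' @param table a [collect_top_tiles()] result, or a plain embedding matrix.
#' @param n_neighbors neighbourhood size (default 50).
#' @param resolution Leiden resolution parameter (default 0.5).
#' @param seed RNG seed.
#' @return integer vector of cluster labels (0-based).
#' @export
cluster_embeddings <- function(table, n_neighbors = 50L, resolution = 0.5,
                               seed = 1L) {
  X <- if (inherits(table, "tile_embedding_table")) table$embeddings
       else as.matrix(table)
  n <- nrow(X)
  if (n <= n_neighbors)
    stop_invalid("need more than n_neighbors (", n_neighbors, ") points, got ", n)
  Xn <- X / sqrt(rowSums(X^2))
  S <- tcrossprod(Xn)                      # cosine similarity
  diag(S) <- -Inf
  nb <- t(apply(S, 1L, function(r) order(r, decreasing = TRUE)[seq_len(n_neighbors)]))
  from <- rep(seq_len(n), each = n_neighbors)
  to <- as.integer(t(nb))
  # symmetrized union, one undirected edge per pair
  a <- pmin(from, to); b <- pmax(from, to)
  key <- paste(a, b)
  keep <- !duplicated(key)
  a <- a[keep]; b <- b[keep]
  w <- S[cbind(a, b)]
  w <- (w + 1) / 2                         # map [-1,1] cosine to (0,1] weight
  g <- igraph::graph_from_edgelist(cbind(a, b), directed = FALSE)
  igraph::E(g)$weight <- w
  set.seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution, n_iterations = 5L)
  lab <- igraph::membership(cl)
  sizes <- sort(table(lab), decreasing = TRUE)
  remap <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  unname(remap[as.character(lab)])
}

#' Classify subclusters by risk-group specificity
#'
#' A cluster is retained in group `g` iff its tile count from `g` strictly
#' exceeds 25% of the cluster total. Retained in both groups: colocalized;
#' only in the high (low) group: high-specific (low-specific). Because the
#' majority group always exceeds 25%, every cluster receives exactly one
#' label.
#'
#' @param labels integer cluster labels (one per tile).
#' @param risk_group character `"high"`/`"low"` per tile.
#' @param keep_frac retention threshold (default 0.25, strict).
#' @return data frame (class `subcluster_report`) with one row per cluster:
#'   `cluster`, `n_total`, `n_high`, `n_low`, `specificity`.
#' @export
classify_subclusters <- function(labels, risk_group, keep_frac = 0.25) {
  if (length(labels) != length(risk_group))
    stop_invalid("labels and risk_group must align")
  if (!all(risk_group %in% c("high", "low")))
    stop_invalid("risk_group values must be 'high' or 'low'")
  cl <- sort(unique(labels))
  rows <- lapply(cl, function(cid) {
    sel <- labels == cid
    n_tot <- sum(sel)
    n_hi <- sum(risk_group[sel] == "high")
    n_lo <- n_tot - n_hi
    keep_hi <- n_hi > keep_frac * n_tot
    keep_lo <- n_lo > keep_frac * n_tot
    spec <- if (keep_hi && keep_lo) "colocalized"
            else if (keep_hi) "high-specific" else "low-specific"
    data.frame(cluster = cid, n_total = n_tot, n_high = n_hi, n_low = n_lo,
               specificity = spec)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("subcluster_report", "data.frame")
  out
}

#' Cellular-composition matrix and Ward dendrogram of subclusters
#'
#' For each cluster, the mean number of cells of each of the five types
#' over its tiles; each column is then min-max scaled across clusters
#' (constant columns become all zeros); finally Ward variance-minimization
#' hierarchical clustering on Euclidean distances over the scaled rows.
#'
#' @param labels integer cluster labels, one per tile.
#' @param cellmaps list of [cell_map()]s, one per tile (same order).
#' @return list with `composition` (raw per-cluster mean counts),
#'   `composition_scaled` (min-max by column), and `hclust` (the merge
#'   tree, heights non-decreasing).
#' @export
composition_dendrogram <- function(labels, cellmaps) {
  if (length(labels) != length(cellmaps))
    stop_invalid("one cell map per tile required")
  ok <- vapply(cellmaps, inherits, logical(1), "cell_map")
  if (!all(ok))
    stop_invalid("missing/invalid cell map for tile(s): ",
                 paste(utils::head(which(!ok), 5L), collapse = ", "))
  counts <- t(vapply(cellmaps, function(cm)
    as.numeric(table(factor(cm$cell_types, levels = CELL_TYPES))),
    numeric(length(CELL_TYPES))))
  colnames(counts) <- CELL_TYPES
  cl <- sort(unique(labels))
  comp <- t(vapply(cl, function(cid)
    colMeans(counts[labels == cid, , drop = FALSE]),
    numeric(length(CELL_TYPES))))
  rownames(comp) <- paste0("SC", cl)
  scaled <- apply(comp, 2L, function(v) {
    r <- max(v) - min(v)
    if (r < .Machine$double.eps) rep(0, length(v)) else (v - min(v)) / r
  })
  if (is.null(dim(scaled))) scaled <- matrix(scaled, nrow = 1L,
                                             dimnames = list(rownames(comp),
                                                             colnames(comp)))
  hc <- if (nrow(scaled) >= 2L)
    stats::hclust(stats::dist(scaled, "euclidean"), method = "ward.D2")
  else NULL
  list(composition = comp, composition_scaled = scaled, hclust = hc)
}
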