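# Phenotype discovery: planted-partition recovery by the cosine-kNN Leiden
# pipeline, the strict 25% specificity rule, the Ward dendrogram against a
# Lance-Williams recurrence oracle, and top-tile collection bookkeeping.

make_blobs <- function(centers, n_each, sd = 0.05, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    matrix(rnorm(n_each * ncol(centers), sd = sd), n_each) +
      matrix(centers[i, ], n_each, ncol(centers), byrow = TRUE)))
  list(X = X, truth = rep(seq_len(nrow(centers)), each = n_each))
}

test_that("two well-separated blobs are recovered exactly", {
  centers <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))   # ~20 sd apart in cosine terms
  bl <- make_blobs(centers, 500, sd = 0.05, seed = 7)
  lab <- cluster_embeddings(bl$X, n_neighbors = 50, seed = 3)
  expect_equal(length(unique(lab)), 2L)
  expect_equal(adjusted_rand_index(lab, bl$truth), 1)
  expect_identical(lab,
                   cluster_embeddings(bl$X, n_neighbors = 50, seed = 3))
  expect_error(cluster_embeddings(bl$X[1:40, ], n_neighbors = 50), "n_neighbors")
})

test_that("duplicated points stay co-clustered", {
  centers <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  bl <- make_blobs(centers, 120, sd = 0.05, seed = 9)
  lab2 <- cluster_embeddings(rbind(bl$X, bl$X), n_neighbors = 20, seed = 5)
  n <- nrow(bl$X)
  expect_gte(adjusted_rand_index(lab2[seq_len(n)], lab2[n + seq_len(n)]), 0.99)
})

test_that("specificity follows the strict 25% retention rule", {
  lab <- rep(0:2, c(100, 100, 100))
  grp <- c(rep(c("high", "low"), c(80, 20)),    # 80/20 -> high-specific
           rep(c("high", "low"), c(74, 26)),    # 74/26 -> colocalized
           rep(c("high", "low"), c(25, 75)))    # 25/75 -> low-specific (strict)
  rep_ <- classify_subclusters(lab, grp)
  expect_identical(rep_$specificity,
                   c("high-specific", "colocalized", "low-specific"))
  expect_identical(rep_$n_total, rep_$n_high + rep_$n_low)

  # totality: every cluster gets exactly one label for any split
  set.seed(21)
  for (r in 1:50) {
    n <- sample(4:60, 1)
    lab_r <- sample(0:3, n, replace = TRUE)
    grp_r <- sample(c("high", "low"), n, replace = TRUE)
    rr <- classify_subclusters(lab_r, grp_r)
    expect_true(all(rr$specificity %in%
                      c("high-specific", "low-specific", "colocalized")))
    expect_equal(nrow(rr), length(unique(lab_r)))
  }
})

# Lance-Williams recurrence for Ward linkage on squared Euclidean
# distances; heights reported on the distance scale (square root), the
# convention of variance-minimization linkage on a Euclidean matrix.
ward_oracle_heights <- function(X) {
  n <- nrow(X)
  D2 <- as.matrix(dist(X))^2
  size <- rep(1, n)
  active <- rep(TRUE, n)
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- Inf; bi <- bj <- NA
    for (i in which(active)) for (j in which(active)) if (i < j) {
      if (D2[i, j] < best) { best <- D2[i, j]; bi <- i; bj <- j }
    }
    heights[step] <- sqrt(best)
    for (k in which(active)) if (k != bi && k != bj) {
      ni <- size[bi]; nj <- size[bj]; nk <- size[k]
      D2[bi, k] <- D2[k, bi] <-
        ((ni + nk) * D2[bi, k] + (nj + nk) * D2[bj, k] - nk * D2[bi, bj]) /
        (ni + nj + nk)
    }
    size[bi] <- size[bi] + size[bj]
    active[bj] <- FALSE
  }
  heights
}

test_that("composition dendrogram reproduces the Lance-Williams recurrence", {
  # 4 clusters with hand-set compositions; 2 tiles per cluster so the
  # per-cluster means are exact
  comps <- rbind(c(10, 2, 0, 5, 1),
                 c(9, 3, 0, 6, 1),
                 c(1, 8, 2, 1, 0),
                 c(2, 9, 1, 1, 0))
  cms <- list(); labs <- integer(0)
  set.seed(2)
  for (cl in 1:4) for (rep in 1:2) {
    counts <- comps[cl, ]
    types <- rep(CELL_TYPES, counts)
    m <- length(types)
    cms[[length(cms) + 1L]] <- cell_map(matrix(runif(2 * m, 0, 100), m, 2),
                                        types, 100, 100)
    labs <- c(labs, cl - 1L)
  }
  res <- composition_dendrogram(labs, cms)
  expect_equal(res$composition, comps, ignore_attr = TRUE)
  # min-max contract per non-constant column
  nonconst <- apply(comps, 2, function(v) diff(range(v)) > 0)
  expect_true(all(apply(res$composition_scaled[, nonconst, drop = FALSE], 2,
                        function(v) min(v) == 0 && max(v) == 1)))
  expect_true(all(res$composition_scaled[, !nonconst] == 0))
  expect_equal(sort(res$hclust$height),
               sort(ward_oracle_heights(res$composition_scaled)),
               tolerance = 1e-8)
  expect_true(all(diff(res$hclust$height) >= -1e-12))

  # identical within-group compositions merge first at height zero
  dup <- composition_dendrogram(c(0L, 0L, 1L, 1L, 2L, 2L, 3L, 3L),
                                cms[c(1, 1, 2, 2, 5, 5, 6, 6)])
  expect_equal(dup$hclust$height[1:2], c(0, 0), tolerance = 1e-12)
})

test_that("planted phenotypes are classified as specific and colocalized", {
  # two embedding blobs present only in high-risk slides, one shared blob
  centers <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0))
  hits <- 0L
  for (seed in 1:50) {
    bl <- make_blobs(centers, 150, sd = 0.05, seed = seed)
    grp <- c(rep("high", 300),                       # blobs 1-2: high only
             rep(c("high", "low"), 75))              # blob 3: half and half
    lab <- cluster_embeddings(bl$X, n_neighbors = 50, seed = seed)
    if (length(unique(lab)) != 3L) next
    rep_ <- classify_subclusters(lab, grp)
    if (identical(sort(rep_$specificity),
                  c("colocalized", "high-specific", "high-specific")))
      hits <- hits + 1L
  }
  expect_gte(hits, 48L)                              # >= 95% of 50 seeds
})

test_that("top-tile collection respects truncation and scoring", {
  cfg <- tiny_config()
  par <- init_params(cfg, seed = 11)
  bags <- list(random_bag(n = 8, c = 8, seed = 1, label = 0.2),
               random_bag(n = 30, c = 8, seed = 2, label = 0.9))
  tab <- collect_top_tiles(bags, par, cfg, k = 10)
  expect_equal(nrow(tab$embeddings), 8 + 10)         # sum of min(k, n_i)
  expect_equal(nrow(tab$meta), 18)
  expect_identical(unique(tab$meta$risk_group[1:8]), "high")
  expect_identical(unique(tab$meta$risk_group[9:18]), "low")

  # selected set matches the top-k oracle on the heavy-tie slide
  sc <- tile_attention_scores(bags[[2]], par, cfg)
  top <- top_k_tiles(sc, bags[[2]]$coords, 10)
  expect_equal(tab$meta$attention[9:18], top$score)
  # each row's embedding equals embed_tile of the chosen tile
  i <- top$index[1]
  expect_equal(tab$embeddings[9, ],
               embed_tile(bags[[2]]$features[i, , drop = FALSE],
                          bags[[2]]$coords[i, ], par, cfg))
})
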