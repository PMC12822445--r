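# Forward-pass contracts: projection and positional-encoding oracles, the
# set-function property, singleton-bag consistency, a straight-line scalar
# re-implementation of the whole forward pass, and the finite-difference
# gradient check.

test_that("tile projection is ReLU(F W + b) with non-negative output", {
  cfg <- tiny_config()
  par <- init_params(cfg, seed = 2)
  par$b_in <- seq(-0.5, 0.5, length.out = cfg$embed_dim)

  zero <- matrix(0, 4, 8)
  out0 <- project_tiles(zero, par)
  for (i in 1:4) expect_equal(out0[i, ], pmax(par$b_in, 0))

  set.seed(9)
  feat <- matrix(rnorm(24), 3, 8)
  out <- project_tiles(feat, par)
  expect_true(all(out >= 0))
  # per-element scalar oracle
  oracle <- matrix(0, 3, cfg$embed_dim)
  for (i in 1:3) for (j in seq_len(cfg$embed_dim)) {
    s <- par$b_in[j]
    for (t in 1:8) s <- s + feat[i, t] * par$w_in[t, j]
    oracle[i, j] <- max(s, 0)
  }
  expect_equal(out, oracle, tolerance = 1e-6)
  expect_error(project_tiles(matrix(0, 2, 5), par), "channels")
})

test_that("2D sinusoidal positional encoding matches its closed form", {
  pe0 <- positional_encoding(matrix(c(0L, 0L), 1), 8L)
  expect_equal(drop(pe0), rep(c(0, 1), 4))          # sin 0 = 0, cos 0 = 1

  # equal coordinates give equal rows
  pe <- positional_encoding(rbind(c(3L, 7L), c(3L, 7L), c(2L, 7L)), 16L)
  expect_equal(pe[1, ], pe[2, ])
  expect_false(isTRUE(all.equal(pe[1, ], pe[3, ])))

  # coords (1, 0), dim 8: direct transcendental evaluation
  pe1 <- drop(positional_encoding(matrix(c(1L, 0L), 1), 8L))
  expected <- c(sin(1 / 10000^(0 / 4)), cos(1 / 10000^(0 / 4)),
                sin(1 / 10000^(2 / 4)), cos(1 / 10000^(2 / 4)),
                0, 1, 0, 1)
  expect_equal(pe1, expected, tolerance = 1e-12)
  expect_true(all(abs(positional_encoding(cbind(0:40, 40:0), 32L)) <= 1))
  expect_error(positional_encoding(matrix(0L, 1, 2), 6L), "divisible")
})

# Straight-line scalar forward oracle: explicit loops over the published
# architecture, sharing no code with the package implementation.
forward_oracle <- function(feat, coords, par, cfg) {
  n <- nrow(feat); E <- cfg$embed_dim; H <- cfg$n_heads; dh <- E / H
  relu <- function(x) ifelse(x > 0, x, 0)
  ln <- function(v, g, b) {
    mu <- mean(v); s <- sqrt(mean((v - mu)^2) + 1e-5)
    g * (v - mu) / s + b
  }
  softmax <- function(v) { e <- exp(v - max(v)); e / sum(e) }

  X <- matrix(0, n + 1, E)
  for (i in 1:n) {
    proj <- relu(as.numeric(feat[i, ] %*% par$w_in) + par$b_in)
    pe <- numeric(E); half <- E / 2; npair <- half / 2
    for (ax in 1:2) {
      pos <- coords[i, ax]
      for (q in seq_len(npair)) {
        div <- 10000^(2 * (q - 1) / half)
        pe[(ax - 1) * half + 2 * q - 1] <- sin(pos / div)
        pe[(ax - 1) * half + 2 * q] <- cos(pos / div)
      }
    }
    X[i, ] <- proj + pe
  }
  X[n + 1, ] <- par$cls

  X1 <- t(apply(X, 1, ln, g = par$ln1_g, b = par$ln1_b))
  k <- min(cfg$n_agents, n + 1)
  O <- matrix(0, n + 1, E)
  for (h in 1:H) {
    idx <- ((h - 1) * dh + 1):(h * dh)
    Q <- X1 %*% par$w_q[, idx]; K <- X1 %*% par$w_k[, idx]
    V <- X1 %*% par$w_v[, idx]
    # segment-mean agents over the n+1 rows
    sizes <- rep((n + 1) %/% k, k); extra <- (n + 1) %% k
    if (extra) sizes[1:extra] <- sizes[1:extra] + 1
    ends <- cumsum(sizes); starts <- c(1, head(ends, -1) + 1)
    A <- matrix(0, k, dh)
    for (j in 1:k) A[j, ] <- colMeans(Q[starts[j]:ends[j], , drop = FALSE])
    VA <- matrix(0, k, dh)
    for (j in 1:k) {
      w <- softmax(as.numeric(A[j, ] %*% t(K)) / sqrt(dh))
      for (m in 1:(n + 1)) VA[j, ] <- VA[j, ] + w[m] * V[m, ]
    }
    for (i in 1:(n + 1)) {
      w <- softmax(as.numeric(Q[i, ] %*% t(A)) / sqrt(dh))
      for (j in 1:k) O[i, idx] <- O[i, idx] + w[j] * VA[j, ]
    }
  }
  H1 <- X + O
  X2 <- t(apply(H1, 1, ln, g = par$ln2_g, b = par$ln2_b))
  FF <- relu(sweep(X2 %*% par$ff_w1, 2, par$ff_b1, "+")) %*% par$ff_w2
  FF <- sweep(FF, 2, par$ff_b2, "+")
  H2 <- H1 + FF
  z <- ln(H2[n + 1, ], par$ln3_g, par$ln3_b)
  1 / (1 + exp(-(sum(z * par$head_w) + par$head_b)))
}

test_that("forward pass reproduces an independent scalar re-implementation", {
  cfg <- model_config(input_dim = 4L, embed_dim = 8L, n_heads = 2L,
                      ff_hidden_dim = 12L, n_agents = 1L)
  par <- init_params(cfg, seed = 1)
  # prescribed small deterministic constants, not the random init
  fill <- function(nr, nc, phase)
    matrix(0.05 * sin(seq_len(nr * nc) / 3 + phase), nr, nc)
  par$w_in <- fill(4, 8, 0); par$b_in <- 0.01 * (1:8)
  par$cls <- matrix(0.1 * cos(1:8), 1, 8)
  par$w_q <- fill(8, 8, 1); par$w_k <- fill(8, 8, 2); par$w_v <- fill(8, 8, 3)
  par$ff_w1 <- fill(8, 12, 4); par$ff_b1 <- rep(0.02, 12)
  par$ff_w2 <- fill(12, 8, 5); par$ff_b2 <- rep(-0.01, 8)
  par$ln1_g <- rep(1.1, 8); par$ln1_b <- rep(0.05, 8)
  par$ln2_g <- rep(0.9, 8); par$ln2_b <- rep(-0.05, 8)
  par$ln3_g <- rep(1.05, 8); par$ln3_b <- rep(0, 8)
  par$head_w <- matrix(0.2 * sin(1:8), 8, 1); par$head_b <- 0.1

  feat <- matrix(0.3 * cos(1:12), 3, 4)
  coords <- cbind(0:2, c(0L, 1L, 0L))
  bag <- tile_bag(feat, coords, "s", "p")
  got <- forward_bag(bag, par, cfg)$risk_probability
  expect_equal(got, forward_oracle(feat, coords, par, cfg), tolerance = 1e-6)
})

test_that("bag prediction behaves as a set function", {
  cfg <- tiny_config()
  par <- init_params(cfg, seed = 4)
  bag <- random_bag(n = 9, c = 8, seed = 21)
  base <- forward_bag(bag, par, cfg)
  expect_true(base$risk_probability > 0 && base$risk_probability < 1)

  set.seed(2)
  perm <- sample(9)
  bag_p <- tile_bag(bag$features[perm, ], bag$coords[perm, ],
                    bag$slide_id, bag$patient_id,
                    label_normalized = bag$label_normalized)
  # fixed agents: exact invariance
  A <- matrix(0.1 * sin(1:(3 * cfg$embed_dim)), 3, cfg$embed_dim)
  expect_equal(forward_bag(bag_p, par, cfg, agents = A)$risk_probability,
               forward_bag(bag, par, cfg, agents = A)$risk_probability,
               tolerance = 1e-5)
  # pooled agents: canonical coordinate ordering makes this exact too
  expect_equal(forward_bag(bag_p, par, cfg)$risk_probability,
               base$risk_probability, tolerance = 1e-12)
  # and the per-tile scores follow the permutation
  expect_equal(forward_bag(bag_p, par, cfg)$tile_scores_raw,
               base$tile_scores_raw[perm], tolerance = 1e-12)
})

test_that("embed_tile equals the class embedding of the singleton bag", {
  cfg <- tiny_config()
  par <- init_params(cfg, seed = 6)
  set.seed(3)
  tf <- matrix(rnorm(8), 1, 8)
  e1 <- embed_tile(tf, c(2L, 5L), par, cfg)
  expect_length(e1, cfg$embed_dim)
  expect_identical(e1, embed_tile(tf, c(2L, 5L), par, cfg))
  sb <- tile_bag(tf, matrix(c(2L, 5L), 1), "s", "p")
  expect_equal(e1, forward_bag(sb, par, cfg)$embedding_cls)
})

test_that("backprop agrees with central finite differences", {
  cfg <- tiny_config()
  par <- init_params(cfg, seed = 8)
  bag <- random_bag(n = 5, c = 8, seed = 12, label = 0.8)
  res <- cpmp:::forward_bag_impl(bag, par, cfg, keep_cache = TRUE)
  gr <- cpmp:::backward_bag(res, par, cfg, bag$label_normalized)
  lossfun <- function(p)
    cpmp:::bag_loss(forward_bag(bag, p, cfg)$risk_probability,
                    bag$label_normalized, cfg)
  eps <- 1e-5
  set.seed(10)
  checked <- 0L
  for (nm in sample(names(par))) {
    ix <- sample(length(par[[nm]]), 1L)
    p1 <- par; p1[[nm]][ix] <- p1[[nm]][ix] + eps
    p2 <- par; p2[[nm]][ix] <- p2[[nm]][ix] - eps
    fd <- (lossfun(p1) - lossfun(p2)) / (2 * eps)
    an <- gr[[nm]][ix]
    expect_lt(abs(fd - an) / max(abs(fd), abs(an), 1e-8), 1e-4)
    checked <- checked + 1L
    if (checked >= 10L) break
  }
})

test_that("duplicating every tile at nearby coords barely moves the prediction", {
  cfg <- tiny_config()
  par <- init_params(cfg, seed = 14)
  bag <- random_bag(n = 12, c = 8, seed = 33)
  # near-duplicates: shift the copy by one grid row beyond the occupied block
  shift <- max(bag$coords[, 2]) + 1L
  bag2 <- tile_bag(rbind(bag$features, bag$features),
                   rbind(bag$coords,
                         cbind(bag$coords[, 1], bag$coords[, 2] + shift)),
                   bag$slide_id, bag$patient_id,
                   label_normalized = bag$label_normalized)
  d <- abs(forward_bag(bag2, par, cfg)$risk_probability -
           forward_bag(bag, par, cfg)$risk_probability)
  expect_lt(d, 0.05)
})
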