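#' Model configuration
#'
#' Architecture and loss hyperparameters of the slide-level network: a
#' linear+ReLU tile projection into `embed_dim`, 2D absolute sinusoidal
#' positional encoding, one pre-norm agent-attention transformer layer, and
#' a LayerNorm + linear + sigmoid regression head on the class token.
#'
#' @param input_dim number of input feature channels `c`.
#' @param embed_dim transformer width (default 256).
#' @param n_heads attention heads (default 4); must divide `embed_dim`.
#' @param n_layers transformer layers (default 1; only 1 is supported).
#' @param ff_hidden_dim feed-forward hidden width (default 512).
#' @param n_agents number of agent tokens `k` (default 16).
#' @param lambda1,lambda2 loss scale factors of the dual-MSE objective
#'   (defaults 1, 1).
#' @return list of class `model_config`.
#' @export
model_config <- function(input_dim, embed_dim = 256L, n_heads = 4L,
                         n_layers = 1L, ff_hidden_dim = 512L,
                         n_agents = 16L, lambda1 = 1, lambda2 = 1) {
  if (embed_dim %% n_heads != 0L)
    stop_invalid("embed_dim must be divisible by n_heads")
  if (embed_dim %% 4L != 0L)
    stop_invalid("embed_dim must be divisible by 4 for 2D positional encoding")
  if (n_layers != 1L)
    stop_invalid("only a single transformer layer is supported")
  if (any(c(input_dim, embed_dim, n_heads, ff_hidden_dim, n_agents) < 1L))
    stop_invalid("all dimensions must be positive")
  if (lambda1 < 0 || lambda2 < 0)
    stop_invalid("lambda1 and lambda2 must be non-negative")
  structure(list(input_dim = as.integer(input_dim),
                 embed_dim = as.integer(embed_dim),
                 n_heads = as.integer(n_heads),
                 n_layers = as.integer(n_layers),
                 ff_hidden_dim = as.integer(ff_hidden_dim),
                 n_agents = as.integer(n_agents),
                 lambda1 = as.numeric(lambda1),
                 lambda2 = as.numeric(lambda2)),
            class = "model_config")
}

# Kaiming-uniform draw for a fan_in x fan_out weight matrix (ReLU gain).
kaiming_uniform <- function(fan_in, fan_out) {
  bound <- sqrt(6 / fan_in)
  matrix(stats::runif(fan_in * fan_out, -bound, bound), fan_in, fan_out)
}

#' Initialize model parameters
#'
#' All weight matrices use the Kaiming uniform scheme; biases start at zero,
#' layer-norm gains at one, and the class token at a small uniform draw.
#'
#' @param config a [model_config()].
#' @param seed RNG seed.
#' @return list of class `model_params` holding all learnable tensors.
#' @export
init_params <- function(config, seed = 1L) {
  set.seed(seed)
  E <- config$embed_dim; Fh <- config$ff_hidden_dim; C <- config$input_dim
  structure(list(
    w_in = kaiming_uniform(C, E), b_in = numeric(E),
    cls = matrix(stats::runif(E, -1, 1) / sqrt(E), 1L, E),
    ln1_g = rep(1, E), ln1_b = numeric(E),
    w_q = kaiming_uniform(E, E),
    w_k = kaiming_uniform(E, E),
    w_v = kaiming_uniform(E, E),
    ln2_g = rep(1, E), ln2_b = numeric(E),
    ff_w1 = kaiming_uniform(E, Fh), ff_b1 = numeric(Fh),
    ff_w2 = kaiming_uniform(Fh, E), ff_b2 = numeric(E),
    ln3_g = rep(1, E), ln3_b = numeric(E),
    head_w = kaiming_uniform(E, 1L), head_b = 0
  ), class = "model_params")
}

#' Project tile features into the embedding space
#'
#' `ReLU(features W + b)`: the instance-level transformation preceding the
#' transformer. Output entries are all non-negative.
#'
#' @param features `n x c` matrix.
#' @param params a `model_params` list (uses `w_in`, `b_in`).
#' @return `n x embed_dim` matrix.
#' @export
project_tiles <- function(features, params) {
  features <- as.matrix(features)
  if (ncol(features) != nrow(params$w_in))
    stop_invalid("feature channels (", ncol(features),
                 ") do not match the model input dimension (",
                 nrow(params$w_in), ")")
  pmax(sweep(features %*% params$w_in, 2L, params$b_in, "+"), 0)
}

#' 2D absolute sinusoidal positional encoding
#'
#' The first `dim/2` channels encode the column coordinate and the last
#' `dim/2` the row, each as interleaved sine/cosine pairs at geometric
#' wavelengths `10000^(2i/(dim/2))`. Values lie in \[-1, 1\] and depend only
#' on the coordinates, so identical positions get identical encodings.
#'
#' @param coords `n x 2` integer (column, row) grid positions.
#' @param dim encoding width; must be divisible by 4.
#' @return `n x dim` matrix.
#' @export
positional_encoding <- function(coords, dim) {
  coords <- as.matrix(coords)
  if (dim %% 4L != 0L) stop_invalid("dim must be divisible by 4")
  half <- dim %/% 2L                      # channels per axis
  npair <- half %/% 2L                    # sin/cos pairs per axis
  div <- 10000^(2 * (seq_len(npair) - 1L) / half)
  enc_axis <- function(pos) {
    ang <- outer(pos, 1 / div)            # n x npair
    out <- matrix(0, length(pos), half)
    out[, seq(1L, half, by = 2L)] <- sin(ang)
    out[, seq(2L, half, by = 2L)] <- cos(ang)
    out
  }
  cbind(enc_axis(as.numeric(coords[, 1L])),
        enc_axis(as.numeric(coords[, 2L])))
}

# Full forward pass with optional cache for backprop.
# agents: optional fixed agent matrix (k x embed_dim, split per head);
#         if NULL, agents are segment-mean pooled from the per-head queries
#         over the full (n+1)-row sequence including the class token.
# Tiles are processed in canonical row-major coordinate order so that
# segment-mean agent pooling (and hence the prediction) is invariant to the
# order tiles arrive in; per-tile outputs are mapped back to input order.
forward_bag_impl <- function(bag, params, config, agents = NULL,
                             keep_cache = FALSE) {
  canon <- order(bag$coords[, 2L], bag$coords[, 1L])
  feat <- bag$features[canon, , drop = FALSE]
  n <- nrow(feat)
  E <- config$embed_dim; H <- config$n_heads; dh <- E %/% H
  k <- min(config$n_agents, n + 1L)

  Ppre <- sweep(feat %*% params$w_in, 2L, params$b_in, "+")
  Pr <- pmax(Ppre, 0)
  PE <- positional_encoding(bag$coords[canon, , drop = FALSE], E)
  X <- rbind(Pr + PE, params$cls)

  ln1 <- layer_norm_fwd(X, params$ln1_g, params$ln1_b)
  X1 <- ln1$y
  Pmat <- if (is.null(agents)) pooling_matrix(n + 1L, k) else NULL

  O <- matrix(0, n + 1L, E)
  R <- matrix(0, n + 1L, n + 1L)
  heads <- vector("list", H)
  sq <- sqrt(dh)
  for (h in seq_len(H)) {
    idx <- ((h - 1L) * dh + 1L):(h * dh)
    Q <- X1 %*% params$w_q[, idx, drop = FALSE]
    K <- X1 %*% params$w_k[, idx, drop = FALSE]
    V <- X1 %*% params$w_v[, idx, drop = FALSE]
    A <- if (is.null(agents)) Pmat %*% Q else agents[, idx, drop = FALSE]
    S1 <- row_softmax(tcrossprod(A, K) / sq)
    VA <- S1 %*% V
    S2 <- row_softmax(tcrossprod(Q, A) / sq)
    O[, idx] <- S2 %*% VA
    R <- R + S2 %*% S1
    if (keep_cache)
      heads[[h]] <- list(Q = Q, K = K, V = V, A = A,
                         S1 = S1, VA = VA, S2 = S2)
  }
  R <- R / H

  H1 <- X + O
  ln2 <- layer_norm_fwd(H1, params$ln2_g, params$ln2_b)
  FFpre <- sweep(ln2$y %*% params$ff_w1, 2L, params$ff_b1, "+")
  FFa <- pmax(FFpre, 0)
  H2 <- H1 + sweep(FFa %*% params$ff_w2, 2L, params$ff_b2, "+")

  cls_out <- H2[n + 1L, , drop = FALSE]
  ln3 <- layer_norm_fwd(cls_out, params$ln3_g, params$ln3_b)
  logit <- drop(ln3$y %*% params$head_w) + params$head_b
  prob <- sigmoid(logit)
  if (!is.finite(prob)) stop_invalid("non-finite activation in forward pass")

  scores <- numeric(n)
  scores[canon] <- R[n + 1L, seq_len(n)]   # back to input tile order
  out <- list(risk_probability = prob,
              tile_scores_raw = scores,
              embedding_cls = drop(cls_out),
              logit = logit)
  if (keep_cache)
    out$cache <- list(feat = feat, Ppre = Ppre, PE = PE, X = X,
                      ln1 = ln1, X1 = X1, Pmat = Pmat, heads = heads,
                      H1 = H1, ln2 = ln2, FFpre = FFpre, FFa = FFa,
                      ln3 = ln3, prob = prob, n = n, k = k, dh = dh,
                      fixed_agents = !is.null(agents))
  out
}

#' Forward pass over one bag
#'
#' Runs the full slide-level network on a bag: tile projection plus
#' positional encoding, class-token concatenation, one pre-norm
#' agent-attention transformer layer with residual connections, and the
#' LayerNorm + linear + sigmoid head on the class position. Tile scores are
#' the class-token row of the head-averaged rollout matrix restricted to
#' tile columns.
#'
#' Tiles are processed internally in canonical row-major coordinate order
#' (coordinates are unique within a bag), so the prediction is invariant to
#' the order in which tiles are supplied even though agent tokens are
#' pooled from contiguous query segments; per-tile scores are returned in
#' the input order.
#'
#' @param bag a [tile_bag()].
#' @param params a `model_params` list from [init_params()] or training.
#' @param config the matching [model_config()].
#' @param agents optional fixed `k x embed_dim` agent matrix; by default
#'   agents are segment-mean pooled from the queries (class token included).
#' @return list with `risk_probability` (in (0,1)), `tile_scores_raw`
#'   (length `n`), `embedding_cls` (the detached class-token vector between
#'   the transformer block and the head), and `logit`.
#' @export
forward_bag <- function(bag, params, config, agents = NULL) {
  if (!inherits(bag, "tile_bag")) stop_invalid("bag must be a tile_bag")
  forward_bag_impl(bag, params, config, agents = agents, keep_cache = FALSE)
}

#' Embed a single tile
#'
#' The class-token embedding of the singleton bag containing one tile:
#' identical to `forward_bag()` on that bag, returning `embedding_cls`.
#'
#' @param tile_features `1 x c` feature row.
#' @param coords `1 x 2` tile coordinate.
#' @param params,config as in [forward_bag()].
#' @return numeric vector of length `embed_dim`.
#' @export
embed_tile <- function(tile_features, coords, params, config) {
  bag <- tile_bag(matrix(as.numeric(tile_features), nrow = 1L),
                  matrix(as.integer(coords), nrow = 1L),
                  slide_id = "tile", patient_id = "tile")
  forward_bag_impl(bag, params, config)$embedding_cls
}

#' Save / load a model checkpoint
#'
#' A checkpoint bundles the parameter tensors, the architecture
#' configuration and the creation seed in a single serialized file.
#'
#' @param params,config model state to store.
#' @param seed integer recorded alongside the state.
#' @param path file path.
#' @return `load_checkpoint` returns a list with `params`, `config`, `seed`.
#' @export
save_checkpoint <- function(params, config, seed, path) {
  stopifnot(inherits(params, "model_params"), inherits(config, "model_config"))
  saveRDS(list(format = "cpmp-checkpoint", version = 1L,
               params = params, config = config, seed = as.integer(seed)),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "cpmp-checkpoint"))
    stop_invalid("not a cpmp checkpoint: ", path)
  E <- ck$config$embed_dim
  if (!identical(dim(ck$params$w_q), c(E, E)))
    stop_invalid("checkpoint parameter shapes do not match its config")
  ck[c("params", "config", "seed")]
}
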