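# Reverse-mode gradients of the per-bag dual-MSE loss with respect to every
# learnable tensor. The loss touches the sequence only through the class
# token, so the head, feed-forward and second layer-norm backward steps
# operate on that single row; the attention and first layer-norm steps are
# full-sequence because keys/values (and pooled agents) involve every tile.

# Softmax Jacobian-vector product for one row.
softmax_bwd_row <- function(s, ds) s * (ds - sum(ds * s))

# Row-wise softmax backward for a full matrix.
softmax_bwd <- function(S, dS) S * (dS - rowSums(dS * S))

# Gradient of the single-bag loss
#   lambda1 (Y - p)^2 + lambda2 1(Y > 0.5) (Y - p)^2
# w.r.t. all parameters. `res` must come from forward_bag_impl(keep_cache=TRUE).
backward_bag <- function(res, params, config, label) {
  ca <- res$cache
  n <- ca$n; E <- config$embed_dim; H <- config$n_heads; dh <- ca$dh
  sq <- sqrt(dh)
  p <- ca$prob
  ind <- as.numeric(label > 0.5)
  dp <- -2 * (config$lambda1 + config$lambda2 * ind) * (label - p)
  dlogit <- dp * p * (1 - p)

  g <- list()

  # head: logit = ln3(cls_out) . head_w + head_b
  g$head_w <- matrix(drop(ca$ln3$y) * dlogit, E, 1L)
  g$head_b <- dlogit
  dln3y <- matrix(drop(params$head_w) * dlogit, 1L, E)
  bw3 <- layer_norm_bwd(dln3y, ca$ln3, params$ln3_g)
  g$ln3_g <- bw3$dgamma; g$ln3_b <- bw3$dbeta
  dcls_out <- bw3$dx                      # 1 x E, gradient at H2[n+1, ]

  # feed-forward block (class row only)
  ffa_row <- ca$FFa[n + 1L, ]
  dffo <- dcls_out                        # 1 x E
  g$ff_w2 <- outer(ffa_row, drop(dffo))
  g$ff_b2 <- drop(dffo)
  dffa <- dffo %*% t(params$ff_w2)        # 1 x Fh
  dffpre <- dffa * (ca$FFpre[n + 1L, ] > 0)
  x2_row <- ca$ln2$y[n + 1L, ]
  g$ff_w1 <- outer(x2_row, drop(dffpre))
  g$ff_b1 <- drop(dffpre)
  dx2 <- dffpre %*% t(params$ff_w1)       # 1 x E

  ln2_row <- list(xhat = ca$ln2$xhat[n + 1L, , drop = FALSE],
                  inv = ca$ln2$inv[n + 1L])
  bw2 <- layer_norm_bwd(dx2, ln2_row, params$ln2_g)
  g$ln2_g <- bw2$dgamma; g$ln2_b <- bw2$dbeta

  dH1_row <- dcls_out + bw2$dx            # residual + LN2 path, 1 x E

  # attention block
  dX1 <- matrix(0, n + 1L, E)
  g$w_q <- matrix(0, E, E); g$w_k <- matrix(0, E, E); g$w_v <- matrix(0, E, E)
  for (h in seq_len(H)) {
    idx <- ((h - 1L) * dh + 1L):(h * dh)
    hd <- ca$heads[[h]]
    do_h <- dH1_row[, idx, drop = FALSE]              # 1 x dh, grad at O cls row

    # second stage (broadcast): O = S2 VA
    dS2r <- do_h %*% t(hd$VA)                         # 1 x k
    dVA <- outer(hd$S2[n + 1L, ], drop(do_h))         # k x dh
    dZ2r <- softmax_bwd_row(hd$S2[n + 1L, ], drop(dS2r))
    dQ_row <- matrix(dZ2r, 1L) %*% hd$A / sq          # 1 x dh
    dA <- outer(dZ2r, hd$Q[n + 1L, ]) / sq            # k x dh

    # first stage (aggregation): VA = S1 V
    dS1 <- dVA %*% t(hd$V)                            # k x (n+1)
    dV <- t(hd$S1) %*% dVA                            # (n+1) x dh
    dZ1 <- softmax_bwd(hd$S1, dS1)
    dA <- dA + dZ1 %*% hd$K / sq
    dK <- t(dZ1) %*% hd$A / sq                        # (n+1) x dh

    # agents: pooled from Q unless fixed
    if (ca$fixed_agents) {
      dQ <- matrix(0, n + 1L, dh)
    } else {
      dQ <- t(ca$Pmat) %*% dA
    }
    dQ[n + 1L, ] <- dQ[n + 1L, ] + drop(dQ_row)

    g$w_q[, idx] <- crossprod(ca$X1, dQ)
    g$w_k[, idx] <- crossprod(ca$X1, dK)
    g$w_v[, idx] <- crossprod(ca$X1, dV)
    dX1 <- dX1 + tcrossprod(dQ, params$w_q[, idx, drop = FALSE]) +
                 tcrossprod(dK, params$w_k[, idx, drop = FALSE]) +
                 tcrossprod(dV, params$w_v[, idx, drop = FALSE])
  }

  bw1 <- layer_norm_bwd(dX1, ca$ln1, params$ln1_g)
  g$ln1_g <- bw1$dgamma; g$ln1_b <- bw1$dbeta
  dX <- bw1$dx
  dX[n + 1L, ] <- dX[n + 1L, ] + drop(dH1_row)        # residual H1 = X + O

  g$cls <- dX[n + 1L, , drop = FALSE]
  dPr <- dX[seq_len(n), , drop = FALSE] * (ca$Ppre > 0)
  g$w_in <- crossprod(ca$feat, dPr)
  g$b_in <- colSums(dPr)

  g[names(params)]
}

# Loss of a single bag given a forward result.
bag_loss <- function(prob, label, config) {
  ind <- as.numeric(label > 0.5)
  (config$lambda1 + config$lambda2 * ind) * (label - prob)^2
}
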