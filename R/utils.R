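# Internal numerics shared across modules.

# Row-wise softmax with max-subtraction for overflow safety.
row_softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Layer normalization over channels (per row), eps inside the sqrt.
# Returns the output plus the quantities the backward pass needs.
layer_norm_fwd <- function(x, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- sweep(xhat, 2L, gamma, "*")
  y <- sweep(y, 2L, beta, "+")
  list(y = y, xhat = xhat, inv = inv)
}

layer_norm_bwd <- function(dy, cache, gamma) {
  xhat <- cache$xhat
  dxhat <- sweep(dy, 2L, gamma, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- cache$inv * (dxhat - m1 - xhat * m2)
  list(dx = dx,
       dgamma = colSums(dy * xhat),
       dbeta = colSums(dy))
}

# Snap doubles to the nearest float32-representable value (the on-disk
# precision of the HDF5 bag layout).
as_float32 <- function(x) {
  v <- readBin(writeBin(as.vector(as.numeric(x)), raw(), size = 4L),
               "numeric", n = length(x), size = 4L)
  if (is.matrix(x)) matrix(v, nrow(x), ncol(x)) else v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(..., call. = FALSE)
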