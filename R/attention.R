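#' Scaled softmax attention
#'
#' The standard dot-product attention `softmax(Q K' / sqrt(d)) V`. Each row
#' of the implicit weight matrix is a softmax over keys, so rows sum to one.
#'
#' @param Q query matrix `n_q x d`.
#' @param K key matrix `n_k x d`.
#' @param V value matrix `n_k x d_v`.
#' @return `n_q x d_v` matrix of attended values.
#' @seealso [agent_attention()], [rollout_matrix()]
#' @export
softmax_attention <- function(Q, K, V) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (ncol(Q) != ncol(K))
    stop_invalid("Q and K must share the feature dimension d")
  if (nrow(K) != nrow(V))
    stop_invalid("K and V must have the same number of rows")
  W <- row_softmax(tcrossprod(Q, K) / sqrt(ncol(Q)))
  W %*% V
}

#' Pool agent tokens from the query sequence
#'
#' Agents are the means of `k` contiguous, near-equal segments of the query
#' rows (segment sizes differ by at most one, longer segments first).
#' `k = n` returns `Q` unchanged; `k = 1` returns the column mean.
#'
#' @param Q query matrix `n x d`.
#' @param k number of agent tokens, `1 <= k <= n`.
#' @return `k x d` agent matrix.
#' @export
make_agent_tokens <- function(Q, k) {
  Q <- as.matrix(Q)
  n <- nrow(Q)
  if (k < 1L || k > n)
    stop_invalid("k must satisfy 1 <= k <= n (got k=", k, ", n=", n, ")")
  P <- pooling_matrix(n, k)
  P %*% Q
}

# k x n segment-mean pooling operator; row j averages its segment of rows.
pooling_matrix <- function(n, k) {
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  P <- matrix(0, k, n)
  for (j in seq_len(k)) P[j, starts[j]:ends[j]] <- 1 / sizes[j]
  P
}

#' Agent attention
#'
#' Two stacked softmax attentions through `k` agent tokens: first the
#' aggregation `V_agent = SAttn(A, K, V)`, then the broadcast
#' `SAttn(Q, A, V_agent)`. This is an exact functional composition, linear
#' in the sequence length for fixed `k`.
#'
#' @param Q,K,V as in [softmax_attention()].
#' @param A agent matrix `k x d`.
#' @return `n x d_v` matrix.
#' @export
agent_attention <- function(Q, K, V, A) {
  A <- as.matrix(A)
  if (ncol(A) != ncol(Q))
    stop_invalid("A must share the feature dimension d with Q")
  softmax_attention(Q, A, softmax_attention(A, K, V))
}

#' Attention-rollout matrix of the agent mechanism
#'
#' The effective token-to-token attention `sigma(Q A'/sqrt(d)) x
#' sigma(A K'/sqrt(d))`. As a product of row-stochastic matrices it is
#' itself row-stochastic; its class-token row provides per-tile importance
#' scores for heatmaps.
#'
#' @param Q,K as in [softmax_attention()].
#' @param A agent matrix `k x d`.
#' @return `n x n` row-stochastic matrix.
#' @export
rollout_matrix <- function(Q, K, A) {
  Q <- as.matrix(Q); K <- as.matrix(K); A <- as.matrix(A)
  if (ncol(Q) != ncol(K) || ncol(Q) != ncol(A))
    stop_invalid("Q, K, A must share the feature dimension d")
  d <- ncol(Q)
  S2 <- row_softmax(tcrossprod(Q, A) / sqrt(d))
  S1 <- row_softmax(tcrossprod(A, K) / sqrt(d))
  S2 %*% S1
}

#' Multiply-accumulate counts of full versus agent attention
#'
#' Tallies the multiply-accumulate operations of every matrix product in one
#' attention pass: for full attention the similarity `Q K'` and the value
#' aggregation (`n^2 d` each, total `2 n^2 d`); for agent attention the two
#' stages `A K'`, `S1 V`, `Q A'`, `S2 V_agent` (`n k d` each, total
#' `2nkd + 2knd`). The ratio `2k/n` makes the linear-versus-quadratic
#' scaling explicit.
#'
#' @param n sequence length.
#' @param k number of agent tokens.
#' @param d feature dimension.
#' @return list with `full`, `agent`, and `ratio` (= agent/full).
#' @export
attention_mac_count <- function(n, k, d) {
  n <- as.numeric(n); k <- as.numeric(k); d <- as.numeric(d)
  full <- n * n * d +      # similarity Q K'
          n * n * d        # aggregation sigma(.) V
  agent <- k * n * d +     # stage 1 similarity A K'
           k * n * d +     # stage 1 aggregation S1 V
           n * k * d +     # stage 2 similarity Q A'
           n * k * d       # stage 2 aggregation S2 V_agent
  list(full = full, agent = agent, ratio = agent / full)
}
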