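# Small builders shared across test files. Oracles that check a specific
# operation live next to their tests; these are plumbing only.

tiny_config <- function(input_dim = 8L, embed_dim = 16L, n_heads = 2L,
                        ff_hidden_dim = 24L, n_agents = 3L, ...) {
  model_config(input_dim = input_dim, embed_dim = embed_dim,
               n_heads = n_heads, ff_hidden_dim = ff_hidden_dim,
               n_agents = n_agents, ...)
}

random_bag <- function(n = 5L, c = 8L, seed = 1L, label = 0.7) {
  set.seed(seed)
  side <- ceiling(sqrt(n))
  grid <- cbind(rep(seq_len(side) - 1L, side),
                rep(seq_len(side) - 1L, each = side))[seq_len(n), , drop = FALSE]
  tile_bag(matrix(rnorm(n * c), n, c), grid,
           slide_id = paste0("s", seed), patient_id = paste0("p", seed),
           label_normalized = label)
}

# Adjusted Rand index between two labelings.
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab)))
  sj <- sum(ch2(colSums(tab)))
  n2 <- ch2(sum(tab))
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}
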