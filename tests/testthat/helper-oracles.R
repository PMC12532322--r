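# Independent brute-force oracles, written directly from the loss and
# attention definitions as explicit sums. They share no code with the
# implementation under test.

oracle_nt_xent <- function(Z_a, Z_b, tau) {
  N <- nrow(Z_a)
  W <- rbind(Z_a, Z_b)
  sim <- function(i, j) {
    sum(W[i, ] * W[j, ]) /
      (tau * sqrt(sum(W[i, ]^2)) * sqrt(sum(W[j, ]^2)))
  }
  total <- 0
  for (m in seq_len(N)) {
    i <- m; p <- N + m
    den1 <- 0
    for (k in seq_len(2 * N)) if (k != i)
      den1 <- den1 + exp(sim(k, i)) + exp(sim(k, p))
    total <- total - log(exp(sim(i, p)) / den1)
    den2 <- 0
    for (k in seq_len(2 * N)) if (k != p)
      den2 <- den2 + exp(sim(k, p)) + exp(sim(k, i))
    total <- total - log(exp(sim(p, i)) / den2)
  }
  total / (2 * N)
}

oracle_attention <- function(Q, K, V, d, mask = NULL) {
  n <- nrow(Q); m <- nrow(K)
  H <- matrix(0, n, ncol(V))
  W <- matrix(0, n, m)
  for (i in seq_len(n)) {
    s <- numeric(m)
    for (j in seq_len(m)) {
      s[j] <- sum(Q[i, ] * K[j, ])
      if (!is.null(mask)) s[j] <- s[j] + mask[i, j]
      s[j] <- s[j] / sqrt(d)
    }
    w <- exp(s - max(s)); w <- w / sum(w)
    W[i, ] <- w
    for (j in seq_len(m)) H[i, ] <- H[i, ] + w[j] * V[j, ]
  }
  list(hidden = H, weights = W)
}

oracle_cross_entropy <- function(logits, labels) {
  tot <- 0
  for (i in seq_len(nrow(logits))) {
    p <- exp(logits[i, ]) / sum(exp(logits[i, ]))
    tot <- tot - log(p[labels[i]])
  }
  tot / nrow(logits)
}

# small toy dataset shared by unit tests (memoized)
.toy_cache <- new.env(parent = emptyenv())
toy_data <- function() {
  if (is.null(.toy_cache$d)) {
    sim <- generate_multiome(n_cells = 120, n_genes = 60, n_peaks = 120,
                             n_types = 3, lag_frac = 0.2, seed = 42)
    .toy_cache$d <- list(sim = sim, proc = preprocess_multiome(sim$dataset))
  }
  .toy_cache$d
}
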