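# Independent oracles used across tests.

# Brute-force topological overlap by the defining triple loop.
tom_brute_force <- function(A) {
  n <- nrow(A)
  out <- diag(n)
  k <- sapply(seq_len(n), function(i) sum(A[i, -i]))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + A[i, u] * A[u, j]
    out[i, j] <- (l + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
  }
  dimnames(out) <- dimnames(A)
  out
}

# Exhaustive hypergeometric upper tail: draw d of N items, K successes,
# probability of >= a successes, by enumerating all subsets.
hyper_tail_enumerate <- function(a, d, K, N) {
  draws <- utils::combn(N, d)
  mean(colSums(draws <= K) >= a)   # items 1..K are the successes
}

# random symmetric "adjacency" in [0,1] with unit diagonal
random_adjacency <- function(n) {
  A <- matrix(stats::runif(n * n), n, n)
  A <- (A + t(A)) / 2
  diag(A) <- 1
  A
}

# tiny labeled matrix builder
toy_matrix <- function(values, genes, samples = NULL) {
  m <- matrix(values, nrow = length(genes), byrow = TRUE)
  rownames(m) <- genes
  colnames(m) <- if (is.null(samples)) sprintf("S%d", seq_len(ncol(m))) else samples
  m
}
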