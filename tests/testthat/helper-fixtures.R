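# Small graph builders and brute-force oracles used across test files.

path_network <- function(symbols) {
  ppi_network(from = symbols[-length(symbols)], to = symbols[-1])
}

star_network <- function(hub, n_leaves) {
  ppi_network(from = rep(hub, n_leaves),
              to = sprintf("L%02d", seq_len(n_leaves)))
}

random_network <- function(n, p, seed) {
  set.seed(seed)
  syms <- sprintf("N%03d", seq_len(n))
  pairs <- t(combn(syms, 2))
  keep <- runif(nrow(pairs)) < p
  if (!any(keep)) keep[1] <- TRUE
  ppi_network(from = pairs[keep, 1], to = pairs[keep, 2], nodes = syms)
}

# Independent dense reference for the normalized adjacency.
dense_normalized <- function(net) {
  ord <- sort(net$nodes)
  n <- length(ord)
  A <- matrix(0, n, n, dimnames = list(ord, ord))
  for (i in seq_len(nrow(net$edges))) {
    A[net$edges$from[i], net$edges$to[i]] <- net$edges$weight[i]
    A[net$edges$to[i], net$edges$from[i]] <- net$edges$weight[i]
  }
  deg <- rowSums(A)
  W <- A
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (A[i, j] > 0) W[i, j] <- A[i, j] / sqrt(deg[i] * deg[j])
  }
  W
}

# All-pairs AUROC enumeration oracle.
brute_auroc <- function(scores, is_positive) {
  pos <- scores[is_positive]
  neg <- scores[!is_positive]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

random_seed_vector <- function(Wn, n_seeds, seed) {
  set.seed(seed)
  ss <- seed_set(sample(Wn$ordering, n_seeds))
  build_seed_vector(ss, Wn)
}
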