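# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths.

sigmoid_ref <- function(x) 1 / (1 + exp(-x))

# brute-force AUC: all positive/negative comparisons, half credit for ties
brute_force_auc <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (q in neg) {
    if (p > q) wins <- wins + 1
    else if (p == q) wins <- wins + 0.5
  }
  wins / (length(pos) * length(neg))
}

# breadth-first-search connected components over an adjacency matrix
bfs_component_sizes <- function(A) {
  m <- nrow(A)
  seen <- logical(m)
  sizes <- integer(0)
  for (s in seq_len(m)) {
    if (seen[s]) next
    queue <- s; seen[s] <- TRUE; size <- 0L
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]; size <- size + 1L
      nb <- which(A[v, ] != 0 & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    sizes <- c(sizes, size)
  }
  sizes
}

# truncated Neumann series sum_{k=0}^{K} alpha^k (-L)^k
rl_series <- function(L, alpha, K = 50L) {
  m <- nrow(L)
  acc <- diag(m)
  term <- diag(m)
  for (k in seq_len(K)) {
    term <- term %*% (-alpha * L)
    acc <- acc + term
  }
  acc
}

# random symmetric matrix with entries in (0, 1), zero-free
random_transition <- function(m) {
  M <- matrix(runif(m * m, 0.05, 0.95), m, m)
  (M + t(M)) / 2
}

# random symmetric "kernel" with node labels
random_kernel_matrix <- function(m, nodes = paste0("P", seq_len(m))) {
  K <- random_transition(m)
  dimnames(K) <- list(nodes, nodes)
  K
}

# random Erdos-Renyi-style binary adjacency with zero diagonal
random_adjacency <- function(m, p = 0.2, nodes = paste0("P", seq_len(m))) {
  A <- matrix(0, m, m, dimnames = list(nodes, nodes))
  up <- which(upper.tri(A))
  on <- up[runif(length(up)) < p]
  A[on] <- 1
  A <- A + t(A)
  A
}
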