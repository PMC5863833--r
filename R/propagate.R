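#' Build the transition matrix from the evolved matrix and training adjacency
#'
#' `T = sigmoid(EA' + EA + trainingAdj)`, elementwise.  `EA' + EA` is
#' symmetric and the training adjacency is symmetric, so `T` is symmetric by
#' construction.  Because `EA` entries lie in (0,1) and the adjacency in
#' \{0,1\}, the sigmoid argument lies in (0,3) and every entry of `T` falls
#' in (0.5, 0.953): the transition matrix is dense by design, which is what
#' lets diffusion reach across disconnected components.
#'
#' @param ea the evolved matrix EA from [train_enn()] (any `m x m` real
#'   matrix is accepted).
#' @param trainingAdj symmetric binary matrix of the same shape and node
#'   order.
#' @return a `transition_matrix` (symmetric real matrix, same dimnames).
#' @export
build_transition <- function(ea, trainingAdj) {
  EA <- as.matrix(ea); A <- as.matrix(trainingAdj)
  if (!all(dim(EA) == dim(A))) stop("shape mismatch between EA and adjacency")
  if (!is.null(rownames(EA)) && !is.null(rownames(A)) &&
      !identical(rownames(EA), rownames(A))) {
    stop("node order of EA and adjacency differ")
  }
  Tm <- sigmoid(t(EA) + EA + A)
  Tm <- (Tm + t(Tm)) / 2   # exact symmetry under floating point
  dimnames(Tm) <- dimnames(A)
  structure(Tm, class = c("transition_matrix", "matrix"))
}

#' Graph Laplacian of a weighted symmetric matrix
#'
#' `L = D - T` where `D` is the diagonal matrix of row sums of `T`.  Every
#' row of `L` sums to zero, and for symmetric nonnegative `T` the Laplacian
#' is positive semi-definite.
#'
#' @param T symmetric real matrix.
#' @return the Laplacian matrix.
#' @export
laplacian_matrix <- function(T) {
  T <- as.matrix(T)
  diag(rowSums(T)) - T
}

#' Spectral radius of a symmetric matrix by power iteration
#'
#' Rayleigh-quotient power iteration from a fixed deterministic start
#' vector, to relative tolerance `tol` with an iteration cap; if the
#' iteration does not converge (e.g. tied extreme eigenvalues) it falls
#' back to a dense symmetric eigendecomposition for `m <= 2000`.
#'
#' @param L symmetric matrix.
#' @param tol relative convergence tolerance on the eigenvalue estimate.
#' @param max_iter iteration cap.
#' @return the largest absolute eigenvalue (a nonnegative scalar).
#' @export
spectral_radius <- function(L, tol = 1e-8, max_iter = 10000L) {
  L <- as.matrix(L)
  m <- nrow(L)
  if (m == 0L || max(abs(L)) == 0) return(0)
  # deterministic start with mass on every coordinate, unlikely to be
  # orthogonal to the dominant eigenvector (all-ones is: L %*% 1 = 0)
  v <- sin(seq_len(m)) + 1e-3
  v <- v / sqrt(sum(v^2))
  lambda <- 0
  for (it in seq_len(max_iter)) {
    w <- L %*% v
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(0)  # v happened to be in the null space
    v <- as.vector(w) / nw
    new_lambda <- sum(v * (L %*% v))
    if (abs(new_lambda - lambda) <= tol * max(abs(new_lambda), 1e-300)) {
      return(abs(new_lambda))
    }
    lambda <- new_lambda
  }
  if (m <= 2000L) {
    return(max(abs(eigen(L, symmetric = TRUE, only.values = TRUE)$values)))
  }
  stop("power iteration did not converge and matrix too large for dense fallback")
}

rl_kernel <- function(Tm, alpha_fraction) {
  if (alpha_fraction <= 0 || alpha_fraction >= 1) {
    stop("alpha_fraction must lie strictly in (0, 1)")
  }
  Tm <- as.matrix(Tm)
  L <- laplacian_matrix(Tm)
  rho <- spectral_radius(L)
  if (rho == 0) {
    P <- diag(nrow(Tm))
    alpha <- 0
  } else {
    alpha <- alpha_fraction / rho
    P <- solve(diag(nrow(Tm)) + alpha * L)
    P <- (P + t(P)) / 2
  }
  dimnames(P) <- dimnames(Tm)
  structure(P, class = c("score_matrix", "matrix"),
            alpha_rl = alpha, alpha_fraction = alpha_fraction,
            spectral_radius_used = rho)
}

#' Regularized Laplacian kernel over a transition matrix
#'
#' Computes the inference matrix `P = (I + alpha * L)^{-1}` with
#' `L = D - T`, equal to the diffusion series `sum_k alpha^k (-L)^k`
#' whenever `alpha * rho(L) < 1`.  The kernel parameter is specified as a
#' fraction of the admissible range: `alpha = alpha_fraction / rho(L)`,
#' which guarantees convergence of the series for any input.  `P[i, j]`
#' scores the interaction between proteins `i` and `j`.
#'
#' @param T a symmetric `transition_matrix` (or any symmetric matrix).
#' @param alpha_fraction fraction in (0,1); default 0.5.
#' @return a `score_matrix` with attributes `alpha_rl` (the absolute alpha
#'   used), `alpha_fraction` and `spectral_radius_used`.
#' @export
regularized_laplacian <- function(T, alpha_fraction = 0.5) {
  rl_kernel(T, alpha_fraction)
}

#' Baseline: regularized Laplacian kernel on the raw training adjacency
#'
#' The control diffusion method ADJ-RL: identical to
#' [regularized_laplacian()] but with the binary training adjacency in
#' place of the learned transition matrix.  An edgeless network yields the
#' identity score matrix.
#'
#' @param trainingAdj symmetric binary adjacency matrix.
#' @inheritParams regularized_laplacian
#' @return a `score_matrix`.
#' @export
adj_rl_baseline <- function(trainingAdj, alpha_fraction = 0.5) {
  rl_kernel(trainingAdj, alpha_fraction)
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("score matrix: %d x %d, alpha %.4g (fraction %.2f), rho(L) %.4g\n",
              nrow(x), ncol(x), attr(x, "alpha_rl"),
              attr(x, "alpha_fraction"), attr(x, "spectral_radius_used")))
  invisible(x)
}

#' Run the full ENN-RL pipeline on a training network
#'
#' Composes [to_adjacency()], [train_enn()], [build_transition()] and
#' [regularized_laplacian()].  The evolved matrix and transition matrix are
#' attached to the result as attributes `ea` and `transition` so callers
#' can persist or reuse them (e.g. as the WOLP fitting target).
#'
#' @param net_train the training network `G_tn` (a `ppi_network` over the
#'   full node set).
#' @param config an [enn_config()].
#' @param alpha_fraction diffusion strength passed to
#'   [regularized_laplacian()].
#' @return a `score_matrix` with attributes `ea` and `transition`.
#' @export
run_ennrl <- function(net_train, config = enn_config(), alpha_fraction = 0.5) {
  A <- to_adjacency(net_train)
  EA <- train_enn(A, config)
  Tm <- build_transition(EA, A)
  P <- regularized_laplacian(Tm, alpha_fraction)
  attr(P, "ea") <- EA
  attr(P, "transition") <- Tm
  P
}
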