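#' Feature kernel constructor
#'
#' A feature kernel is a symmetric `m x m` similarity matrix over the
#' network's node order, carried as dimnames.
#'
#' @param values symmetric numeric matrix.
#' @param node_order character vector of protein identifiers.
#' @param name short kernel label.
#' @return object of class `feature_kernel`.
#' @export
feature_kernel <- function(values, node_order = rownames(values),
                           name = "kernel") {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("kernel must be square")
  if (is.null(node_order)) stop("kernel requires a node order")
  dimnames(values) <- list(node_order, node_order)
  structure(values, class = c("feature_kernel", "matrix"), name = name)
}

#' @export
print.feature_kernel <- function(x, ...) {
  cat(sprintf("feature kernel '%s': %d x %d, range [%.3g, %.3g]\n",
              attr(x, "name"), nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' Jaccard neighbourhood-similarity kernel
#'
#' Entry `(i, j)` is `|N(i) intersect N(j)| / |N(i) union N(j)|` computed on
#' the training network only, 0 when both neighbourhoods are empty.  The
#' diagonal is 1 for nodes with at least one neighbour and 0 for isolated
#' nodes.
#'
#' @param net a `ppi_network` (the training network; held-out edges must
#'   never leak into topology features).
#' @return a `feature_kernel` with entries in \[0, 1\].
#' @export
jaccard_kernel <- function(net) {
  A <- to_adjacency(net)
  deg <- rowSums(A)
  common <- A %*% A                       # |N(i) intersect N(j)|
  union_ <- outer(deg, deg, `+`) - common
  K <- ifelse(union_ > 0, common / union_, 0)
  diag(K) <- as.numeric(deg > 0)
  feature_kernel(K, net$nodes, "Jaccard")
}

#' Shared-neighbours (degree-sum) kernel
#'
#' Raw entry `(i, j)` is `degree(i) + degree(j)` on the training network;
#' the returned kernel is min-max normalised to \[0, 1\] (see
#' [normalize_kernel()]).
#'
#' @inheritParams jaccard_kernel
#' @return a normalised `feature_kernel`.
#' @export
shared_neighbors_kernel <- function(net) {
  A <- to_adjacency(net)
  deg <- rowSums(A)
  K <- feature_kernel(outer(deg, deg, `+`), net$nodes, "SN")
  normalize_kernel(K)
}

#' Min-max normalise a kernel to \[0, 1\]
#'
#' `(K - min) / (max - min)` over all entries, so heterogeneous kernels on
#' very different scales do not bias the weighted fusion.  A constant
#' matrix maps to all zeros (by convention, to avoid division by zero).
#'
#' @param K a `feature_kernel` (or plain matrix) with finite entries.
#' @return a `feature_kernel` with entries in \[0, 1\].
#' @export
normalize_kernel <- function(K) {
  v <- as.matrix(K)
  if (!all(is.finite(v))) stop("kernel has non-finite entries")
  rng <- range(v)
  v <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else v * 0
  feature_kernel(v, rownames(v),
                 if (inherits(K, "feature_kernel")) attr(K, "name") else "kernel")
}

#' Load a precomputed kernel matrix from a tab-separated file
#'
#' Expected format (same as [save_kernel_matrix()] writes): first row and
#' first column are protein identifiers, dense tab-separated values.
#' Rows/columns are reordered to the supplied node order; an identifier
#' missing from the file is an error.  Small numeric asymmetry (at most
#' `1e-6`) is repaired by averaging with the transpose; larger asymmetry is
#' an error.
#'
#' @param path file path.
#' @param node_order protein identifiers defining the target order.
#' @param name kernel label; defaults to the file name.
#' @return a `feature_kernel`.
#' @export
load_kernel_matrix <- function(path, node_order,
                               name = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) stop("kernel file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                          check.names = FALSE)
  M <- as.matrix(df)
  if (nrow(M) != ncol(M)) stop("kernel file is not a square matrix: ", path)
  missing <- setdiff(node_order, rownames(M))
  if (length(missing) > 0L) {
    stop("kernel file ", path, " is missing node(s): ",
         paste(missing, collapse = ", "))
  }
  M <- M[node_order, node_order]
  asym <- max(abs(M - t(M)))
  if (asym > 1e-6) stop("kernel file grossly asymmetric (max |K - K'| = ",
                        format(asym), "): ", path)
  M <- (M + t(M)) / 2
  feature_kernel(M, node_order, name)
}

#' Save a kernel (or any node-labelled matrix) as tab-separated text
#'
#' @param K matrix with node identifiers as dimnames.
#' @param path output path.
#' @export
save_kernel_matrix <- function(K, path) {
  utils::write.table(as.matrix(K), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' Fuse the training adjacency with feature kernels by weighted sum
#'
#' Computes `W0 * G_tn + sum_i Wi * Ki`.  Equal-weight fusion (the EW
#' baseline) sets every weight to `1 / (n + 1)` where `n` is the number of
#' kernels.
#'
#' @param gtn_adj adjacency matrix of the training network.
#' @param kernels list of `feature_kernel`s on the same node order.
#' @param weights a `kernel_weights` object from [optimize_weights()], a
#'   numeric vector `c(w0, w1, ..., wn)`, or `"equal"`.
#' @return a `feature_kernel` named `"fusion"`.
#' @export
fuse_kernels <- function(gtn_adj, kernels, weights = "equal") {
  A <- as.matrix(gtn_adj)
  mats <- c(list(A), lapply(kernels, as.matrix))
  if (identical(weights, "equal")) {
    w <- rep(1 / length(mats), length(mats))
  } else if (inherits(weights, "kernel_weights")) {
    w <- c(weights$w0, weights$w)
  } else {
    w <- as.numeric(weights)
  }
  if (length(w) != length(mats)) {
    stop("need ", length(mats), " weights (w0 plus one per kernel), got ",
         length(w))
  }
  fused <- Reduce(`+`, Map(`*`, w, mats))
  feature_kernel(fused, rownames(A), "fusion")
}

#' Fit nonnegative fusion weights against a target transition matrix (WOLP)
#'
#' Finds `W >= 0` minimising the squared Frobenius norm
#' `|| W0 * G_tn + sum_i Wi * Ki - T ||^2`, i.e. the elementwise difference
#' between the weighted kernel combination and the target transition
#' matrix.  Solved as a nonnegative least-squares problem over the
#' vectorised matrices (Lawson-Hanson active set).
#'
#' @param gtn_adj adjacency matrix of the training network `G_tn`.
#' @param kernels list of `feature_kernel`s (at least one, none all-zero).
#' @param target the target transition matrix, typically the one learned by
#'   [run_ennrl()] (attribute `"transition"`).
#' @return object of class `kernel_weights`: list with `w0`, `w` (one per
#'   kernel, named), and `residual` (achieved squared Frobenius distance).
#' @export
optimize_weights <- function(gtn_adj, kernels, target) {
  A <- as.matrix(gtn_adj)
  if (length(kernels) < 1L) stop("need at least one feature kernel")
  mats <- c(list(A), lapply(kernels, as.matrix))
  if (any(vapply(mats, function(M) all(M == 0), logical(1L)))) {
    stop("degenerate all-zero kernel in the fusion basis")
  }
  tgt <- as.matrix(target)
  if (!all(dim(tgt) == dim(A))) stop("target shape mismatch")
  C <- vapply(mats, as.vector, numeric(length(A)))
  fit <- pracma::lsqnonneg(C, as.vector(tgt))
  w <- fit$x
  resid <- sum((C %*% w - as.vector(tgt))^2)
  knames <- vapply(seq_along(kernels), function(i) {
    nm <- attr(kernels[[i]], "name")
    if (is.null(nm)) paste0("K", i) else nm
  }, character(1L))
  structure(list(w0 = w[1L], w = stats::setNames(w[-1L], knames),
                 residual = resid),
            class = "kernel_weights")
}

#' @export
print.kernel_weights <- function(x, ...) {
  cat(sprintf("kernel weights: w0 (G_tn) = %.4g; %s; residual %.4g\n",
              x$w0,
              paste(sprintf("%s = %.4g", names(x$w), x$w), collapse = "; "),
              x$residual))
  invisible(x)
}
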