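#' Rank-based AUC of positive versus negative scores
#'
#' Probability that a uniformly chosen positive outscores a uniformly
#' chosen negative, with ties counted as half credit (the Wilcoxon
#' Mann-Whitney statistic).
#'
#' @param pos_scores numeric scores of true positives.
#' @param neg_scores numeric scores of negatives.
#' @return AUC in \[0, 1\].
#' @export
rank_auc <- function(pos_scores, neg_scores) {
  n_pos <- length(pos_scores); n_neg <- length(neg_scores)
  if (n_pos == 0L || n_neg == 0L) stop("need at least one positive and one negative")
  r <- rank(c(pos_scores, neg_scores))
  (sum(r[seq_len(n_pos)]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# ROC curve points with tied scores grouped, so the trapezoidal area
# equals the rank AUC exactly
roc_points <- function(pos_scores, neg_scores) {
  scores <- c(pos_scores, neg_scores)
  is_pos <- rep(c(TRUE, FALSE), c(length(pos_scores), length(neg_scores)))
  o <- order(scores, decreasing = TRUE)
  scores <- scores[o]; is_pos <- is_pos[o]
  grp_end <- which(!duplicated(scores, fromLast = TRUE))  # last index per tie group
  tp <- cumsum(is_pos)[grp_end]
  fp <- cumsum(!is_pos)[grp_end]
  data.frame(fpr = c(0, fp / length(neg_scores)),
             tpr = c(0, tp / length(pos_scores)))
}

# logical m x m matrix marking the unordered pairs in `edges` (i < j)
pair_mask <- function(edges, m) {
  mask <- matrix(FALSE, m, m)
  if (NROW(edges) > 0L) mask[edges] <- TRUE
  mask
}

#' ROC/AUC evaluation of a score matrix against held-out test edges
#'
#' Positives are the held-out test edges; candidate negatives are all
#' unordered non-self pairs absent from the golden standard (neither
#' training nor test edges).  With `negative_policy = "sampled"`,
#' `neg_ratio * n_pos` negatives are drawn without replacement under the
#' seed.  Scores are read from the upper triangle of the (symmetric) score
#' matrix.  AUC is the rank-based Wilcoxon statistic with half-credit
#' ties, and equals the trapezoidal area under the returned curve.
#'
#' @param P a `score_matrix` (node order must match the split).
#' @param split an `edge_split` from [split_golden_standard()].
#' @param negative_policy `"all"` (default) or `"sampled"`.
#' @param neg_ratio negatives per positive under the sampled policy.
#' @param seed seed for negative sampling.
#' @return object of class `roc_result`: list with `auc`, `curve`
#'   (data frame of fpr/tpr), `n_pos`, `n_neg`, `negative_policy`, `seed`.
#' @export
roc_auc <- function(P, split, negative_policy = c("all", "sampled"),
                    neg_ratio = 10L, seed = 1L) {
  negative_policy <- match.arg(negative_policy)
  P <- as.matrix(P)
  m <- nrow(P)
  if (!is.null(rownames(P)) &&
      !identical(rownames(P), split$training$nodes)) {
    stop("node order of score matrix and split differ")
  }
  test_edges <- split$test_edges
  if (NROW(test_edges) == 0L) stop("split has no test edges")
  known <- pair_mask(rbind(split$training$edges, test_edges), m)
  neg_idx <- which(upper.tri(P) & !known, arr.ind = TRUE)
  n_pos <- nrow(test_edges)
  if (negative_policy == "sampled") {
    if (neg_ratio < 1L) stop("neg_ratio must be >= 1")
    n_draw <- min(nrow(neg_idx), neg_ratio * n_pos)
    sel <- with_seed(seed, sample.int(nrow(neg_idx), n_draw))
    neg_idx <- neg_idx[sel, , drop = FALSE]
  }
  pos_scores <- P[test_edges]
  neg_scores <- P[neg_idx]
  structure(
    list(auc = rank_auc(pos_scores, neg_scores),
         curve = roc_points(pos_scores, neg_scores),
         n_pos = n_pos, n_neg = length(neg_scores),
         negative_policy = negative_policy, seed = as.integer(seed)),
    class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.4f (%d positives, %d negatives, policy %s)\n",
              x$auc, x$n_pos, x$n_neg, x$negative_policy))
  invisible(x)
}

#' Component reconnection curve
#'
#' All unordered non-self pairs except training edges are ranked by score
#' (descending; ties broken by node-index pair order for reproducibility).
#' For each top fraction `rho`, the predicted positives `G_pp` are the top
#' `floor(rho * N)` pairs, the predicted true positives `G_ptp` their
#' intersection with the held-out test edges, and the curve reports the
#' number of connected components of the training network after adding
#' `G_ptp` back.  Recovered-edge sets grow with `rho`, so the counts are
#' non-increasing; at `rho = 1` every test edge is recovered and the count
#' equals `components(G_tn union G_tt)`.
#'
#' @param P a `score_matrix`.
#' @param split an `edge_split`.
#' @param rho_values strictly increasing fractions in (0, 1\].
#' @return object of class `reconnection_curve`: list with `rho_values`,
#'   `component_counts`, `n_recovered` (size of `G_ptp` per rho), and
#'   `baseline_components` (components of `G_tn`).
#' @export
reconnection_curve <- function(P, split,
                               rho_values = c(0.0005, 0.001, 0.002, 0.005,
                                              0.01, 0.02, 0.05, 0.1, 0.2,
                                              0.5, 1)) {
  if (length(rho_values) == 0L) stop("empty rho grid")
  if (any(rho_values <= 0) || any(rho_values > 1) ||
      any(diff(rho_values) <= 0)) {
    stop("rho_values must be strictly increasing fractions in (0, 1]")
  }
  P <- as.matrix(P)
  m <- nrow(P)
  train_net <- split$training
  train_mask <- pair_mask(train_net$edges, m)
  cand <- which(upper.tri(P) & !train_mask, arr.ind = TRUE)
  scores <- P[cand]
  o <- order(-scores, cand[, 1L], cand[, 2L])
  cand <- cand[o, , drop = FALSE]
  is_test <- pair_mask(split$test_edges, m)[cand]
  N <- nrow(cand)
  counts <- integer(length(rho_values))
  recovered <- integer(length(rho_values))
  for (k in seq_along(rho_values)) {
    top <- floor(rho_values[k] * N)
    hit <- which(is_test[seq_len(top)])
    recovered[k] <- length(hit)
    aug <- ppi_network(train_net$nodes,
                       rbind(train_net$edges, cand[hit, , drop = FALSE]))
    counts[k] <- component_summary(aug)$count
  }
  structure(
    list(rho_values = rho_values, component_counts = counts,
         n_recovered = recovered,
         baseline_components = component_summary(train_net)$count),
    class = "reconnection_curve")
}

#' @export
print.reconnection_curve <- function(x, ...) {
  cat("component reconnection (baseline", x$baseline_components, "components):\n")
  print(data.frame(rho = x$rho_values, components = x$component_counts,
                   recovered_edges = x$n_recovered), row.names = FALSE)
  invisible(x)
}

score_one_method <- function(method, split, enn_cfg, alpha_fraction,
                             kernels, ennrl_cache) {
  A <- to_adjacency(split$training)
  switch(method,
    adjrl = adj_rl_baseline(A, alpha_fraction),
    ennrl = ennrl_cache$P,
    ewrl = {
      ks <- if (is.null(kernels)) default_topology_kernels(split$training) else kernels
      regularized_laplacian(fuse_kernels(A, ks, "equal"), alpha_fraction)
    },
    ennlp = {
      ks <- if (is.null(kernels)) default_topology_kernels(split$training) else kernels
      w <- optimize_weights(A, ks, attr(ennrl_cache$P, "transition"))
      regularized_laplacian(fuse_kernels(A, ks, w), alpha_fraction)
    },
    stop("unknown method: ", method))
}

default_topology_kernels <- function(net) {
  list(jaccard_kernel(net), shared_neighbors_kernel(net))
}

#' Repeated split-and-evaluate benchmark
#'
#' For each repeat `r`, the golden standard network is re-split with seed
#' `base_seed + r`, every requested method is run on the same split, and
#' the AUC is evaluated on the held-out edges.  Methods: `"ennrl"`
#' (evolution network + diffusion), `"adjrl"` (diffusion on the raw
#' training adjacency), `"ewrl"` (equal-weight kernel fusion + diffusion)
#' and `"ennlp"` (fusion with WOLP weights fitted to the learned transition
#' matrix).  When no kernel list is supplied, the fusion methods use the
#' Jaccard and shared-neighbours kernels computed from each repeat's
#' training network.
#'
#' @param net golden standard `ppi_network`.
#' @param ratio_cap training-fraction cap for [split_golden_standard()].
#' @param methods character vector of method names.
#' @param n_repeats number of repeats (>= 2).
#' @param base_seed integer; repeat `r` uses seed `base_seed + r` for the
#'   split and for the network training.
#' @param config an [enn_config()] template (its seed is replaced per
#'   repeat).
#' @param alpha_fraction diffusion strength.
#' @param kernels optional list of precomputed `feature_kernel`s for the
#'   fusion methods.
#' @param negative_policy,neg_ratio passed to [roc_auc()].
#' @return data frame with one row per method: `method`, `ratio_cap`,
#'   `mean_auc`, `sd_auc` (sample standard deviation), `n_repeats`; the
#'   per-repeat AUC matrix is attached as attribute `"auc"`.
#' @export
repeat_benchmark <- function(net, ratio_cap,
                             methods = c("ennrl", "adjrl"),
                             n_repeats = 10L, base_seed = 0L,
                             config = enn_config(), alpha_fraction = 0.5,
                             kernels = NULL,
                             negative_policy = "all", neg_ratio = 10L) {
  if (n_repeats < 2L) stop("n_repeats must be >= 2")
  bad <- setdiff(methods, c("ennrl", "adjrl", "ewrl", "ennlp"))
  if (length(bad) > 0L) stop("unknown method name: ", paste(bad, collapse = ", "))
  aucs <- matrix(NA_real_, n_repeats, length(methods),
                 dimnames = list(NULL, methods))
  for (r in seq_len(n_repeats)) {
    seed_r <- base_seed + r
    split <- split_golden_standard(net, ratio_cap, seed = seed_r)
    ennrl_cache <- NULL
    if (any(c("ennrl", "ennlp") %in% methods)) {
      cfg <- config; cfg$seed <- as.integer(seed_r)
      ennrl_cache <- list(P = run_ennrl(split$training, cfg, alpha_fraction))
    }
    for (meth in methods) {
      P <- score_one_method(meth, split, config, alpha_fraction,
                            kernels, ennrl_cache)
      aucs[r, meth] <- roc_auc(P, split, negative_policy,
                               neg_ratio = neg_ratio, seed = seed_r)$auc
    }
  }
  out <- data.frame(method = methods, ratio_cap = ratio_cap,
                    mean_auc = colMeans(aucs),
                    sd_auc = apply(aucs, 2L, stats::sd),
                    n_repeats = n_repeats, row.names = NULL)
  attr(out, "auc") <- aucs
  out
}
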