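test_that("Jaccard kernel matches set arithmetic", {
  # neighbours(i) = {a,b,c}, neighbours(j) = {b,c,d}: 2 shared of 4 total
  net <- ppi_network(c("i", "j", "a", "b", "c", "d"),
                     rbind(c("i","a"), c("i","b"), c("i","c"),
                           c("j","b"), c("j","c"), c("j","d")))
  K <- jaccard_kernel(net)
  expect_equal(K["i", "j"], 0.5)
  # identical nonempty neighbourhoods -> 1; here a and d share {i}/{j}? no:
  # b and c both neighbour {i, j}: identical neighbourhoods
  expect_equal(K["b", "c"], 1)
  expect_equal(K["b", "b"], 1)
  expect_lt(max(abs(K - t(K))), 1e-12)

  # disjoint neighbourhoods -> 0; isolated node diagonal -> 0
  net2 <- ppi_network(c("a", "b", "c", "d", "e"),
                      rbind(c("a","b"), c("c","d")))
  K2 <- jaccard_kernel(net2)
  expect_equal(K2["a", "c"], 0)
  expect_equal(K2["e", "e"], 0)
})

test_that("shared-neighbours kernel is the normalised degree sum", {
  net <- ppi_network(c("a", "b", "c", "d"),
                     rbind(c("a","b"), c("a","c"), c("b","c"), c("b","d")))
  # degrees: a=2, b=3, c=2, d=1; raw entries span [2, 6]
  K <- shared_neighbors_kernel(net)
  expect_equal(max(K), 1)
  expect_equal(K["a", "c"], (4 - 2) / 4)  # (deg sum - min) / (max - min)
  expect_equal(K["b", "b"], 1)            # 3 + 3 = raw max
})

test_that("min-max normalisation is idempotent and handles constants", {
  set.seed(3)
  K <- feature_kernel(random_kernel_matrix(10) * 4 + 2, name = "raw")
  K1 <- normalize_kernel(K)
  expect_equal(range(K1), c(0, 1))
  expect_equal(unclass(normalize_kernel(K1)), unclass(K1))
  # affine map: (K - min) / (max - min)
  expect_equal(unclass(K1), (unclass(K) - min(K)) / (max(K) - min(K)))

  const <- feature_kernel(matrix(7, 4, 4, dimnames = rep(list(letters[1:4]), 2)))
  expect_equal(unclass(normalize_kernel(const)), matrix(0, 4, 4),
               ignore_attr = TRUE)
  bad <- feature_kernel(matrix(c(1, Inf, Inf, 1), 2, 2,
                               dimnames = rep(list(c("a","b")), 2)))
  expect_error(normalize_kernel(bad), "finite")
})

test_that("kernel matrices round-trip through files, tolerate permutation", {
  set.seed(9)
  nodes <- paste0("P", 1:8)
  K <- random_kernel_matrix(8, nodes)
  f <- withr::local_tempfile(fileext = ".tsv")
  save_kernel_matrix(K, f)
  back <- load_kernel_matrix(f, nodes)
  expect_equal(unclass(back), K, tolerance = 1e-12, ignore_attr = TRUE)

  # permuted rows/columns on disk are reordered to node_order
  perm <- sample(nodes)
  save_kernel_matrix(K[perm, perm], f)
  back2 <- load_kernel_matrix(f, nodes)
  expect_equal(unclass(back2), K, tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(load_kernel_matrix(f, c(nodes, "UNKNOWN_ID")), "UNKNOWN_ID")

  asym <- K; asym[1, 2] <- asym[1, 2] + 0.5
  save_kernel_matrix(asym, f)
  expect_error(load_kernel_matrix(f, nodes), "asymmetric")
})

test_that("kernel fusion is the stated weighted sum and is linear", {
  set.seed(4)
  nodes <- paste0("P", 1:6)
  A <- random_adjacency(6, 0.4, nodes)
  K1 <- feature_kernel(random_kernel_matrix(6, nodes), name = "K1")
  K2 <- feature_kernel(random_kernel_matrix(6, nodes), name = "K2")

  expect_equal(unclass(fuse_kernels(A, list(K1, K2), c(1, 0, 0))), A,
               ignore_attr = TRUE)
  expect_equal(unclass(fuse_kernels(A, list(K1, K1), c(0, 0.5, 0.5))),
               unclass(K1), ignore_attr = TRUE)
  eq <- fuse_kernels(A, list(K1, K2), "equal")
  expect_equal(unclass(eq), (A + unclass(K1) + unclass(K2)) / 3,
               ignore_attr = TRUE)
  # fusion linearity in the weights
  w <- c(0.2, 0.5, 0.3)
  expect_equal(unclass(fuse_kernels(A, list(K1, K2), 3 * w)),
               3 * unclass(fuse_kernels(A, list(K1, K2), w)),
               ignore_attr = TRUE)
  expect_error(fuse_kernels(A, list(K1, K2), c(1, 0)), "weights")
})

test_that("weight optimisation recovers planted nonnegative mixtures", {
  set.seed(6)
  nodes <- paste0("P", 1:10)
  A <- random_adjacency(10, 0.3, nodes)
  K1 <- feature_kernel(random_kernel_matrix(10, nodes), name = "K1")
  K2 <- feature_kernel(random_kernel_matrix(10, nodes), name = "K2")
  target <- 0.3 * A + 0.7 * unclass(K1) + 0 * unclass(K2)
  w <- optimize_weights(A, list(K1, K2), target)
  expect_equal(unname(c(w$w0, w$w)), c(0.3, 0.7, 0), tolerance = 1e-6)
  expect_lt(w$residual, 1e-8)

  w2 <- optimize_weights(A, list(K1, K2), A)
  expect_equal(unname(c(w2$w0, w2$w)), c(1, 0, 0), tolerance = 1e-6)

  zero <- feature_kernel(matrix(0, 10, 10, dimnames = list(nodes, nodes)))
  expect_error(optimize_weights(A, list(zero), target), "all-zero")
})

test_that("NNLS residual matches a dense grid-search oracle", {
  set.seed(15)
  nodes <- paste0("P", 1:6)
  A <- random_adjacency(6, 0.4, nodes)
  K1 <- feature_kernel(random_kernel_matrix(6, nodes), name = "K1")
  K2 <- feature_kernel(random_kernel_matrix(6, nodes), name = "K2")
  target <- random_kernel_matrix(6, nodes)  # not representable in general
  fit <- optimize_weights(A, list(K1, K2), target)

  # vectorised grid search over (w0, w1, w2) in [0, 1.5] step 0.01
  C <- cbind(as.vector(A), as.vector(unclass(K1)), as.vector(unclass(K2)))
  t_vec <- as.vector(target)
  G <- crossprod(C); b <- crossprod(C, t_vec); tt <- sum(t_vec^2)
  grid <- seq(0, 1.5, by = 0.01)
  W <- as.matrix(expand.grid(grid, grid, grid))
  res <- rowSums((W %*% G) * W) - 2 * (W %*% b) + tt
  expect_lt(abs(fit$residual - min(res)), 1e-3)
  expect_lte(fit$residual, min(res) + 1e-9)
})

test_that("planted-weight recovery holds across sizes and kernel counts", {
  set.seed(30)
  for (i in 1:5) {
    m <- sample(8:30, 1)
    nk <- sample(2:5, 1)
    nodes <- paste0("P", seq_len(m))
    A <- random_adjacency(m, 0.3, nodes)
    ks <- lapply(seq_len(nk), function(j)
      feature_kernel(random_kernel_matrix(m, nodes), name = paste0("K", j)))
    true_w <- round(runif(nk + 1, 0, 1), 3)
    target <- Reduce(`+`, Map(`*`, true_w,
                              c(list(A), lapply(ks, unclass))))
    fit <- optimize_weights(A, ks, target)
    expect_equal(unname(c(fit$w0, fit$w)), true_w, tolerance = 1e-5)
    expect_lt(fit$residual, 1e-8)
  }
})
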