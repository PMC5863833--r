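test_that("edge-list reading drops self-pairs and duplicate orientations", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "b\ta", "a\ta"), f)
  net <- read_edge_list(f)
  expect_equal(net$nodes, c("a", "b"))
  expect_equal(nrow(net$edges), 1L)

  writeLines(c("# comment", "a\tb", "", "b\tc"), f)
  net <- read_edge_list(f)
  expect_equal(n_nodes(net), 3L)
  expect_equal(n_edges(net), 2L)
  expect_equal(net$nodes, c("a", "b", "c"))
})

test_that("edge-list parse errors name the offending line", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "lonely"), f)
  expect_error(read_edge_list(f), "line 2")
  expect_error(read_edge_list(file.path(tempdir(), "no_such_file.tsv")),
               "not found")
})

test_that("edge list round-trips through write and read", {
  # an edge list carries exactly the edge set; isolated nodes are not
  # representable in the format, so the round trip preserves edges
  net <- generate_synthetic_ppi(40, seed = 5)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, f)
  back <- read_edge_list(f)
  to_ids <- function(x) {
    p <- cbind(x$nodes[x$edges[, 1]], x$nodes[x$edges[, 2]])
    sort(paste(pmin(p[, 1], p[, 2]), pmax(p[, 1], p[, 2])))
  }
  expect_identical(to_ids(back), to_ids(net))
  expect_identical(sort(back$nodes),
                   sort(unique(c(net$nodes[net$edges]))))
})

test_that("adjacency matrix is symmetric, binary, zero-diagonal", {
  net <- ppi_network(c("a", "b", "c"))
  expect_equal(to_adjacency(net), matrix(0, 3, 3,
               dimnames = list(c("a","b","c"), c("a","b","c"))))

  net <- ppi_network(c("a", "b"), cbind("a", "b"))
  expect_equal(unname(to_adjacency(net)), matrix(c(0, 1, 1, 0), 2, 2))

  path3 <- ppi_network(c("a", "b", "c"), rbind(c("a","b"), c("b","c")))
  expect_equal(unname(rowSums(to_adjacency(path3))), c(1, 2, 1))
})

test_that("adjacency round-trip reproduces the edge set exactly", {
  for (seed in 1:5) {
    set.seed(seed)
    net <- generate_synthetic_ppi(30, 0.5, 0.2, seed = seed)
    back <- from_adjacency(to_adjacency(net))
    expect_identical(back$edges, net$edges)
    expect_identical(back$nodes, net$nodes)
  }
})

test_that("component summary counts isolated nodes as components", {
  net <- ppi_network(paste0("n", 1:5))
  cs <- component_summary(net)
  expect_equal(cs$count, 5L)
  expect_equal(c(cs$min_size, cs$mean_size, cs$max_size), c(1, 1, 1))

  # path of 3 plus isolated node
  net <- ppi_network(c("a", "b", "c", "d"), rbind(c("a","b"), c("b","c")))
  cs <- component_summary(net)
  expect_equal(cs$count, 2L)
  expect_equal(c(cs$min_size, cs$mean_size, cs$max_size), c(1, 2, 3))

  expect_error(component_summary(ppi_network(character(0))), "empty")
})

test_that("component summary agrees with a BFS oracle on random graphs", {
  set.seed(42)
  for (i in 1:10) {
    m <- sample(5:50, 1)
    A <- random_adjacency(m, p = runif(1, 0.02, 0.3))
    net <- from_adjacency(A)
    cs <- component_summary(net)
    sizes <- bfs_component_sizes(A)
    expect_equal(cs$count, length(sizes))
    expect_equal(sort(cs$sizes), sort(sizes))
    expect_equal(sum(cs$sizes), m)
  }
})

test_that("golden standard splits partition the edge set at the cap", {
  net <- generate_synthetic_ppi(200, seed = 11)
  stopifnot(n_edges(net) >= 100)
  sp <- split_golden_standard(net, 0.25, seed = 9)
  expect_equal(n_edges(sp$training), floor(0.25 * n_edges(net)))
  all_edges <- rbind(sp$training$edges, sp$test_edges)
  expect_identical(all_edges[order(all_edges[,1], all_edges[,2]), ],
                   net$edges)
  expect_identical(sp$training$nodes, net$nodes)

  sp2 <- split_golden_standard(net, 0.25, seed = 9)
  expect_identical(sp2, sp)

  expect_error(split_golden_standard(net, 1.2, 1), "ratio_cap")
  expect_error(split_golden_standard(net, 0, 1), "ratio_cap")
})

test_that("synthetic generator: seed triangle, determinism, skewed degrees", {
  tri <- generate_synthetic_ppi(3, seed = 1)
  expect_equal(n_edges(tri), 3L)
  expect_equal(unname(rowSums(to_adjacency(tri))), c(2, 2, 2))

  a <- generate_synthetic_ppi(300, 0.4, 0.1, seed = 17)
  b <- generate_synthetic_ppi(300, 0.4, 0.1, seed = 17)
  expect_identical(a, b)
  expect_false(identical(a, generate_synthetic_ppi(300, 0.4, 0.1, seed = 18)))

  # right-skewed degree distribution: hubs emerge under duplication
  skewed <- vapply(1:5, function(s) {
    deg <- rowSums(to_adjacency(generate_synthetic_ppi(500, 0.5, 0.1, seed = s)))
    max(deg) > 3 * mean(deg)
  }, logical(1))
  expect_true(all(skewed))

  expect_error(generate_synthetic_ppi(2, seed = 1), "n must be")
  expect_error(generate_synthetic_ppi(10, retention_prob = 1.5, seed = 1),
               "retention_prob")
})
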