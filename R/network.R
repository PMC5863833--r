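#' Construct a PPI network from nodes and edges
#'
#' A `ppi_network` is an undirected graph \eqn{G=(V,E)} over a stable,
#' explicit node order.  Edges are stored once as index pairs `(i, j)` with
#' `i < j`; self-pairs are disallowed.
#'
#' @param nodes character vector of unique protein identifiers.  Their order
#'   is the node order used by every matrix derived from the network.
#' @param edges two-column integer matrix of node indices (1-based), or a
#'   two-column character matrix of node identifiers.  Duplicates (in either
#'   orientation) are collapsed and self-pairs dropped.
#' @return an object of class `ppi_network` with elements `nodes`
#'   (character) and `edges` (two-column integer matrix, `i < j`, sorted).
#' @export
ppi_network <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node identifiers")
  if (length(nodes) == 0L) stop("empty node set")
  if (is.null(edges) || NROW(edges) == 0L) {
    em <- matrix(integer(0), ncol = 2L)
  } else {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2L) stop("edges must have two columns")
    if (is.character(edges)) {
      idx <- match(edges, nodes)
      if (anyNA(idx)) {
        stop("unknown node identifier in edges: ",
             paste(unique(edges[is.na(idx)]), collapse = ", "))
      }
      edges <- matrix(idx, ncol = 2L)
    }
    storage.mode(edges) <- "integer"
    if (any(edges < 1L) || any(edges > length(nodes))) {
      stop("edge endpoint out of range")
    }
    em <- canonical_edges(edges)
  }
  structure(list(nodes = nodes, edges = em), class = "ppi_network")
}

# order each pair (i<j), drop self-pairs, deduplicate, sort lexicographically
canonical_edges <- function(edges) {
  i <- pmin(edges[, 1L], edges[, 2L])
  j <- pmax(edges[, 1L], edges[, 2L])
  keep <- i != j
  i <- i[keep]; j <- j[keep]
  if (length(i) == 0L) return(matrix(integer(0), ncol = 2L))
  key <- !duplicated(paste(i, j))
  i <- unname(i[key]); j <- unname(j[key])
  o <- order(i, j)
  cbind(i = i[o], j = j[o])
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("PPI network:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Number of nodes / edges of a network
#' @param net a `ppi_network`
#' @return integer count
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

#' Read an undirected network from a tab-separated edge list
#'
#' Each non-comment line carries at least two tab-separated protein
#' identifiers; additional columns are ignored.  Lines starting with `#` and
#' blank lines are skipped.  Self-interactions are removed and duplicate
#' edges (in either orientation) collapsed.  Node order is
#' first-appearance order while scanning the file.
#'
#' @param path path to the edge-list file.
#' @return a [ppi_network()].
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("edge-list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) stop("no edges in file: ", path)
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2L)) {
    bad <- idx[which(nf < 2L)[1L]]
    stop("parse error at line ", bad, " of ", path,
         ": expected >= 2 tab-separated fields")
  }
  a <- vapply(parts, `[[`, "", 1L)
  b <- vapply(parts, `[[`, "", 2L)
  # first-appearance node order, scanning each line left to right
  nodes <- unique(as.vector(rbind(a, b)))
  ppi_network(nodes, cbind(a, b))
}

#' Write a network as a tab-separated edge list
#'
#' @param net a `ppi_network` (or a two-column character matrix of IDs).
#' @param path output path.
#' @export
write_edge_list <- function(net, path) {
  if (inherits(net, "ppi_network")) {
    ids <- cbind(net$nodes[net$edges[, 1L]], net$nodes[net$edges[, 2L]])
  } else {
    ids <- as.matrix(net)
  }
  writeLines(paste(ids[, 1L], ids[, 2L], sep = "\t"), path)
  invisible(path)
}

#' Binary adjacency matrix of a network
#'
#' @param net a `ppi_network`.
#' @return an `m x m` symmetric 0/1 matrix with zero diagonal; dimnames
#'   carry the node order.
#' @export
to_adjacency <- function(net) {
  m <- n_nodes(net)
  A <- matrix(0, m, m, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges) > 0L) {
    A[net$edges] <- 1
    A[net$edges[, c(2L, 1L), drop = FALSE]] <- 1
  }
  A
}

#' Recover the network from an adjacency matrix
#'
#' @param A symmetric 0/1 matrix with node identifiers as dimnames.
#' @return a [ppi_network()].
#' @export
from_adjacency <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  nodes <- rownames(A)
  if (is.null(nodes)) nodes <- paste0("n", seq_len(nrow(A)))
  idx <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
  ppi_network(nodes, idx)
}

ppi_components <- function(net) {
  g <- igraph::make_empty_graph(n = n_nodes(net), directed = FALSE)
  if (nrow(net$edges) > 0L) {
    g <- igraph::add_edges(g, t(net$edges))
  }
  igraph::components(g)
}

#' Connected-component summary of a network
#'
#' Components are counted over all nodes, so isolated proteins count as
#' size-1 components.  The `(min, mean, max)` triple mirrors the way sparse
#' disconnected training networks are usually summarised.
#'
#' @param net a `ppi_network`.
#' @return object of class `component_summary`: a list with `count`,
#'   `min_size`, `mean_size`, `max_size`, and the integer vector `sizes`.
#' @export
component_summary <- function(net) {
  if (n_nodes(net) < 1L) stop("empty node set")
  comp <- ppi_components(net)
  sizes <- as.integer(comp$csize)
  structure(
    list(count = comp$no,
         min_size = min(sizes),
         mean_size = mean(sizes),
         max_size = max(sizes),
         sizes = sizes),
    class = "component_summary")
}

#' @export
print.component_summary <- function(x, ...) {
  cat(sprintf("%d components (%d, %.2f, %d)\n",
              x$count, x$min_size, x$mean_size, x$max_size))
  invisible(x)
}

#' Split a golden standard network into training and test edges
#'
#' Uniform random edge sampling without replacement: exactly
#' `floor(ratio_cap * |E|)` edges are kept as the training network `G_tn`
#' (same node set, hence typically highly disconnected) and the remainder
#' become held-out test edges `G_tt`.  The achieved training fraction is
#' therefore always at or below `ratio_cap`.
#'
#' @param net a `ppi_network`, the golden standard `G`.
#' @param ratio_cap fraction in (0,1): cap on `|E_tn| / |E|`.
#' @param seed integer seed; the same seed always reproduces the same split.
#' @return object of class `edge_split`: list with `training` (a
#'   `ppi_network` over the full node set), `test_edges` (two-column integer
#'   matrix), `ratio_cap`, `seed`.
#' @export
split_golden_standard <- function(net, ratio_cap, seed = 1L) {
  if (!is.numeric(ratio_cap) || ratio_cap <= 0 || ratio_cap >= 1) {
    stop("ratio_cap must lie strictly in (0, 1)")
  }
  nE <- n_edges(net)
  if (nE < 2L) stop("need at least 2 edges to split")
  n_train <- floor(ratio_cap * nE)
  pick <- with_seed(seed, sample.int(nE, n_train))
  keep <- logical(nE); keep[pick] <- TRUE
  training <- ppi_network(net$nodes, net$edges[keep, , drop = FALSE])
  structure(
    list(training = training,
         test_edges = net$edges[!keep, , drop = FALSE],
         ratio_cap = ratio_cap,
         seed = as.integer(seed)),
    class = "edge_split")
}

#' @export
print.edge_split <- function(x, ...) {
  cat(sprintf("edge split: %d training / %d test edges (cap %.3f, seed %d)\n",
              n_edges(x$training), nrow(x$test_edges), x$ratio_cap, x$seed))
  invisible(x)
}

# run code under a temporary RNG state, restoring the caller's state after
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic PPI-like network by duplication and divergence
#'
#' Starting from a connected 3-node seed triangle, nodes are added one at a
#' time by duplicating a randomly chosen existing node: each edge of the
#' template is retained by the duplicate independently with probability
#' `retention_prob`, and the duplicate is linked to its template with
#' probability `attach_prob`.  This growth process yields the right-skewed
#' degree distributions and many small disconnected fragments typical of
#' curated PPI networks, which makes it a convenient test-bed for methods
#' aimed at sparse disconnected training networks.
#'
#' @param n final number of nodes (>= 3).
#' @param retention_prob probability that the duplicate inherits each edge
#'   of its template; in (0,1).
#' @param attach_prob probability of a duplicate-template edge; in (0,1).
#' @param seed integer seed; output is deterministic given the seed.
#' @return a [ppi_network()] with nodes `P1 ... Pn`.
#' @export
generate_synthetic_ppi <- function(n, retention_prob = 0.4,
                                   attach_prob = 0.1, seed = 1L) {
  if (!is.numeric(n) || n < 3) stop("n must be >= 3")
  if (retention_prob <= 0 || retention_prob >= 1 ||
      attach_prob <= 0 || attach_prob >= 1) {
    stop("retention_prob and attach_prob must lie strictly in (0, 1)")
  }
  n <- as.integer(n)
  edges <- with_seed(seed, {
    nb <- vector("list", n)                 # adjacency lists
    nb[[1L]] <- c(2L, 3L); nb[[2L]] <- c(1L, 3L); nb[[3L]] <- c(1L, 2L)
    if (n > 3L) for (v in 4:n) {
      u <- sample.int(v - 1L, 1L)           # template node
      inherited <- nb[[u]][stats::runif(length(nb[[u]])) < retention_prob]
      if (stats::runif(1L) < attach_prob) inherited <- c(inherited, u)
      nb[[v]] <- inherited
      for (w in inherited) nb[[w]] <- c(nb[[w]], v)
    }
    i <- rep.int(seq_len(n), lengths(nb))
    j <- unlist(nb, use.names = FALSE)
    cbind(i, j)[i < j, , drop = FALSE]
  })
  ppi_network(paste0("P", seq_len(n)), edges)
}
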