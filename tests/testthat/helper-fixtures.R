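# Shared fixture builders. Everything is generated in code; no data files.

# Small named network from an edge string like "A-B B-C"
toy_net <- function(edge_str, nodes = NULL, weights = NULL) {
  if (!nzchar(edge_str)) {
    return(ppi_network(nodes %||% character()))
  }
  pairs <- strsplit(strsplit(edge_str, " ", fixed = TRUE)[[1]], "-",
                    fixed = TRUE)
  from <- vapply(pairs, `[[`, "", 1L)
  to <- vapply(pairs, `[[`, "", 2L)
  all_nodes <- unique(c(rbind(from, to), nodes))
  ppi_network(all_nodes, data.frame(
    from = from, to = to,
    weight = weights %||% rep(1, length(from))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random labeled feature table with named columns
random_table <- function(n, nf, seed, labels = NULL) {
  set.seed(seed)
  mat <- matrix(rnorm(n * nf), n, nf)
  colnames(mat) <- sprintf("f%02d", seq_len(nf))
  if (is.null(labels)) labels <- rbinom(n, 1, 0.3)
  feature_table(sprintf("g%03d", seq_len(n)), mat, labels)
}

# Erdos-Renyi labeled graph as ppi_network (independent of the package's
# synthetic generator; used by brute-force oracles)
random_net <- function(n, p_edge, seed) {
  set.seed(seed)
  nodes <- sprintf("v%02d", seq_len(n))
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p_edge
  ppi_network(nodes, data.frame(from = nodes[pairs[keep, 1]],
                                to = nodes[pairs[keep, 2]]))
}

# Adjacency matrix of a ppi_network (for definition-level oracles)
adj_matrix <- function(net) {
  n <- length(net$nodes)
  A <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  for (k in seq_along(net$edge_i)) {
    A[net$edge_i[k], net$edge_j[k]] <- net$weight[k]
    A[net$edge_j[k], net$edge_i[k]] <- net$weight[k]
  }
  A
}

# True BFS shortest-path distance between two node indices (oracle)
bfs_distance <- function(A, from, to) {
  if (from == to) return(0L)
  n <- nrow(A)
  dist <- rep(NA_integer_, n)
  dist[from] <- 0L
  frontier <- from
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      nbrs <- which(A[v, ] > 0)
      new <- nbrs[is.na(dist[nbrs])]
      dist[new] <- dist[v] + 1L
      nxt <- c(nxt, new)
    }
    if (!is.na(dist[to])) return(dist[to])
    frontier <- nxt
  }
  Inf
}

# Brute-force second-order transition distribution for directed edge (t, v):
# recomputes alpha from true BFS distances, independent of the package index.
oracle_second_step <- function(net, t, v, p, q) {
  A <- adj_matrix(net)
  xs <- unname(which(A[v, ] > 0))
  mass <- vapply(xs, function(x) {
    d <- min(bfs_distance(A, t, x), 2)
    a <- if (d == 0) 1 / p else if (d == 1) 1 else 1 / q
    a * A[v, x]
  }, 0)
  list(nbr = xs, prob = unname(mass / sum(mass)))
}
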