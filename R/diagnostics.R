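#' Convert a `ppi_network` to an igraph object
#' @param net A `ppi_network`.
#' @return An undirected weighted `igraph` graph with the same node order.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  g <- igraph::make_empty_graph(n = length(net$nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = net$nodes)
  if (length(net$edge_i)) {
    g <- igraph::add_edges(g, rbind(net$edge_i, net$edge_j),
                           weight = net$weight)
  }
  g
}

#' One-hop disease sub-network
#'
#' The induced subgraph on a disease's genes plus their direct neighbors:
#' the node set is `(disease genes in the network) union their neighbors`,
#' the edge set is every network edge with both endpoints inside that set
#' (not only edges touching a disease gene).
#'
#' @param net A `ppi_network`.
#' @param disease A `gene_set` intersecting the network's nodes.
#' @return A `ppi_network`; node order follows the parent network.
#' @export
one_hop_subnetwork <- function(net, disease) {
  stopifnot(inherits(net, "ppi_network"), inherits(disease, "gene_set"))
  seeds <- match(intersect(disease$members, net$nodes), net$nodes)
  if (!length(seeds)) {
    stop2("no disease genes present in the network")
  }
  keep <- sort(unique(c(seeds, unlist(net$adj$nbr[seeds]))))
  in_set <- logical(length(net$nodes))
  in_set[keep] <- TRUE
  e_keep <- in_set[net$edge_i] & in_set[net$edge_j]
  ppi_network(net$nodes[keep],
              data.frame(from = net$nodes[net$edge_i[e_keep]],
                         to = net$nodes[net$edge_j[e_keep]],
                         weight = net$weight[e_keep]))
}

#' Sparsity statistics of a (sub-)network
#'
#' Average local clustering coefficient — nodes of degree < 2 contribute 0
#' rather than being excluded, which matters for sparse disease
#' sub-networks — plus the number of connected components. The global
#' transitivity is reported alongside as an alternative single-number
#' summary.
#'
#' @param sub A non-empty `ppi_network`.
#' @return A list: `n_nodes`, `n_edges`, `avg_clustering`, `transitivity`,
#'   `n_components`.
#' @export
subnetwork_stats <- function(sub) {
  stopifnot(inherits(sub, "ppi_network"))
  if (!length(sub$nodes)) stop2("empty network")
  g <- as_igraph(sub)
  local_cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  local_cc[!is.finite(local_cc)] <- 0     # degree-1 nodes
  glob <- igraph::transitivity(g, type = "global")
  if (!is.finite(glob)) glob <- 0
  list(n_nodes = length(sub$nodes),
       n_edges = n_edges(sub),
       avg_clustering = mean(local_cc),
       transitivity = glob,
       n_components = igraph::components(g)$no)
}

#' Rescale values linearly into `[0.5, 1]`
#'
#' `x -> 0.5 + 0.5 * (x - min) / (max - min)`; the minimum maps to 0.5, the
#' maximum to 1. A constant input maps to 0.75 everywhere (midpoint of the
#' target range). Used to put clustering coefficients and component counts
#' of several diseases on a common scale.
#'
#' @param values Numeric vector, length >= 1.
#' @return Numeric vector of the same length, within `[0.5, 1]`.
#' @export
normalize_range <- function(values) {
  if (!length(values)) stop2("empty input")
  lo <- min(values); hi <- max(values)
  if (hi == lo) return(rep(0.75, length(values)))
  0.5 + 0.5 * (values - lo) / (hi - lo)
}

#' Batch sub-network diagnostics across diseases
#'
#' Extracts the one-hop sub-network of every disease, computes the sparsity
#' statistics, and adds `[0.5, 1]`-normalized columns comparable across the
#' batch (normalization needs >= 2 diseases to be meaningful; with one it
#' returns the degenerate 0.75 midpoint).
#'
#' @param net A `ppi_network`.
#' @param diseases A list of `gene_set`s.
#' @return A data frame, one row per disease.
#' @export
diagnose_diseases <- function(net, diseases) {
  stats <- lapply(diseases, function(d)
    subnetwork_stats(one_hop_subnetwork(net, d)))
  df <- data.frame(
    disease = vapply(diseases, function(d) d$name, ""),
    n_nodes = vapply(stats, `[[`, 0, "n_nodes"),
    n_edges = vapply(stats, `[[`, 0, "n_edges"),
    avg_clustering = vapply(stats, `[[`, 0, "avg_clustering"),
    transitivity = vapply(stats, `[[`, 0, "transitivity"),
    n_components = vapply(stats, `[[`, 0, "n_components"))
  df$norm_clustering <- normalize_range(df$avg_clustering)
  df$norm_components <- normalize_range(df$n_components)
  df
}
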