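#' Construct a protein-protein interaction network
#'
#' A `ppi_network` is an undirected, positively weighted gene graph. Gene
#' identifiers are case-sensitive opaque strings; node order is the order of
#' first appearance and is preserved through every operation so results are
#' deterministic. Self-loops are rejected, duplicate edges collapse to the
#' maximum weight seen (merged interaction evidence, order-independent).
#'
#' @param nodes Character vector of unique gene identifiers. May include
#'   genes that take part in no edge (isolated nodes).
#' @param edges A data frame with columns `from`, `to` and optionally
#'   `weight` (default 1). Endpoints must be members of `nodes`.
#' @return An object of class `ppi_network` with elements `nodes` (character),
#'   `edge_i`/`edge_j` (integer node indices, `edge_i < edge_j`), `weight`
#'   (positive numeric) and `adj` (per-node adjacency: integer neighbor
#'   indices paired with weights).
#' @export
ppi_network <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop2("duplicate node identifiers: ",
    paste(unique(nodes[duplicated(nodes)]), collapse = ", "))
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric())
  }
  if (is.null(edges$weight)) edges$weight <- rep(1, nrow(edges))
  if (any(!is.finite(edges$weight)) || any(edges$weight <= 0)) {
    stop2("edge weights must be positive and finite")
  }
  i <- match(as.character(edges$from), nodes)
  j <- match(as.character(edges$to), nodes)
  if (anyNA(i) || anyNA(j)) {
    bad <- unique(c(edges$from[is.na(i)], edges$to[is.na(j)]))
    stop2("edge endpoints not in node set: ", paste(bad, collapse = ", "))
  }
  if (any(i == j)) stop2("self-loops are not allowed")
  lo <- pmin(i, j); hi <- pmax(i, j)
  # collapse duplicates keeping the maximum weight
  key <- paste(lo, hi)
  if (anyDuplicated(key)) {
    w <- tapply(edges$weight, key, max)
    keep <- !duplicated(key)
    lo <- lo[keep]; hi <- hi[keep]
    wkey <- paste(lo, hi)
    weight <- as.numeric(w[wkey])
  } else {
    weight <- as.numeric(edges$weight)
  }
  ord <- order(lo, hi)
  lo <- lo[ord]; hi <- hi[ord]; weight <- weight[ord]
  net <- structure(
    list(nodes = nodes, edge_i = lo, edge_j = hi, weight = weight,
         adj = build_adjacency(length(nodes), lo, hi, weight)),
    class = "ppi_network")
  net
}

build_adjacency <- function(n, ei, ej, w) {
  nbr <- vector("list", n)
  wts <- vector("list", n)
  if (length(ei)) {
    ends <- c(ei, ej)
    other <- c(ej, ei)
    ww <- c(w, w)
    ord <- order(ends, other)
    ends <- ends[ord]; other <- other[ord]; ww <- ww[ord]
    split_idx <- split(seq_along(ends), factor(ends, levels = seq_len(n)))
    for (v in seq_len(n)) {
      idx <- split_idx[[v]]
      nbr[[v]] <- other[idx]
      wts[[v]] <- ww[idx]
    }
  } else {
    for (v in seq_len(n)) { nbr[[v]] <- integer(); wts[[v]] <- numeric() }
  }
  list(nbr = nbr, w = wts)
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network: %d nodes, %d edges\n",
              length(x$nodes), length(x$edge_i)))
  invisible(x)
}

#' Number of edges / node degrees
#' @param net A `ppi_network`.
#' @return `n_edges`: integer edge count. `degrees`: named integer vector.
#' @export
n_edges <- function(net) length(net$edge_i)

#' @rdname n_edges
#' @export
degrees <- function(net) {
  d <- lengths(net$adj$nbr)
  names(d) <- net$nodes
  d
}

#' Look up the weight of an undirected edge
#' @param net A `ppi_network`.
#' @param u,v Gene identifiers.
#' @return The positive weight, or `NA` if the edge is absent.
#' @export
edge_weight <- function(net, u, v) {
  i <- match(u, net$nodes); j <- match(v, net$nodes)
  if (is.na(i) || is.na(j)) return(NA_real_)
  k <- match(j, net$adj$nbr[[i]])
  if (is.na(k)) NA_real_ else net$adj$w[[i]][k]
}

#' Read a PPI network from a tab-separated edge list
#'
#' Expected format: `geneA<TAB>geneB[<TAB>weight]`, one interaction per line.
#' Lines starting with `#` are comments; a header line is skipped
#' automatically when its third field is non-numeric. Self-loop lines are
#' dropped (and counted in the load report); duplicate edges keep the
#' maximum weight.
#'
#' @param path Path to the edge-list file.
#' @param weighted If `TRUE`, a third numeric column is required; if `FALSE`
#'   all weights are 1; if `NULL` (default) the weight column is used when
#'   present.
#' @param node_list Optional path to a plain-text sidecar naming the full
#'   node universe (one identifier per line); this is the only way isolated
#'   nodes enter a loaded network.
#' @return A `ppi_network` carrying an attribute `report`, a list with
#'   `self_loops_removed` and `duplicates_collapsed` counts.
#' @export
load_edge_list <- function(path, weighted = NULL, node_list = NULL) {
  if (!file.exists(path)) stop2("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop2("no edges in ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  # header detection: first line whose third field is non-numeric, or an
  # unweighted file whose first line repeats known column labels
  if (nf[1] >= 3 && is.na(suppressWarnings(as.numeric(parts[[1]][3])))) {
    parts <- parts[-1]; nf <- nf[-1]; lineno <- lineno[-1]
  }
  if (!length(parts)) stop2("no edges in ", path)
  want <- if (isTRUE(weighted)) 3L else 2L
  bad <- which(nf < want)
  if (length(bad)) {
    stop2(sprintf("malformed line %d in %s: expected %d tab-separated fields",
                  lineno[bad[1]], path, want))
  }
  from <- vapply(parts, `[[`, "", 1L)
  to <- vapply(parts, `[[`, "", 2L)
  use_w <- isTRUE(weighted) || (is.null(weighted) && all(nf >= 3))
  if (use_w) {
    w <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
    if (anyNA(w)) {
      stop2(sprintf("malformed line %d in %s: non-numeric weight",
                    lineno[which(is.na(w))[1]], path))
    }
    if (any(w <= 0)) {
      stop2(sprintf("invalid weight on line %d in %s: weights must be > 0",
                    lineno[which(w <= 0)[1]], path))
    }
  } else {
    w <- rep(1, length(from))
  }
  self <- from == to
  n_self <- sum(self)
  from <- from[!self]; to <- to[!self]; w <- w[!self]
  nodes <- unique(c(rbind(from, to)))
  if (!is.null(node_list)) {
    sidecar <- load_gene_list(node_list)
    nodes <- unique(c(nodes, sidecar$members))
  }
  key <- paste(pmin(from, to), pmax(from, to))
  n_dup <- sum(duplicated(key))
  net <- ppi_network(nodes, data.frame(from = from, to = to, weight = w))
  attr(net, "report") <- list(self_loops_removed = n_self,
                              duplicates_collapsed = n_dup)
  net
}

#' Write a network back to edge-list TSV
#' @param net A `ppi_network`.
#' @param path Output path.
#' @param weighted Write the weight column (default `TRUE`).
#' @export
write_edge_list <- function(net, path, weighted = TRUE) {
  a <- net$nodes[net$edge_i]; b <- net$nodes[net$edge_j]
  lines <- if (weighted) {
    paste(a, b, format(net$weight, digits = 15, trim = TRUE), sep = "\t")
  } else {
    paste(a, b, sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Construct / load a named gene set
#'
#' @param name Label for the set (e.g. a disease code).
#' @param members Character vector of gene identifiers; duplicates collapse.
#' @return An object of class `gene_set` with `name` and `members`.
#' @export
gene_set <- function(name, members) {
  members <- as.character(members)
  members <- members[nzchar(members)]
  if (!length(members)) stop2("gene set '", name, "' is empty")
  dup <- duplicated(members)
  if (any(dup)) {
    warn2(sum(dup), " duplicate identifiers collapsed in gene set '",
          name, "'")
    members <- members[!dup]
  }
  structure(list(name = as.character(name), members = members),
            class = "gene_set")
}

#' @rdname gene_set
#' @param path Plain-text file, one gene identifier per line.
#' @export
load_gene_list <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop2("file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  if (!length(lines)) stop2("gene list ", path, " is empty")
  gene_set(name, lines)
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s': %d genes\n", x$name, length(x$members)))
  invisible(x)
}

#' Report gene-set members missing from a network
#' @param disease A `gene_set`.
#' @param net A `ppi_network`.
#' @return Character vector of members absent from `net` (possibly empty).
#' @export
missing_from_network <- function(disease, net) {
  setdiff(disease$members, net$nodes)
}
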