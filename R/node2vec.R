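#' Configuration for second-order biased random walks
#'
#' `p` (return parameter) and `q` (in-out parameter) control the walk bias:
#' the probability mass on a candidate next node x is proportional to
#' `search_bias(d_tx, p, q) * w_vx`, where `d_tx` is the shortest-path
#' distance between the previous walk node t and x. Small `p` keeps the walk
#' local (breadth-first flavor); small `q` pushes it outward (depth-first).
#'
#' @param p,q Positive reals.
#' @param walks_per_node Number of walks started from every non-isolated
#'   node (default 10).
#' @param walk_length Nodes per walk, including the start (default 80).
#' @param seed Integer seed for the walk simulation.
#' @return A `walk_config` list.
#' @export
walk_config <- function(p = 1, q = 1, walks_per_node = 10, walk_length = 80,
                        seed = 1) {
  stopifnot(p > 0, q > 0, walk_length >= 2, walks_per_node >= 1)
  structure(list(p = p, q = q,
                 walks_per_node = as.integer(walks_per_node),
                 walk_length = as.integer(walk_length),
                 seed = as.integer(seed)),
            class = "walk_config")
}

#' Walk search-bias multiplier
#'
#' Returns `1/p` when the candidate is the previous node (`d_tx = 0`), `1`
#' when the candidate is a shared neighbor of the previous and current node
#' (`d_tx = 1`), and `1/q` when the candidate moves the walk two hops away
#' from the previous node (`d_tx = 2`). No other distances can occur for a
#' neighbor of the current node.
#'
#' @param d_tx Shortest-path distance between the previous walk node and the
#'   candidate next node; must be 0, 1 or 2.
#' @param p,q Positive bias parameters.
#' @return A positive real multiplier.
#' @export
search_bias <- function(d_tx, p, q) {
  if (!is.numeric(p) || !is.numeric(q) || any(p <= 0) || any(q <= 0)) {
    stop2("p and q must be positive")
  }
  if (!all(d_tx %in% c(0, 1, 2))) stop2("d_tx must be 0, 1 or 2")
  out <- numeric(length(d_tx))
  out[d_tx == 0] <- 1 / p
  out[d_tx == 1] <- 1
  out[d_tx == 2] <- 1 / q
  out
}

#' Precompute first- and second-order transition distributions
#'
#' For every node v the first-step distribution over neighbors x has mass
#' proportional to the edge weight w_vx. For every directed edge (t, v) the
#' second-step distribution over neighbors x of v has mass proportional to
#' `search_bias(d_tx, p, q) * w_vx`, where d_tx is 0 iff x = t, 1 iff x is
#' adjacent to t, and 2 otherwise.
#'
#' @param net A `ppi_network`.
#' @param config A `walk_config` (only `p` and `q` are used).
#' @return A `transition_index`: `first_step` is a list (per node index) of
#'   `list(nbr, prob)`; `second_step` is an environment keyed `"t|v"` (node
#'   indices) holding `list(nbr, prob)`.
#' @export
build_transition_index <- function(net, config) {
  stopifnot(inherits(net, "ppi_network"), inherits(config, "walk_config"))
  if (!length(net$nodes)) stop2("empty network")
  p <- config$p; q <- config$q
  nbr <- net$adj$nbr; wts <- net$adj$w
  n <- length(net$nodes)
  first_step <- vector("list", n)
  for (v in seq_len(n)) {
    if (length(nbr[[v]])) {
      pr <- wts[[v]] / sum(wts[[v]])
      first_step[[v]] <- list(nbr = nbr[[v]], prob = pr)
    }
  }
  second_step <- new.env(hash = TRUE, parent = emptyenv())
  for (v in seq_len(n)) {
    xs <- nbr[[v]]; wx <- wts[[v]]
    if (!length(xs)) next
    for (k in seq_along(xs)) {
      t <- xs[k]
      t_nbr <- nbr[[t]]
      d <- ifelse(xs == t, 0L, ifelse(xs %in% t_nbr, 1L, 2L))
      mass <- search_bias(d, p, q) * wx
      assign(paste0(t, "|", v),
             list(nbr = xs, prob = mass / sum(mass)),
             envir = second_step)
    }
  }
  structure(list(first_step = first_step, second_step = second_step,
                 p = p, q = q, n_nodes = n),
            class = "transition_index")
}

#' Simulate biased random walks over a network
#'
#' Starts `walks_per_node` walks from every non-isolated node; node visiting
#' order is reshuffled each round with the seeded generator. The first
#' transition is drawn from the first-step distribution, later ones from the
#' second-order distributions. A walk reaching a node with no neighbors is
#' truncated. Isolated start nodes are skipped and recorded in the
#' `"skipped"` attribute.
#'
#' @param net A `ppi_network`.
#' @param index A `transition_index` built from `net` with the same p, q.
#' @param config A `walk_config`.
#' @return A list of character vectors (gene identifiers), bit-reproducible
#'   given `config$seed`.
#' @export
simulate_walks <- function(net, index, config) {
  stopifnot(inherits(index, "transition_index"))
  if (index$p != config$p || index$q != config$q) {
    stop2("transition index was built with different p/q")
  }
  n <- length(net$nodes)
  deg <- lengths(net$adj$nbr)
  starts <- which(deg > 0L)
  isolated <- net$nodes[deg == 0L]
  L <- config$walk_length
  first <- index$first_step
  second <- index$second_step
  walks <- with_seed(config$seed, {
    out <- vector("list", length(starts) * config$walks_per_node)
    k <- 0L
    for (round in seq_len(config$walks_per_node)) {
      order_v <- sample(starts)
      for (v in order_v) {
        walk <- integer(L)
        walk[1L] <- v
        fs <- first[[v]]
        walk[2L] <- fs$nbr[sample.int(length(fs$nbr), 1L, prob = fs$prob)]
        len <- 2L
        while (len < L) {
          t <- walk[len - 1L]; cur <- walk[len]
          dist <- get(paste0(t, "|", cur), envir = second)
          walk[len + 1L] <-
            dist$nbr[sample.int(length(dist$nbr), 1L, prob = dist$prob)]
          len <- len + 1L
        }
        k <- k + 1L
        out[[k]] <- net$nodes[walk[seq_len(len)]]
      }
    }
    out
  })
  attr(walks, "skipped") <- isolated
  walks
}

#' Skip-gram training configuration
#'
#' @param dim Embedding dimensionality (default 128).
#' @param window Symmetric context window in tokens (default 10).
#' @param negative_samples Negative samples per positive pair (default 5).
#' @param epochs Passes over the walk corpus (default 5). `epochs = 0`
#'   returns the seeded random initialization unchanged.
#' @param initial_learning_rate Starting SGD step size, decayed linearly
#'   (default 0.025).
#' @param seed Integer seed for initialization and negative sampling.
#' @return A `skipgram_config` list.
#' @export
skipgram_config <- function(dim = 128, window = 10, negative_samples = 5,
                            epochs = 5, initial_learning_rate = 0.025,
                            seed = 1) {
  stopifnot(dim >= 1, window >= 1, negative_samples >= 0, epochs >= 0,
            initial_learning_rate > 0)
  structure(list(dim = as.integer(dim), window = as.integer(window),
                 negative_samples = as.integer(negative_samples),
                 epochs = as.integer(epochs),
                 initial_learning_rate = initial_learning_rate,
                 seed = as.integer(seed)),
            class = "skipgram_config")
}

#' Train skip-gram embeddings with negative sampling on walk corpora
#'
#' Single-worker stochastic gradient descent on the skip-gram objective with
#' negative sampling; negatives are drawn from the unigram distribution
#' raised to the 3/4 power. Deterministic given the seed.
#'
#' @param walks List of walks (character vectors of gene identifiers).
#' @param config A `skipgram_config`.
#' @return An `embedding_matrix`: `genes` (distinct tokens in order of first
#'   appearance) and `vectors` (one row per gene, `dim` columns).
#' @export
train_skipgram <- function(walks, config) {
  stopifnot(inherits(config, "skipgram_config"))
  if (!length(walks)) stop2("walk list is empty")
  vocab <- unique(unlist(walks, use.names = FALSE))
  sents <- lapply(walks, function(w) match(w, vocab) - 1L)
  counts <- tabulate(unlist(sents, use.names = FALSE) + 1L, length(vocab))
  mat <- sgns_train(sents, length(vocab), as.numeric(counts),
                    config$dim, config$window, config$negative_samples,
                    config$epochs, config$initial_learning_rate,
                    config$seed)
  embedding_matrix(vocab, mat)
}

#' Construct / validate an embedding matrix
#' @param genes Ordered gene identifiers (no duplicates).
#' @param vectors Numeric matrix, one row per gene; all entries finite.
#' @return An `embedding_matrix`.
#' @export
embedding_matrix <- function(genes, vectors) {
  genes <- as.character(genes)
  vectors <- as.matrix(vectors)
  if (anyDuplicated(genes)) stop2("duplicate gene identifiers")
  if (nrow(vectors) != length(genes)) stop2("row/gene count mismatch")
  if (length(vectors) && !all(is.finite(vectors))) {
    stop2("non-finite embedding entries")
  }
  rownames(vectors) <- genes
  structure(list(genes = genes, vectors = vectors), class = "embedding_matrix")
}

#' @export
print.embedding_matrix <- function(x, ...) {
  cat(sprintf("embedding_matrix: %d genes x %d dimensions\n",
              length(x$genes), ncol(x$vectors)))
  invisible(x)
}

#' Embed a whole network (walks + skip-gram in one call)
#'
#' Convenience wrapper: builds the transition index, simulates walks and
#' trains the skip-gram model. Isolated nodes never enter the walk corpus;
#' they receive the zero vector so they still carry keyword features
#' downstream, and are flagged in the `"isolated"` attribute.
#'
#' @param net A `ppi_network`.
#' @param walk_cfg A `walk_config`.
#' @param sg_cfg A `skipgram_config`.
#' @return An `embedding_matrix` whose gene order equals `net$nodes`.
#' @export
embed_network <- function(net, walk_cfg = walk_config(),
                          sg_cfg = skipgram_config()) {
  index <- build_transition_index(net, walk_cfg)
  walks <- simulate_walks(net, index, walk_cfg)
  if (!length(walks)) stop2("network has no edges; nothing to embed")
  emb <- train_skipgram(walks, sg_cfg)
  full <- matrix(0, nrow = length(net$nodes), ncol = ncol(emb$vectors))
  hit <- match(emb$genes, net$nodes)
  full[hit, ] <- emb$vectors
  out <- embedding_matrix(net$nodes, full)
  attr(out, "isolated") <- attr(walks, "skipped")
  out
}

#' Write / read embeddings in word2vec text format
#'
#' Header line `N d`, then one line per gene: identifier followed by `d`
#' decimal values at 8+ significant digits.
#'
#' @param emb An `embedding_matrix`.
#' @param path File path.
#' @export
write_embeddings <- function(emb, path) {
  stopifnot(inherits(emb, "embedding_matrix"))
  d <- ncol(emb$vectors)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(length(emb$genes), d), con)
  vals <- apply(emb$vectors, 1L, function(r)
    paste(format(r, digits = 9, trim = TRUE, scientific = FALSE),
          collapse = " "))
  writeLines(paste(emb$genes, vals), con)
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop2("empty embedding file")
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) != 2L) stop2("malformed header in ", path)
  n <- as.integer(hdr[1]); d <- as.integer(hdr[2])
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) != n) {
    stop2(sprintf("header declares %d rows but file has %d", n, length(body)))
  }
  parts <- strsplit(body, "\\s+")
  if (any(lengths(parts) != d + 1L)) {
    stop2("row with wrong number of fields in ", path)
  }
  genes <- vapply(parts, `[[`, "", 1L)
  vecs <- matrix(NA_real_, n, d)
  for (i in seq_len(n)) vecs[i, ] <- as.numeric(parts[[i]][-1L])
  if (anyNA(vecs)) stop2("non-numeric embedding value in ", path)
  embedding_matrix(genes, vecs)
}
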