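#' Specification of a synthetic planted-community benchmark
#'
#' Defines a gene network with one planted disease community: every pair of
#' disease genes is connected independently with probability `p_in`, every
#' other pair with `p_out`, and `n_informative` keywords are enriched in
#' disease genes (`rho1` there, `rho0` elsewhere). This is the test bed for
#' the whole pipeline: the embedding stage must detect community cohesion
#' and the annotation stage must exploit keyword enrichment — the two
#' signals the method combines on real interactome data.
#'
#' @param n_genes Total gene count.
#' @param n_disease Planted disease-community size.
#' @param p_in Within-community edge probability.
#' @param p_out Background edge probability (`p_out <= p_in`).
#' @param n_keywords Keyword vocabulary size.
#' @param n_informative Number of disease-enriched keywords
#'   (`<= n_keywords`).
#' @param rho1 Informative-keyword probability in disease genes.
#' @param rho0 Background keyword probability (`rho0 <= rho1`).
#' @param seed Integer seed; generators are pure functions of the spec.
#' @return A `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 500, n_disease = 30, p_in = 0.2,
                           p_out = 0.01, n_keywords = 200,
                           n_informative = 10, rho1 = 0.6, rho0 = 0.05,
                           seed = 1) {
  if (!(p_out >= 0 && p_out <= p_in && p_in <= 1)) {
    stop2("need 0 <= p_out <= p_in <= 1")
  }
  if (!(rho0 >= 0 && rho0 <= rho1 && rho1 <= 1)) {
    stop2("need 0 <= rho0 <= rho1 <= 1")
  }
  if (n_informative > n_keywords) stop2("n_informative > n_keywords")
  if (n_disease > n_genes) stop2("n_disease > n_genes")
  structure(list(n_genes = as.integer(n_genes),
                 n_disease = as.integer(n_disease),
                 p_in = p_in, p_out = p_out,
                 n_keywords = as.integer(n_keywords),
                 n_informative = as.integer(n_informative),
                 rho1 = rho1, rho0 = rho0, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a network with a planted disease community
#'
#' Genes are labeled `g0001..gN`; the first `n_disease` form the disease
#' community. Edges are sampled independently: probability `p_in` inside
#' the community, `p_out` elsewhere. Bit-reproducible from the spec seed.
#'
#' @param spec A `synthetic_spec`.
#' @return A list: `net` (a `ppi_network`, isolated genes included) and
#'   `disease` (a `gene_set`).
#' @export
make_planted_disease_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_genes
  genes <- sprintf("g%04d", seq_len(n))
  dis <- seq_len(spec$n_disease)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  in_comm <- pairs[, 1] <= spec$n_disease & pairs[, 2] <= spec$n_disease
  prob <- ifelse(in_comm, spec$p_in, spec$p_out)
  keep <- with_seed(derive_seed(spec$seed, "edges"),
                    runif(nrow(pairs)) < prob)
  edges <- data.frame(from = genes[pairs[keep, 1]],
                      to = genes[pairs[keep, 2]])
  net <- ppi_network(genes, edges)
  list(net = net, disease = gene_set("planted", genes[dis]))
}

#' Generate keyword annotations enriched in a disease community
#'
#' The first `n_informative` keywords fire with probability `rho1` in
#' disease genes and `rho0` elsewhere; all remaining keywords fire at the
#' background rate `rho0` for every gene. Categories are assigned
#' round-robin over the eight UniProt keyword categories.
#'
#' @param genes Ordered gene identifiers (the network's node set).
#' @param disease A `gene_set`.
#' @param spec A `synthetic_spec`.
#' @return A `keyword_matrix`.
#' @export
make_keyword_annotations <- function(genes, disease, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  genes <- as.character(genes)
  nk <- spec$n_keywords
  kw_names <- sprintf("K%03d", seq_len(nk))
  is_dis <- genes %in% disease$members
  prob <- matrix(spec$rho0, length(genes), nk)
  if (spec$n_informative > 0) {
    prob[is_dis, seq_len(spec$n_informative)] <- spec$rho1
  }
  mat <- with_seed(derive_seed(spec$seed, "keywords"),
                   matrix(as.numeric(runif(length(prob)) < prob),
                          nrow(prob), nk))
  cats <- setNames(rep_len(KEYWORD_CATEGORIES, nk), kw_names)
  keyword_matrix(genes, kw_names, mat, cats)
}

#' Generate an imbalanced two-class Gaussian feature table
#'
#' Minority rows (label 1) are drawn from `Normal(shift * 1, I)`, majority
#' rows (label 0) from `Normal(0, I)`. `shift = 0` is the null case where
#' any classifier's cross-validated AUC should hover around 0.5.
#'
#' @param n_min,n_maj Class sizes (`n_min >= 2`).
#' @param dim Feature dimensionality.
#' @param shift Minority mean offset on every coordinate.
#' @param seed Integer seed.
#' @return A labeled `feature_table` with `n_min + n_maj` rows.
#' @export
make_imbalanced_gaussian <- function(n_min, n_maj, dim, shift, seed = 1) {
  if (n_min < 2) stop2("n_min must be >= 2")
  with_seed(derive_seed(seed, "gaussian"), {
    Xmin <- matrix(rnorm(n_min * dim, mean = shift), n_min, dim)
    Xmaj <- matrix(rnorm(n_maj * dim, mean = 0), n_maj, dim)
    mat <- rbind(Xmin, Xmaj)
    colnames(mat) <- sprintf("f%03d", seq_len(dim))
    feature_table(sprintf("s%04d", seq_len(n_min + n_maj)), mat,
                  c(rep(1L, n_min), rep(0L, n_maj)))
  })
}

#' Write a synthetic benchmark to standard file formats
#'
#' Emits `edges.tsv` (edge list), `annotations.tsv` (long-format
#' gene/keyword/category) and `disease.txt` (one gene per line) under
#' `out_dir`, the same formats [load_edge_list()], [load_annotations()] and
#' [load_gene_list()] read.
#'
#' @param spec A `synthetic_spec`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_synthetic_benchmark <- function(spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- make_planted_disease_network(spec)
  kw <- make_keyword_annotations(gen$net$nodes, gen$disease, spec)
  paths <- file.path(out_dir, c("edges.tsv", "annotations.tsv",
                                "disease.txt"))
  write_edge_list(gen$net, paths[1], weighted = FALSE)
  idx <- which(kw$mat == 1, arr.ind = TRUE)
  ann <- data.frame(gene = kw$genes[idx[, 1]],
                    keyword = kw$keywords[idx[, 2]],
                    category = kw$categories[kw$keywords[idx[, 2]]])
  ann <- ann[order(ann$gene, ann$keyword), ]
  utils::write.table(ann, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(gen$disease$members, paths[3])
  invisible(setNames(paths, c("edges", "annotations", "disease")))
}
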