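# The eight UniProt keyword categories used for the category summary.
KEYWORD_CATEGORIES <- c(
  "Biological process", "Cellular component", "Coding sequence diversity",
  "Domain", "Ligand", "Molecular function",
  "Post-translational modification", "Technical term")

#' Construct a binary gene-by-keyword matrix
#'
#' @param genes Ordered gene identifiers.
#' @param keywords Keyword vocabulary; stored sorted lexicographically.
#' @param mat Binary matrix (genes x keywords), entries in `{0, 1}`.
#' @param categories Named character vector mapping each keyword to one of
#'   the eight UniProt keyword categories; keywords without a category get
#'   `"Uncategorized"`.
#' @return A `keyword_matrix`.
#' @export
keyword_matrix <- function(genes, keywords, mat,
                           categories = NULL) {
  genes <- as.character(genes)
  keywords <- as.character(keywords)
  mat <- as.matrix(mat)
  if (anyDuplicated(genes)) stop2("duplicate genes")
  if (anyDuplicated(keywords)) stop2("duplicate keywords")
  if (nrow(mat) != length(genes) || ncol(mat) != length(keywords)) {
    stop2("matrix dimensions do not match genes/keywords")
  }
  if (length(mat) && !all(mat %in% c(0, 1))) stop2("entries must be 0/1")
  ord <- order(keywords, method = "radix")
  keywords <- keywords[ord]
  mat <- mat[, ord, drop = FALSE]
  cats <- setNames(rep("Uncategorized", length(keywords)), keywords)
  if (!is.null(categories) && length(categories)) {
    hit <- intersect(names(categories), keywords)
    cats[hit] <- categories[hit]
  }
  dimnames(mat) <- list(genes, keywords)
  structure(list(genes = genes, keywords = keywords, mat = mat,
                 categories = cats),
            class = "keyword_matrix")
}

#' @export
print.keyword_matrix <- function(x, ...) {
  cat(sprintf("keyword_matrix: %d genes x %d keywords\n",
              length(x$genes), length(x$keywords)))
  invisible(x)
}

#' Load gene-keyword annotations from long-format TSV
#'
#' Expected format: `gene<TAB>keyword[<TAB>category]`, one association per
#' line; `#` comments allowed. Genes in `gene_universe` with no annotation
#' get an all-zero row (counted in the `"report"` attribute); annotations
#' for genes outside the universe are ignored (also counted).
#'
#' @param path Path to the annotation file.
#' @param gene_universe Ordered gene identifiers, typically the network's
#'   node set.
#' @return A `keyword_matrix` over `gene_universe`.
#' @export
load_annotations <- function(path, gene_universe) {
  if (!file.exists(path)) stop2("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < 2L)
  if (length(bad)) {
    stop2(sprintf("malformed line %d in %s: expected gene<TAB>keyword",
                  lineno[bad[1]], path))
  }
  gene <- vapply(parts, `[[`, "", 1L)
  kw <- vapply(parts, `[[`, "", 2L)
  cat3 <- ifelse(nf >= 3L, vapply(parts, function(p)
    if (length(p) >= 3L) p[[3L]] else "", ""), "")
  gene_universe <- as.character(gene_universe)
  in_univ <- gene %in% gene_universe
  vocab <- sort(unique(kw[in_univ]), method = "radix")
  mat <- matrix(0, length(gene_universe), length(vocab))
  gi <- match(gene[in_univ], gene_universe)
  ki <- match(kw[in_univ], vocab)
  mat[cbind(gi, ki)] <- 1
  cats <- character(0)
  has_cat <- in_univ & nzchar(cat3)
  if (any(has_cat)) {
    cats <- setNames(cat3[has_cat], kw[has_cat])
    cats <- cats[!duplicated(names(cats))]
  }
  out <- keyword_matrix(gene_universe, vocab, mat, cats)
  out$mat <- out$mat[, , drop = FALSE]
  attr(out, "report") <- list(
    unannotated_genes = sum(rowSums(mat) == 0),
    ignored_outside_universe = sum(!in_univ))
  out
}

#' Construct a gene-by-feature table
#'
#' The central container shared by feature selection, resampling and model
#' fitting: a numeric matrix with named columns, one row per gene, plus an
#' optional 0/1 disease-label vector.
#'
#' @param genes Ordered gene identifiers.
#' @param mat Numeric matrix, one row per gene, named columns.
#' @param labels Optional integer 0/1 vector covering every gene
#'   (1 = disease gene).
#' @return A `feature_table`.
#' @export
feature_table <- function(genes, mat, labels = NULL) {
  genes <- as.character(genes)
  mat <- as.matrix(mat)
  if (anyDuplicated(genes)) stop2("duplicate gene identifiers")
  if (nrow(mat) != length(genes)) stop2("row count != gene count")
  if (is.null(colnames(mat)) && ncol(mat) > 0) {
    stop2("feature columns must be named")
  }
  if (anyDuplicated(colnames(mat))) stop2("duplicate feature names")
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != length(genes)) stop2("labels must cover every gene")
    if (!all(labels %in% c(0L, 1L))) stop2("labels must be 0/1")
  }
  rownames(mat) <- genes
  structure(list(genes = genes, features = colnames(mat), mat = mat,
                 labels = labels),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d genes x %d features%s\n",
              length(x$genes), length(x$features),
              if (is.null(x$labels)) ""
              else sprintf(", %d positives", sum(x$labels))))
  invisible(x)
}

#' Concatenate node embeddings with keyword vectors (N2VK representation)
#'
#' Both inputs must cover the same gene universe (order may differ; rows are
#' aligned by identifier). Embedding columns are prefixed `emb_`, keyword
#' columns `kw_`; row order follows the embedding's gene order.
#'
#' @param emb An `embedding_matrix`.
#' @param kw A `keyword_matrix` over the same genes.
#' @return An unlabeled `feature_table` with `dim + |vocabulary|` columns.
#' @export
build_n2vk <- function(emb, kw) {
  stopifnot(inherits(emb, "embedding_matrix"), inherits(kw, "keyword_matrix"))
  only_emb <- setdiff(emb$genes, kw$genes)
  only_kw <- setdiff(kw$genes, emb$genes)
  if (length(only_emb) || length(only_kw)) {
    stop2("gene universes differ; only in embedding: {",
          paste(only_emb, collapse = ", "), "}; only in keywords: {",
          paste(only_kw, collapse = ", "), "}")
  }
  d <- ncol(emb$vectors)
  emat <- emb$vectors
  colnames(emat) <- paste0("emb_", seq_len(d))
  kmat <- kw$mat[match(emb$genes, kw$genes), , drop = FALSE]
  if (ncol(kmat)) colnames(kmat) <- paste0("kw_", kw$keywords)
  feature_table(emb$genes, cbind(emat, kmat))
}

#' Embedding-only feature table
#' @param emb An `embedding_matrix`.
#' @return An unlabeled `feature_table` with `emb_` columns.
#' @export
embedding_features <- function(emb) {
  m <- emb$vectors
  colnames(m) <- paste0("emb_", seq_len(ncol(m)))
  feature_table(emb$genes, m)
}

#' Attach disease labels to a feature table
#'
#' Genes in the disease set get label 1, all others 0 (absence of evidence
#' treated as negative: a Positive-Unlabeled approximation). Positives
#' absent from the table are reported via the `"missing_positives"`
#' attribute, never silently dropped.
#'
#' @param table An unlabeled `feature_table`.
#' @param disease A `gene_set`.
#' @return The labeled `feature_table`.
#' @export
attach_labels <- function(table, disease) {
  stopifnot(inherits(table, "feature_table"), inherits(disease, "gene_set"))
  if (!is.null(table$labels)) stop2("table already has labels")
  hit <- table$genes %in% disease$members
  if (!any(hit)) {
    stop2("no disease genes present in the table; disease '", disease$name,
          "' is unusable with this network")
  }
  missing <- setdiff(disease$members, table$genes)
  out <- feature_table(table$genes, table$mat, as.integer(hit))
  attr(out, "missing_positives") <- missing
  out
}

#' Serialize / load a feature table as TSV
#'
#' Header row; gene identifier in the first column, optional `label` last.
#'
#' @param table A `feature_table`.
#' @param path File path.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(gene = table$genes, table$mat, check.names = FALSE)
  if (!is.null(table$labels)) df$label <- table$labels
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"gene" %in% names(df)) stop2("missing 'gene' column in ", path)
  labels <- NULL
  if ("label" %in% names(df)) {
    labels <- df$label
    df$label <- NULL
  }
  genes <- df$gene
  df$gene <- NULL
  feature_table(genes, as.matrix(df), labels)
}
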