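#' Fit a ridge-stabilized logistic classifier
#'
#' Maximizes the Bernoulli log-likelihood minus `l2/2 * ||beta||^2` (the
#' intercept is not penalized) by iteratively reweighted least squares.
#' Convergence: max absolute coefficient change < 1e-8, capped at 100
#' iterations. The small default ridge keeps the fit defined on linearly
#' separable embeddings.
#'
#' @param table A labeled `feature_table` with both classes present.
#' @param l2 Ridge strength (default 1e-6).
#' @return A `classifier_model` with `method = "glm"`, coefficients
#'   (intercept first) and the feature names it was fitted on.
#' @export
fit_logistic <- function(table, l2 = 1e-6) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(table$labels)) stop2("labels required")
  y <- as.numeric(table$labels)
  if (all(y == 1) || all(y == 0)) stop2("both classes must be present")
  X <- cbind(1, table$mat)
  p <- ncol(X)
  pen <- diag(c(0, rep(l2, p - 1L)), p)
  beta <- rep(0, p)
  converged <- FALSE
  for (iter in seq_len(100L)) {
    eta <- as.numeric(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    new_beta <- tryCatch(
      as.numeric(solve(XtW %*% X + pen, XtW %*% z)),
      error = function(e) NULL)
    if (is.null(new_beta)) break
    delta <- max(abs(new_beta - beta))
    beta <- new_beta
    if (delta < 1e-8) { converged <- TRUE; break }
  }
  if (!converged && l2 == 0) {
    warn2("logistic fit did not converge at l2 = 0; returning iteration cap")
  }
  structure(list(method = "glm", coefficients = beta,
                 feature_names = table$features, l2 = l2,
                 converged = converged),
            class = "classifier_model")
}

#' Fit a k-nearest-neighbor scorer
#'
#' Scores a query as the fraction of its k nearest training rows (Euclidean
#' distance) labeled 1; distance ties break by training row order.
#'
#' @param table A labeled `feature_table`.
#' @param k Neighbor count, `1 <= k <= n`.
#' @return A `classifier_model` with `method = "knn"`.
#' @export
fit_knn <- function(table, k) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(table$labels)) stop2("labels required")
  if (k < 1) stop2("k must be >= 1")
  if (k > length(table$genes)) stop2("k exceeds training size")
  structure(list(method = "knn", train = table$mat,
                 train_labels = table$labels, k = as.integer(k),
                 feature_names = table$features),
            class = "classifier_model")
}

#' @export
print.classifier_model <- function(x, ...) {
  cat(sprintf("classifier_model: %s on %d features\n", x$method,
              length(x$feature_names)))
  invisible(x)
}

#' Score genes with a fitted classifier
#'
#' @param object A `classifier_model`.
#' @param table A `feature_table` whose features match the fitted names
#'   exactly (order included); anything else is rejected.
#' @param ... Unused.
#' @return Numeric scores in `[0, 1]`, named by gene.
#' @export
predict.classifier_model <- function(object, table, ...) {
  stopifnot(inherits(table, "feature_table"))
  if (!identical(table$features, object$feature_names)) {
    stop2("feature names do not match the fitted model")
  }
  scores <- switch(object$method,
    glm = {
      eta <- as.numeric(cbind(1, table$mat) %*% object$coefficients)
      1 / (1 + exp(-eta))
    },
    knn = {
      apply(table$mat, 1L, function(x) {
        d <- sqrt(colSums((t(object$train) - x)^2))
        nn <- order(d)[seq_len(object$k)]   # stable: ties by row order
        mean(object$train_labels[nn])
      })
    },
    stop2("unknown model method: ", object$method))
  setNames(as.numeric(scores), table$genes)
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' Probability that a random positive outscores a random negative, ties
#' counted half: `(#{score_pos > score_neg} + 0.5 * #ties) / (n1 * n0)`.
#'
#' @param scores Numeric score per gene.
#' @param labels Binary 0/1 label per gene; both classes required.
#' @return A real in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop2("length mismatch")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop2("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified k-fold cross-validation of the full pipeline tail
#'
#' Genes are partitioned into `folds` disjoint folds, stratified so the
#' per-class counts differ by at most one across folds; the assignment
#' depends only on the labels and the seed. Within each fold, feature
#' selection is fitted on the training 80% only, oversampling is applied to
#' the (selected) training portion only, the classifier is fitted, and AUC
#' is measured on the untouched test fold. This ordering keeps synthetic
#' minority copies out of the test set.
#'
#' @param table A labeled `feature_table`.
#' @param pipe Pipeline tail configuration: a list with `fs` (list:
#'   `method` in mrmr/varimp/stepwise/none, `m`), `oversample` (a
#'   `resample_config` or `list(method = "none")`), `model` (list:
#'   `method` in glm/knn, `l2`, `k`).
#' @param folds Number of folds (default 5).
#' @param seed Integer seed for the fold assignment and per-fold
#'   oversampling streams.
#' @return A `cv_result`: `fold_auc` (length `folds`), `mean_auc`,
#'   `fold_assignments` (integer per gene), `selected` (per-fold selected
#'   features) and `config` provenance.
#' @export
stratified_kfold_cv <- function(table, pipe = cv_pipe(), folds = 5, seed = 1) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(table$labels)) stop2("labels required")
  n1 <- sum(table$labels == 1L); n0 <- sum(table$labels == 0L)
  if (n1 < folds || n0 < folds) {
    stop2("need at least ", folds, " genes per class; got ", n1,
          " positives and ", n0, " negatives — use fewer folds")
  }
  assign <- assign_folds(table$labels, folds, seed)
  fold_auc <- numeric(folds)
  selected <- vector("list", folds)
  for (f in seq_len(folds)) {
    test_idx <- which(assign == f)
    train_idx <- which(assign != f)
    train <- feature_table(table$genes[train_idx],
                           table$mat[train_idx, , drop = FALSE],
                           table$labels[train_idx])
    test <- feature_table(table$genes[test_idx],
                          table$mat[test_idx, , drop = FALSE],
                          table$labels[test_idx])
    sel <- run_feature_selection(train, pipe$fs$method %||% "none",
                                 pipe$fs$m %||% 100L)
    selected[[f]] <- sel$features
    train <- subset_features(train, sel)
    test_sub <- subset_features(test, sel)
    os <- pipe$oversample
    if (!is.null(os) && os$method != "none") {
      os$seed <- derive_seed(seed, paste0("oversample_fold", f))
      train <- run_resampling(train, os)
    }
    model <- switch(pipe$model$method %||% "glm",
      glm = fit_logistic(train, pipe$model$l2 %||% 1e-6),
      knn = fit_knn(train, pipe$model$k %||% 5L),
      stop2("unknown model: ", pipe$model$method))
    scores <- predict(model, test_sub)
    fold_auc[f] <- auc(scores, test$labels)
  }
  structure(list(fold_auc = fold_auc, mean_auc = mean(fold_auc),
                 fold_assignments = setNames(assign, table$genes),
                 selected = selected,
                 config = list(pipe = pipe, folds = folds, seed = seed)),
            class = "cv_result")
}

# Stratified fold assignment: shuffle each class with the seeded generator,
# then deal round-robin. Depends only on (labels, seed), never on features.
assign_folds <- function(labels, folds, seed) {
  assign <- integer(length(labels))
  with_seed(derive_seed(seed, "folds"), {
    for (cls in c(0L, 1L)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

#' Default pipeline-tail configuration for [stratified_kfold_cv()]
#' @param fs_method,fs_m Feature selection method and subset size.
#' @param oversample A `resample_config` or `list(method = "none")`.
#' @param model_method `"glm"` or `"knn"`.
#' @param l2,k Model hyperparameters.
#' @return A `pipe` list.
#' @export
cv_pipe <- function(fs_method = "none", fs_m = 100L,
                    oversample = list(method = "none"),
                    model_method = "glm", l2 = 1e-6, k = 5L) {
  list(fs = list(method = fs_method, m = as.integer(fs_m)),
       oversample = oversample,
       model = list(method = model_method, l2 = l2, k = as.integer(k)))
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: mean AUC %.4f over %d folds (%s)\n",
              x$mean_auc, length(x$fold_auc),
              paste(sprintf("%.3f", x$fold_auc), collapse = ", ")))
  invisible(x)
}
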