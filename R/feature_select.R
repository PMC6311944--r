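#' Selection result container
#'
#' @param features Selected feature names, in selection order.
#' @param scores Method-specific score per selected feature.
#' @param method Method tag (`"mrmr"`, `"varimp"`, `"stepwise"`).
#' @param m Requested subset size (NA for stepwise, which sizes itself).
#' @return A `selection_result`.
#' @export
selection_result <- function(features, scores, method, m = NA_integer_) {
  features <- as.character(features)
  if (anyDuplicated(features)) stop2("duplicate selected features")
  stopifnot(length(scores) == length(features))
  structure(list(features = features, scores = as.numeric(scores),
                 method = method, m = m),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result (%s): %d features\n", x$method,
              length(x$features)))
  invisible(x)
}

# Discretize a feature column for mutual-information estimation: binary
# columns are used as-is; continuous columns get 3 bins split at
# mean - sd and mean + sd.
discretize_column <- function(x) {
  if (all(x %in% c(0, 1))) return(as.integer(x) + 1L)
  m <- mean(x); s <- sd(x)
  ifelse(x < m - s, 1L, ifelse(x > m + s, 3L, 2L))
}

# Mutual information (nats) between two small-alphabet integer vectors.
mutual_information <- function(a, b) {
  ka <- max(a); kb <- max(b)
  joint <- tabulate((a - 1L) * kb + b, ka * kb) / length(a)
  pa <- rowSums(matrix(joint, ka, kb, byrow = TRUE))
  pb <- colSums(matrix(joint, ka, kb, byrow = TRUE))
  outer_p <- as.vector(t(outer(pa, pb)))
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / outer_p[nz]))
}

# lexicographic tie-break on near-equal scores
argmax_lex <- function(score, names, tol = 1e-12) {
  best <- max(score)
  tied <- which(score >= best - tol)
  tied[order(names[tied], method = "radix")][1L]
}

#' Minimum-redundancy maximum-relevance feature selection
#'
#' Greedy mutual-information-difference (MID) scheme: the first feature
#' maximizes relevance I(f; y); each later pick maximizes
#' `I(f; y) - mean over selected s of I(f; s)`. Continuous features are
#' discretized into 3 bins at mean +/- one standard deviation; binary
#' features are used as-is. Ties break by lexicographic feature name.
#'
#' @param table A labeled `feature_table` (training data only).
#' @param m Number of features to select.
#' @return A `selection_result`; scores are the greedy MID objective values
#'   at the moment of selection.
#' @export
mrmr_select <- function(table, m) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(table$labels)) stop2("labels required")
  if (m < 1) stop2("m must be >= 1")
  feats <- table$features
  nf <- length(feats)
  if (!nf) return(selection_result(character(), numeric(), "mrmr", m))
  if (m > nf) {
    warn2("m = ", m, " exceeds feature count ", nf, "; returning all features")
    m <- nf
  }
  disc <- apply(table$mat, 2L, discretize_column)
  y <- as.integer(table$labels) + 1L
  relevance <- vapply(seq_len(nf), function(j)
    mutual_information(disc[, j], y), 0)
  selected <- integer(0)
  red_sum <- numeric(nf)          # sum of I(f; s) over selected s
  scores <- numeric(0)
  remaining <- seq_len(nf)
  for (step in seq_len(m)) {
    obj <- if (length(selected)) {
      relevance[remaining] - red_sum[remaining] / length(selected)
    } else {
      relevance[remaining]
    }
    pick <- remaining[argmax_lex(obj, feats[remaining])]
    scores <- c(scores, relevance[pick] -
                  if (length(selected)) red_sum[pick] / length(selected) else 0)
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    if (length(remaining)) {
      for (f in remaining) {
        red_sum[f] <- red_sum[f] + mutual_information(disc[, f], disc[, pick])
      }
    }
  }
  selection_result(feats[selected], scores, "mrmr", m)
}

#' t-statistic variable importance (linear-model fit)
#'
#' Fits one ordinary least-squares model of the 0/1 label on all features
#' (with intercept; a ridge stabilizer of 1e-8 is added to the normal
#' equations). Importance is the absolute t-statistic of each coefficient;
#' the top `m` are returned, ties broken lexicographically.
#'
#' @param table A labeled `feature_table` with `n > features + 1`.
#' @param m Number of features to keep.
#' @return A `selection_result`; scores are `|t|`.
#' @export
varimp_select <- function(table, m) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(table$labels)) stop2("labels required")
  n <- length(table$genes)
  nf <- length(table$features)
  if (!nf) return(selection_result(character(), numeric(), "varimp", m))
  if (n <= nf + 1L) {
    stop2("need n > features + 1 for the OLS fit (n = ", n,
          ", features = ", nf, ")")
  }
  if (m > nf) {
    warn2("m exceeds feature count; returning all features")
    m <- nf
  }
  X <- cbind(`(Intercept)` = 1, table$mat)
  y <- as.numeric(table$labels)
  XtX <- crossprod(X) + diag(1e-8, ncol(X))
  inv <- solve(XtX)
  beta <- inv %*% crossprod(X, y)
  resid <- y - X %*% beta
  sigma2 <- sum(resid^2) / (n - ncol(X))
  se <- sqrt(sigma2 * diag(inv))
  tstat <- as.numeric(beta) / se
  tstat <- tstat[-1L]                      # drop intercept
  if (any(!is.finite(tstat))) {
    stop2("non-finite t-statistics for: ",
          paste(table$features[!is.finite(tstat)], collapse = ", "))
  }
  imp <- abs(tstat)
  ord <- order(-imp, table$features, method = "radix")
  keep <- ord[seq_len(m)]
  selection_result(table$features[keep], imp[keep], "varimp", m)
}

#' Backward stepwise elimination by AIC on a logistic model
#'
#' Starts from the full logistic model and repeatedly drops the feature
#' whose removal gives the minimum AIC, as long as that AIC improves on the
#' current model's; stops at the first step with no improvement. AIC is
#' `2k - 2 lnL` with k counting all coefficients including the intercept.
#'
#' @param table A labeled `feature_table`.
#' @return A `selection_result` holding the surviving features; scores are
#'   the AIC of the model at the time each survivor was last retained
#'   (the final model's AIC, repeated).
#' @export
stepwise_aic_select <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(table$labels)) stop2("labels required")
  feats <- table$features
  if (!length(feats)) {
    return(selection_result(character(), numeric(), "stepwise"))
  }
  y <- as.numeric(table$labels)
  fit_aic <- function(cols) {
    X <- cbind(1, table$mat[, cols, drop = FALSE])
    converged <- TRUE
    fit <- withCallingHandlers(
      suppressWarnings(stats::glm.fit(X, y, family = binomial())),
      warning = function(w) converged <<- FALSE)
    if (!fit$converged) converged <- FALSE
    list(aic = fit$aic, converged = converged)
  }
  current <- feats
  cur <- fit_aic(current)
  repeat {
    if (!length(current)) break
    cand_aic <- rep(NA_real_, length(current))
    for (i in seq_along(current)) {
      res <- tryCatch(fit_aic(setdiff(current, current[i])),
                      error = function(e) NULL)
      if (is.null(res) || !res$converged) {
        warn2("logistic fit without '", current[i],
              "' did not converge; drop candidate skipped")
        next
      }
      cand_aic[i] <- res$aic
    }
    if (all(is.na(cand_aic))) break
    best <- which.min(cand_aic)
    if (cand_aic[best] < cur$aic) {
      current <- setdiff(current, current[best])
      cur <- list(aic = cand_aic[best], converged = TRUE)
    } else {
      break
    }
  }
  selection_result(current, rep(cur$aic, length(current)), "stepwise")
}

#' Percentage of selected keywords per annotation category
#'
#' Summarizes which UniProt keyword categories the selected features draw
#' on. Only features with the `kw_` prefix are counted; percentages sum to
#' 100 whenever at least one keyword was selected.
#'
#' @param sel A `selection_result`.
#' @param kw The `keyword_matrix` the features came from.
#' @return Named numeric vector of percentages (possibly empty).
#' @export
categorize_selected_keywords <- function(sel, kw) {
  stopifnot(inherits(sel, "selection_result"), inherits(kw, "keyword_matrix"))
  kws <- sub("^kw_", "", grep("^kw_", sel$features, value = TRUE))
  if (!length(kws)) return(setNames(numeric(0), character(0)))
  cats <- kw$categories[kws]
  cats[is.na(cats)] <- "Uncategorized"
  tab <- table(cats)
  setNames(100 * as.numeric(tab) / length(kws), names(tab))
}

# dispatch helper used by the CV driver and pipeline
run_feature_selection <- function(table, method, m) {
  switch(method,
    mrmr = mrmr_select(table, m),
    varimp = varimp_select(table, m),
    stepwise = stepwise_aic_select(table),
    none = selection_result(table$features,
                            rep(NA_real_, length(table$features)), "none"),
    stop2("unknown feature-selection method: ", method))
}

#' Restrict a feature table to a selected feature subset
#' @param table A `feature_table`.
#' @param sel A `selection_result` (or character vector of names).
#' @return A `feature_table` with only the selected columns, in selection
#'   order.
#' @export
subset_features <- function(table, sel) {
  names <- if (inherits(sel, "selection_result")) sel$features else sel
  missing <- setdiff(names, table$features)
  if (length(missing)) stop2("unknown features: ",
                             paste(missing, collapse = ", "))
  feature_table(table$genes, table$mat[, names, drop = FALSE], table$labels)
}
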