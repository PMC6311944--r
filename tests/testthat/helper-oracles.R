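# Independent oracles used by both unit and acceptance tests. Each
# recomputes the quantity from its definition by a different route than the
# implementation under test.

# -- MRMR: entropy-based mutual information + from-scratch greedy loop -----
oracle_mi <- function(a, b) {
  H <- function(x) {
    p <- table(x) / length(x)
    -sum(p * log(p))
  }
  H(a) + H(b) - H(paste(a, b))
}

oracle_discretize <- function(x) {
  if (all(x %in% c(0, 1))) return(x)
  cut(x, c(-Inf, mean(x) - sd(x), mean(x) + sd(x), Inf), labels = FALSE)
}

oracle_mrmr <- function(mat, y, m) {
  disc <- apply(mat, 2, oracle_discretize)
  feats <- colnames(mat)
  rel <- sapply(feats, function(f) oracle_mi(disc[, f], y))
  sel <- character(0)
  for (step in seq_len(m)) {
    remaining <- setdiff(feats, sel)
    obj <- sapply(remaining, function(f) {
      red <- if (length(sel)) {
        mean(sapply(sel, function(s) oracle_mi(disc[, f], disc[, s])))
      } else 0
      rel[f] - red
    })
    best <- max(obj)
    tied <- sort(remaining[obj >= best - 1e-12])
    sel <- c(sel, tied[1])
  }
  sel
}

# -- Logistic regression: BFGS on the ridge-penalized log-likelihood ------
oracle_logistic <- function(X, y, l2) {
  nll <- function(b) {
    eta <- X %*% b
    -sum(y * eta - log1p(exp(eta))) + 0.5 * l2 * sum(b[-1]^2)
  }
  grad <- function(b) {
    mu <- plogis(as.numeric(X %*% b))
    g <- -as.numeric(crossprod(X, y - mu))
    g[-1] <- g[-1] + l2 * b[-1]
    g
  }
  stats::optim(rep(0, ncol(X)), nll, grad, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))$par
}

# -- Graph statistics: exhaustive triangle counting and union-find --------
oracle_avg_clustering <- function(net) {
  A <- adj_matrix(net) > 0
  n <- nrow(A)
  cc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(A[v, ])
    k <- length(nb)
    if (k < 2) { cc[v] <- 0; next }
    tri <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      if (A[nb[a], nb[b]]) tri <- tri + 1
    }
    cc[v] <- 2 * tri / (k * (k - 1))
  }
  mean(cc)
}

oracle_components <- function(net) {
  A <- adj_matrix(net) > 0
  n <- nrow(A)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (v in seq_len(n)) for (u in which(A[v, ])) {
      m <- min(comp[v], comp[u])
      if (comp[v] != m || comp[u] != m) {
        comp[v] <- m; comp[u] <- m; changed <- TRUE
      }
    }
    if (!changed) break
  }
  length(unique(comp))
}
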