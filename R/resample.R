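#' Configuration for class-imbalance correction
#'
#' @param method One of `"smote"`, `"rose"`, `"none"`.
#' @param smote_k Neighbor count for SMOTE interpolation (default 5).
#' @param smote_N Oversampling percentage, a multiple of 100; `"auto"`
#'   (default) picks the multiple of 100 that brings the minority class
#'   closest to balance without exceeding the majority count.
#' @param rose_p Target minority fraction of the ROSE output (default 0.5).
#' @param rose_n Output sample count; `NULL` (default) uses the input size.
#' @param bandwidth_shrink Multiplier on the Silverman-type kernel
#'   bandwidth; 0 degenerates ROSE to a plain bootstrap (default 1).
#' @param seed Integer seed.
#' @return A `resample_config`.
#' @export
resample_config <- function(method = c("smote", "rose", "none"),
                            smote_k = 5, smote_N = "auto",
                            rose_p = 0.5, rose_n = NULL,
                            bandwidth_shrink = 1, seed = 1) {
  method <- match.arg(method)
  if (!identical(smote_N, "auto")) {
    if (smote_N %% 100 != 0 || smote_N < 100) {
      stop2("smote_N must be a positive multiple of 100")
    }
  }
  if (rose_p <= 0 || rose_p >= 1) stop2("rose_p must be in (0, 1)")
  if (bandwidth_shrink < 0) stop2("bandwidth_shrink must be >= 0")
  structure(list(method = method, smote_k = as.integer(smote_k),
                 smote_N = smote_N, rose_p = rose_p, rose_n = rose_n,
                 bandwidth_shrink = bandwidth_shrink,
                 seed = as.integer(seed)),
            class = "resample_config")
}

#' SMOTE: synthetic minority oversampling by neighbor interpolation
#'
#' For each minority (label-1) sample, `N/100` synthetic points are added.
#' Each synthetic point picks one of the sample's k nearest minority
#' neighbors (Euclidean distance on the raw feature values) and emits
#' `x + u * (x_nn - x)` with `u ~ Uniform(0, 1)`. All original rows are kept;
#' synthetic rows carry label 1 and generated identifiers. Binary keyword
#' columns interpolate to fractional values, as in the original
#' formulation.
#'
#' @param table A labeled training `feature_table` with >= 2 minority rows.
#' @param cfg A `resample_config` (fields `smote_k`, `smote_N`, `seed`).
#' @param u_fn Uniform generator, exposed for testing the interpolation
#'   geometry (e.g. `function(n) rep(0, n)` duplicates sources exactly).
#' @return A `feature_table` with `minority_count * N / 100` added rows.
#' @export
smote <- function(table, cfg, u_fn = stats::runif) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(table$labels)) stop2("labels required")
  min_idx <- which(table$labels == 1L)
  maj_idx <- which(table$labels == 0L)
  n_min <- length(min_idx)
  if (n_min < 2L) stop2("SMOTE needs at least 2 minority samples")
  N <- cfg$smote_N
  if (identical(N, "auto")) {
    N <- 100 * max(1, floor(length(maj_idx) / n_min) - 1)
  }
  per_sample <- N / 100
  k <- cfg$smote_k
  if (k >= n_min) {
    warn2("k = ", k, " >= minority count ", n_min, "; clamped to ", n_min - 1)
    k <- n_min - 1L
  }
  X <- table$mat[min_idx, , drop = FALSE]
  # k nearest minority neighbors of each minority sample (exact, exhaustive)
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  nn_raw <- apply(D, 1L, function(r) order(r)[seq_len(k)])
  nn <- if (k == 1L) matrix(nn_raw, ncol = 1L) else t(nn_raw)
  synth <- with_seed(cfg$seed, {
    rows <- matrix(NA_real_, n_min * per_sample, ncol(table$mat))
    r <- 0L
    for (i in seq_len(n_min)) {
      for (rep_i in seq_len(per_sample)) {
        j <- nn[i, sample.int(k, 1L)]
        u <- u_fn(1L)
        r <- r + 1L
        rows[r, ] <- X[i, ] + u * (X[j, ] - X[i, ])
      }
    }
    rows
  })
  colnames(synth) <- table$features
  synth_ids <- sprintf("smote_%d", seq_len(nrow(synth)))
  feature_table(c(table$genes, synth_ids),
                rbind(table$mat, synth),
                c(table$labels, rep(1L, nrow(synth))))
}

#' ROSE-style smoothed bootstrap resampling
#'
#' Emits `rose_n` rows. Each row draws class 1 with probability `rose_p`
#' (else class 0), picks a uniformly random training row of that class, and
#' perturbs every feature with independent Gaussian noise of standard
#' deviation `shrink * (4 / ((dim + 2) * n_j))^(1 / (dim + 4)) * sigma_jd`
#' (class j, feature d, class-wise standard deviation sigma). With
#' `bandwidth_shrink = 0` this is a plain class-balanced bootstrap.
#'
#' @param table A labeled `feature_table`; both classes need >= 2 rows so
#'   the class-wise standard deviations exist.
#' @param cfg A `resample_config` (fields `rose_p`, `rose_n`,
#'   `bandwidth_shrink`, `seed`).
#' @return A `feature_table` with exactly `rose_n` rows (generated
#'   identifiers, labels set to the drawn class).
#' @export
rose <- function(table, cfg) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(table$labels)) stop2("labels required")
  idx <- list(`0` = which(table$labels == 0L), `1` = which(table$labels == 1L))
  if (!length(idx$`0`) || !length(idx$`1`)) stop2("both classes required")
  if (any(lengths(idx) < 2L)) {
    stop2("each class needs >= 2 samples for the kernel bandwidth")
  }
  n_out <- cfg$rose_n %||% length(table$genes)
  dim <- ncol(table$mat)
  h <- lapply(idx, function(rows) {
    nj <- length(rows)
    sds <- apply(table$mat[rows, , drop = FALSE], 2L, sd)
    cfg$bandwidth_shrink * (4 / ((dim + 2) * nj))^(1 / (dim + 4)) * sds
  })
  out <- with_seed(cfg$seed, {
    cls <- as.integer(runif(n_out) < cfg$rose_p)
    rows <- matrix(NA_real_, n_out, dim)
    for (r in seq_len(n_out)) {
      pool <- idx[[as.character(cls[r])]]
      src <- pool[sample.int(length(pool), 1L)]
      bw <- h[[as.character(cls[r])]]
      noise <- if (all(bw == 0)) rep(0, dim) else rnorm(dim, 0, bw)
      rows[r, ] <- table$mat[src, ] + noise
    }
    list(cls = cls, rows = rows)
  })
  colnames(out$rows) <- table$features
  feature_table(sprintf("rose_%d", seq_len(n_out)), out$rows, out$cls)
}

# dispatch helper shared by the CV driver and pipeline
run_resampling <- function(table, cfg) {
  switch(cfg$method,
    smote = smote(table, cfg),
    rose = rose(table, cfg),
    none = table,
    stop2("unknown resampling method: ", cfg$method))
}
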