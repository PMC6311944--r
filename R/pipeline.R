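#' Full pipeline configuration
#'
#' One flat object holding every tunable of the end-to-end workflow; each
#' stage picks out the fields it needs. A single `seed` expands
#' deterministically into per-stage seeds via [derive_seed()].
#'
#' @param p,q Walk bias parameters.
#' @param dim Embedding dimensionality.
#' @param walk_length,walks_per_node Walk corpus shape.
#' @param window,negative_samples,epochs,learning_rate Skip-gram training.
#' @param fs_method `"mrmr"`, `"varimp"`, `"stepwise"` or `"none"`.
#' @param fs_m Subset size for mrmr/varimp.
#' @param os_method `"smote"`, `"rose"` or `"none"`.
#' @param smote_k,smote_N,rose_p,bandwidth_shrink Oversampler settings
#'   (see [resample_config()]).
#' @param model `"glm"` or `"knn"`; `l2` and `knn_k` are its settings.
#' @param folds Cross-validation folds.
#' @param seed Global integer seed.
#' @return An `n2vko_config` list.
#' @export
n2vko_config <- function(p = 1, q = 1, dim = 128, walk_length = 80,
                         walks_per_node = 10, window = 10,
                         negative_samples = 5, epochs = 5,
                         learning_rate = 0.025,
                         fs_method = "mrmr", fs_m = 100L,
                         os_method = "rose", smote_k = 5L,
                         smote_N = "auto", rose_p = 0.5,
                         bandwidth_shrink = 1,
                         model = "glm", l2 = 1e-6, knn_k = 5L,
                         folds = 5L, seed = 1L) {
  structure(list(p = p, q = q, dim = as.integer(dim),
                 walk_length = as.integer(walk_length),
                 walks_per_node = as.integer(walks_per_node),
                 window = as.integer(window),
                 negative_samples = as.integer(negative_samples),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 fs_method = fs_method, fs_m = as.integer(fs_m),
                 os_method = os_method, smote_k = as.integer(smote_k),
                 smote_N = smote_N, rose_p = rose_p,
                 bandwidth_shrink = bandwidth_shrink,
                 model = model, l2 = l2, knn_k = as.integer(knn_k),
                 folds = as.integer(folds), seed = as.integer(seed)),
            class = "n2vko_config")
}

config_embed <- function(config, seed) {
  list(walk = walk_config(p = config$p, q = config$q,
                          walks_per_node = config$walks_per_node,
                          walk_length = config$walk_length,
                          seed = derive_seed(seed, "walks")),
       sg = skipgram_config(dim = config$dim, window = config$window,
                            negative_samples = config$negative_samples,
                            epochs = config$epochs,
                            initial_learning_rate = config$learning_rate,
                            seed = derive_seed(seed, "skipgram")))
}

config_resample <- function(config, seed) {
  if (config$os_method == "none") return(list(method = "none"))
  resample_config(method = config$os_method, smote_k = config$smote_k,
                  smote_N = config$smote_N, rose_p = config$rose_p,
                  bandwidth_shrink = config$bandwidth_shrink,
                  seed = derive_seed(seed, "oversample"))
}

config_pipe <- function(config, seed, fs, os) {
  cv_pipe(fs_method = fs, fs_m = config$fs_m,
          oversample = if (os == "none") list(method = "none") else {
            resample_config(method = os, smote_k = config$smote_k,
                            smote_N = config$smote_N, rose_p = config$rose_p,
                            bandwidth_shrink = config$bandwidth_shrink,
                            seed = derive_seed(seed, "oversample"))
          },
          model_method = config$model, l2 = config$l2, k = config$knn_k)
}

#' Evaluate one of the four feature/oversampling scenarios
#'
#' The scenarios isolate the contribution of each pipeline component:
#' * `node2vec` — embeddings only, no feature selection, no oversampling;
#' * `n2vo` — embeddings plus oversampling, no feature selection;
#' * `n2vk` — embedding + keyword features with feature selection, no
#'   oversampling;
#' * `n2vko` — embedding + keyword features with feature selection followed
#'   by oversampling of the selected training subset.
#'
#' @param net A `ppi_network`.
#' @param kw A `keyword_matrix` (required for `n2vk`/`n2vko`, may be `NULL`
#'   otherwise).
#' @param disease A `gene_set`.
#' @param scenario One of the four scenario names.
#' @param config An `n2vko_config`.
#' @param seed Global seed (default `config$seed`).
#' @param emb Optional precomputed `embedding_matrix` (skips the walk and
#'   training stage; useful when comparing scenarios on one embedding).
#' @return A `cv_result` with scenario and config provenance attached.
#' @export
run_scenario <- function(net, kw, disease,
                         scenario = c("node2vec", "n2vo", "n2vk", "n2vko"),
                         config = n2vko_config(), seed = config$seed,
                         emb = NULL) {
  scenario <- match.arg(scenario)
  needs_kw <- scenario %in% c("n2vk", "n2vko")
  if (needs_kw && is.null(kw)) {
    stop2("scenario '", scenario, "' requires keyword annotations")
  }
  if (!needs_kw && config$fs_method != "none" &&
      scenario %in% c("node2vec", "n2vo")) {
    warn2("feature selection is not part of scenario '", scenario,
          "'; ignored")
  }
  if (is.null(emb)) {
    ec <- config_embed(config, seed)
    emb <- embed_network(net, ec$walk, ec$sg)
  }
  features <- if (needs_kw) build_n2vk(emb, kw) else embedding_features(emb)
  labeled <- attach_labels(features, disease)
  fs <- if (needs_kw) config$fs_method else "none"
  os <- if (scenario %in% c("n2vo", "n2vko")) config$os_method else "none"
  pipe <- config_pipe(config, seed, fs, os)
  cv <- stratified_kfold_cv(labeled, pipe, folds = config$folds, seed = seed)
  cv$config$scenario <- scenario
  cv$config$p <- config$p
  cv$config$q <- config$q
  cv
}

#' Grid-tune the walk bias parameters p and q
#'
#' Evaluates the mean cross-validated AUC of the logistic classifier on
#' embedding-only features for every `(p, q)` grid point and returns the
#' argmax (ties: smaller p, then smaller q). Note the tuning criterion is
#' the same CV AUC later reported, so the tuned figure carries an
#' optimistic selection bias; an untouched hold-out is the remedy when one
#' is affordable.
#'
#' @param net A `ppi_network`.
#' @param disease A `gene_set`.
#' @param grid Data frame with columns `p` and `q` (default the 5x5 grid
#'   over `{0.25, 0.5, 1, 2, 4}`).
#' @param config An `n2vko_config` (walk/training/CV settings).
#' @param seed Global seed.
#' @return A list: `p`, `q`, `embedding` (of the winner), `cv` (its
#'   `cv_result`) and `results` (the full grid with mean AUCs).
#' @export
tune_pq <- function(net, disease, grid = default_pq_grid(),
                    config = n2vko_config(), seed = config$seed) {
  grid <- as.data.frame(grid)
  if (!nrow(grid)) stop2("empty grid")
  mean_auc <- numeric(nrow(grid))
  cvs <- vector("list", nrow(grid))
  embs <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg_i <- config
    cfg_i$p <- grid$p[i]; cfg_i$q <- grid$q[i]
    cfg_i$fs_method <- "none"     # tuning is on embedding-only features
    ec <- config_embed(cfg_i, seed)
    embs[[i]] <- embed_network(net, ec$walk, ec$sg)
    cvs[[i]] <- run_scenario(net, NULL, disease, "node2vec", cfg_i,
                             seed = seed, emb = embs[[i]])
    mean_auc[i] <- cvs[[i]]$mean_auc
  }
  ord <- order(-mean_auc, grid$p, grid$q)
  best <- ord[1L]
  list(p = grid$p[best], q = grid$q[best], embedding = embs[[best]],
       cv = cvs[[best]],
       results = data.frame(p = grid$p, q = grid$q, mean_auc = mean_auc))
}

#' @rdname tune_pq
#' @export
default_pq_grid <- function() {
  vals <- c(0.25, 0.5, 1, 2, 4)
  expand.grid(p = vals, q = vals, KEEP.OUT.ATTRS = FALSE)
}

#' Search the best feature-selection / oversampling combination
#'
#' Runs the full scenario (feature selection then oversampling, both inside
#' the training folds) for every pair from `fs_methods` x `os_methods` on a
#' single shared embedding, and returns the pair with the highest mean CV
#' AUC (ties: lexicographic method names, feature selection first).
#'
#' @param net,kw,disease Network, keyword matrix and disease set.
#' @param fs_methods,os_methods Non-empty character vectors.
#' @param config An `n2vko_config`.
#' @param seed Global seed.
#' @return A list: `fs_method`, `os_method`, `cv` (best `cv_result`) and
#'   `results` (data frame over all pairs).
#' @export
select_best_combination <- function(net, kw, disease,
                                    fs_methods = c("mrmr", "varimp"),
                                    os_methods = c("smote", "rose"),
                                    config = n2vko_config(),
                                    seed = config$seed) {
  if (!length(fs_methods) || !length(os_methods)) {
    stop2("method lists must be non-empty")
  }
  ec <- config_embed(config, seed)
  emb <- embed_network(net, ec$walk, ec$sg)
  combos <- expand.grid(fs = fs_methods, os = os_methods,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cvs <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    cfg_i <- config
    cfg_i$fs_method <- combos$fs[i]
    cfg_i$os_method <- combos$os[i]
    cvs[[i]] <- run_scenario(net, kw, disease, "n2vko", cfg_i,
                             seed = seed, emb = emb)
  }
  mean_auc <- vapply(cvs, `[[`, 0, "mean_auc")
  ord <- order(-mean_auc, combos$fs, combos$os, method = "radix")
  best <- ord[1L]
  list(fs_method = combos$fs[best], os_method = combos$os[best],
       cv = cvs[[best]],
       results = data.frame(fs = combos$fs, os = combos$os,
                            mean_auc = mean_auc))
}

#' Rank candidate disease genes with the final model
#'
#' Trains the configured pipeline on all labeled data (feature selection on
#' all data, oversampling on all data, logistic fit — the standard
#' full-data refit after evaluation) and scores every gene not in the
#' disease set. Known positives are excluded from the output.
#'
#' @param net,kw,disease Network, keyword matrix (or `NULL` for
#'   embedding-only features) and disease set.
#' @param config An `n2vko_config` fixing p, q, the feature selector and
#'   the oversampler.
#' @param seed Global seed.
#' @param emb Optional precomputed embedding.
#' @return A `ranked_predictions` data frame: `gene`, `score`, `rank`
#'   (scores non-increasing; score ties broken by gene identifier).
#' @export
rank_candidates <- function(net, kw, disease, config = n2vko_config(),
                            seed = config$seed, emb = NULL) {
  if (is.null(emb)) {
    ec <- config_embed(config, seed)
    emb <- embed_network(net, ec$walk, ec$sg)
  }
  features <- if (is.null(kw)) embedding_features(emb) else
    build_n2vk(emb, kw)
  labeled <- attach_labels(features, disease)
  sel <- run_feature_selection(labeled, config$fs_method, config$fs_m)
  train <- subset_features(labeled, sel)
  os <- config_resample(config, seed)
  if (os$method != "none") train <- run_resampling(train, os)
  model <- switch(config$model,
    glm = fit_logistic(train, config$l2),
    knn = fit_knn(train, config$knn_k),
    stop2("unknown model: ", config$model))
  cand <- setdiff(labeled$genes, disease$members)
  cand_tab <- feature_table(cand,
                            labeled$mat[match(cand, labeled$genes),
                                        sel$features, drop = FALSE])
  scores <- predict(model, cand_tab)
  ord <- order(-scores, cand, method = "radix")
  out <- data.frame(gene = cand[ord], score = as.numeric(scores[ord]),
                    rank = seq_along(cand))
  attr(out, "config") <- config
  attr(out, "selected") <- sel$features
  class(out) <- c("ranked_predictions", "data.frame")
  out
}
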