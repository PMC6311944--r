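test_that("intercept-only logistic fit on balanced labels scores everyone 0.5", {
  n <- 30
  ft <- feature_table(sprintf("g%02d", 1:n), matrix(numeric(0), n, 0),
                      rep(c(0L, 1L), n / 2))
  model <- fit_logistic(ft)
  expect_equal(unname(model$coefficients), 0, tolerance = 1e-8)
  expect_equal(unname(predict(model, ft)), rep(0.5, n), tolerance = 1e-8)
})

test_that("logistic coefficients match an independent optimizer oracle", {
  set.seed(20)
  n <- 500
  X <- cbind(rnorm(n), rnorm(n))
  beta_true <- c(-0.5, 1.2, -2)
  y <- rbinom(n, 1, plogis(beta_true[1] + X %*% beta_true[-1]))
  colnames(X) <- c("f1", "f2")
  ft <- feature_table(sprintf("g%03d", 1:n), X, y)
  model <- fit_logistic(ft, l2 = 1e-6)
  oracle <- oracle_logistic(cbind(1, X), y, 1e-6)
  expect_lt(max(abs(model$coefficients - oracle)), 1e-4)
})

test_that("one-class labels are rejected", {
  ft <- feature_table(c("a", "b"), matrix(rnorm(2), 2, 1,
                      dimnames = list(NULL, "x")), c(1L, 1L))
  expect_error(fit_logistic(ft), "both classes")
})

test_that("logistic scores are invariant to shifting a feature", {
  set.seed(21)
  n <- 200
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  y <- rbinom(n, 1, plogis(X[, 1]))
  ft <- feature_table(sprintf("g%03d", 1:n), X, y)
  Xs <- X; Xs[, 1] <- Xs[, 1] + 10
  fts <- feature_table(ft$genes, Xs, y)
  s1 <- predict(fit_logistic(ft), ft)
  s2 <- predict(fit_logistic(fts), fts)
  expect_lt(max(abs(s1 - s2)), 1e-6)
})

test_that("kNN scoring follows the exhaustive-distance definition", {
  mat <- matrix(c(0, 0, 1, 0, 0, 1, 5, 5, 6, 5), 5, 2, byrow = TRUE,
                dimnames = list(NULL, c("x", "y")))
  ft <- feature_table(sprintf("g%d", 1:5), mat, c(1L, 1L, 0L, 0L, 1L))
  # k=1 on a training point itself
  m1 <- fit_knn(ft, 1)
  expect_equal(unname(predict(m1, ft)[1]), 1.0)
  # k=n gives the global positive fraction everywhere
  mn <- fit_knn(ft, 5)
  expect_equal(unname(predict(mn, ft)), rep(3 / 5, 5))
  # k=3: brute-force oracle on a query point
  m3 <- fit_knn(ft, 3)
  q <- feature_table("q", matrix(c(0.4, 0.1), 1, 2,
                     dimnames = list(NULL, c("x", "y"))))
  d <- sqrt(rowSums((mat - matrix(c(0.4, 0.1), 5, 2, byrow = TRUE))^2))
  want <- mean(ft$labels[order(d)[1:3]])
  expect_equal(unname(predict(m3, q)), want)
  expect_error(fit_knn(ft, 0), "k must be")
  expect_error(fit_knn(ft, 6), "exceeds")
})

test_that("scoring rejects feature-name mismatches", {
  ft <- random_table(20, 3, seed = 22)
  model <- fit_logistic(ft)
  wrong <- feature_table(ft$genes, ft$mat[, c(2, 1, 3)])
  expect_error(predict(model, wrong), "do not match")
})

test_that("AUC equals the pair-counting definition, with ties at half", {
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_equal(auc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 0.75)
  # random score vectors vs exhaustive pair counting
  for (s in 1:10) {
    set.seed(300 + s)
    n <- 40
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    scores <- round(runif(n), 2)  # force some ties
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(auc(scores, labels), mean(pairs))
    # complement property (ties counted half on both sides)
    expect_equal(auc(scores, labels) + auc(-scores, labels), 1)
  }
  expect_error(auc(c(1, 2), c(1, 1)), "both classes")
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  labels <- rbinom(100, 1, 0.3)
  scores <- rnorm(100) + labels
  expect_equal(auc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              quiet = TRUE, direction = "<"))))
})

test_that("stratified folds hold 80% of genes per class in training and partition the set", {
  ft <- make_imbalanced_gaussian(100, 900, dim = 2, shift = 0.5, seed = 24)
  cv <- stratified_kfold_cv(ft, cv_pipe(), folds = 5, seed = 7)
  assign <- cv$fold_assignments
  expect_setequal(names(assign), ft$genes)
  for (f in 1:5) {
    expect_equal(sum(assign != f), 800)
    expect_equal(sum(assign == f & ft$labels == 1L), 20)
  }
  # union of test folds = all genes, pairwise disjoint (assignment is a map)
  expect_equal(sort(unique(assign)), 1:5)
  expect_length(assign, 1000)
})

test_that("fold assignment depends only on labels and seed, not features", {
  ft1 <- make_imbalanced_gaussian(20, 80, dim = 3, shift = 1, seed = 25)
  ft2 <- feature_table(ft1$genes, ft1$mat * 100 + 3, ft1$labels)
  cv1 <- stratified_kfold_cv(ft1, cv_pipe(), folds = 5, seed = 9)
  cv2 <- stratified_kfold_cv(ft2, cv_pipe(), folds = 5, seed = 9)
  expect_identical(cv1$fold_assignments, cv2$fold_assignments)
  cv3 <- stratified_kfold_cv(ft1, cv_pipe(), folds = 5, seed = 10)
  expect_false(identical(cv1$fold_assignments, cv3$fold_assignments))
})

test_that("cross-validation errors when a class has fewer members than folds", {
  ft <- make_imbalanced_gaussian(3, 50, dim = 2, shift = 1, seed = 26)
  expect_error(stratified_kfold_cv(ft, cv_pipe(), folds = 5, seed = 1),
               "fewer folds")
})

test_that("mean AUC is the arithmetic mean of fold AUCs, all within [0, 1]", {
  ft <- make_imbalanced_gaussian(25, 100, dim = 4, shift = 2, seed = 27)
  cv <- stratified_kfold_cv(ft, cv_pipe(fs_method = "varimp", fs_m = 3),
                            folds = 5, seed = 2)
  expect_equal(cv$mean_auc, mean(cv$fold_auc))
  expect_true(all(cv$fold_auc >= 0 & cv$fold_auc <= 1))
  expect_gt(cv$mean_auc, 0.9)  # shift 2 in 4 dims separates well
})
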