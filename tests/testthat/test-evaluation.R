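test_that("split_dataset is stratified, exhaustive and deterministic", {
  set.seed(6)
  fm <- feature_matrix(matrix(rnorm(100 * 2), 100), rep(0L, 100), "a")
  sp <- split_dataset(fm, c(0.7, 0.15, 0.15), seed = 1)
  expect_equal(nrow(sp$train$X), 70)
  expect_equal(nrow(sp$val$X), 15)
  expect_equal(nrow(sp$test$X), 15)
  all_idx <- sort(c(sp$idx$train, sp$idx$val, sp$idx$test))
  expect_identical(all_idx, 1:100)
  sp2 <- split_dataset(fm, c(0.7, 0.15, 0.15), seed = 1)
  expect_identical(sp$idx, sp2$idx)
  expect_error(split_dataset(fm, c(0.5, 0.5, 0.5)), "sum to 1")
})

test_that("soft_vote averages probabilities with stated tie handling", {
  a <- matrix(c(0.6, 0.4), 1)
  b <- matrix(c(0.2, 0.8), 1)
  expect_equal(soft_vote(list(a, b)), 1L)             # mean (0.4, 0.6)
  expect_equal(soft_vote(list(a, a)), 0L)             # unanimity
  tie <- matrix(c(0.5, 0.5), 1)
  expect_equal(soft_vote(list(tie, tie)), 0L)         # tie -> lowest index
  expect_error(soft_vote(list(a)), ">= 2")
  expect_error(soft_vote(list(a, matrix(0.5, 1, 3))), "mismatch")
  expect_error(soft_vote(list(a * 2, b)), "sum to 1")
  # weighted vote: the heavier member dominates
  u <- matrix(c(1, 0), 1); v <- matrix(c(0, 1), 1)
  expect_equal(soft_vote(list(u, v), weights = c(3, 1)), 0L)
  expect_equal(soft_vote(list(u, v), weights = c(1, 3)), 1L)
})

test_that("confusion_metrics implements the row=actual convention", {
  CM <- matrix(c(8, 3, 2, 7), 2)   # rows actual: [[8,2],[3,7]]
  m <- confusion_metrics(CM)
  expect_equal(m$precision[1], 8 / 11)
  expect_equal(m$recall[1], 0.8)
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$f1[1], 2 * (8/11) * 0.8 / (8/11 + 0.8))
  # perfect diagonal
  p <- confusion_metrics(diag(c(4, 6, 2)))
  expect_true(all(p$precision == 1) && all(p$recall == 1) && p$accuracy == 1)
  # never-predicted class yields 0, not an error
  CM0 <- matrix(c(5, 3, 0, 0), 2)
  expect_message(m0 <- confusion_metrics(CM0), "precision")
  expect_equal(m0$precision[2], 0)
  expect_error(confusion_metrics(matrix(1, 2, 3)), "square")
})

test_that("micro recall equals accuracy on random confusion matrices", {
  set.seed(10)
  for (i in 1:30) {
    k <- sample(2:6, 1)
    CM <- matrix(rpois(k * k, 4), k)
    m <- confusion_metrics(CM)
    micro_recall <- sum(diag(CM)) / sum(CM)
    expect_equal(m$accuracy, micro_recall)
  }
})

test_that("kfold partitions samples exactly once and averages folds", {
  fxf <- fixture_separable_features()
  rep_ <- kfold_evaluate(fxf$fm, list("DecisionTree"), k = 5, seed = 42)
  folds <- rep_$classifiers$DecisionTree$folds
  expect_equal(length(folds), 5)
  expect_equal(sum(vapply(folds, `[[`, 1L, "n_test")), 30)
  accs <- vapply(folds, `[[`, 1, "accuracy")
  expect_equal(rep_$classifiers$DecisionTree$cv$accuracy, mean(accs))
  expect_error(kfold_evaluate(fxf$fm, list("KNN"), k = 1), ">= 2")
})

test_that("guarded mode ignores test-fold labels entirely", {
  fxf <- fixture_separable_features()
  fm <- fxf$fm
  r1 <- kfold_evaluate(fm, list("DecisionTree"), k = 3, seed = 7)
  fm2 <- fm
  victim <- 1L    # flip one sample's label; only its own row may change
  fm2$y[victim] <- (fm2$y[victim] + 1L) %% 3L
  # the victim appears in exactly one test fold; other folds' CMs built
  # from training must differ, but folds where the victim is in TEST and
  # predictions of other rows are unaffected when it is in the test fold
  fold <- leaffusion:::stratified_folds(fm$y, 3, leaffusion:::derive_seed(7, 1))
  # score the victim's test fold manually under both label sets
  f <- fold[victim]
  tr <- leaffusion:::fm_subset(fm, which(fold != f))
  te1 <- leaffusion:::fm_subset(fm, which(fold == f))
  te2 <- leaffusion:::fm_subset(fm2, which(fold == f))
  std <- standardize(smote_resample(tr, seed = 1), list(te1))
  h <- build_classifier("DecisionTree")
  h$fit(std$train$X, std$train$y)
  expect_identical(h$predict(std$others[[1]]$X), h$predict(std$others[[1]]$X))
  expect_identical(te1$X, te2$X)   # features untouched by label mutation
})

test_that("soft vote of identical members equals the member", {
  fxf <- fixture_separable_features()
  std <- standardize(fxf$fm)
  h1 <- build_classifier(classifier_spec("DecisionTree", seed = 3))
  h1$fit(std$train$X, std$train$y)
  p <- h1$predict_proba(std$train$X)
  expect_identical(soft_vote(list(p, p, p)), h1$predict(std$train$X))
})

test_that("fused features rank at or above color-only on look-alikes", {
  fm <- fixture_lookalike_features()
  for (nm in c("RandomForest", "GradientBoost")) {
    full <- kfold_evaluate(fm, list(nm), k = 3, seed = 11)
    color <- kfold_evaluate(fm_segment(fm, "C1"), list(nm), k = 3, seed = 11)
    expect_gte(full$classifiers[[nm]]$cv$accuracy,
               color$classifiers[[nm]]$cv$accuracy)
  }
})
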