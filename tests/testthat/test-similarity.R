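test_that("class means are arithmetic and order-invariant", {
  X <- rbind(c(0, 0), c(2, 4), c(10, 10))
  fm <- feature_matrix(X, c(0L, 0L, 1L), c("a", "b"))
  M <- class_mean_vectors(fm)
  expect_equal(M["a", ], c(1, 2), ignore_attr = TRUE)
  expect_equal(M["b", ], c(10, 10), ignore_attr = TRUE)
  perm <- c(3, 1, 2)
  fm2 <- feature_matrix(X[perm, ], fm$y[perm], fm$class_names)
  expect_equal(class_mean_vectors(fm2), M)
})

test_that("synthetic rows are excluded from means unless requested", {
  X <- rbind(c(0, 0), c(2, 2), c(100, 100))
  fm <- feature_matrix(X, c(0L, 0L, 0L), "a",
                       synthetic = c(FALSE, FALSE, TRUE))
  fm$y <- c(0L, 0L, 0L)
  b <- feature_matrix(rbind(c(5, 5)), 1L, c("a", "b"))
  fm_all <- feature_matrix(rbind(X, c(5, 5)), c(0L, 0L, 0L, 1L), c("a", "b"),
                           synthetic = c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(class_mean_vectors(fm_all)["a", ], c(1, 1), ignore_attr = TRUE)
  expect_equal(class_mean_vectors(fm_all, include_synthetic = TRUE)["a", ],
               c(34, 34), ignore_attr = TRUE)
})

test_that("interclass similarity maps cosine onto [0, 1] correctly", {
  M <- rbind(a = c(1, 0), b = c(1, 0), c = c(-1, 0), d = c(0, 1))
  S <- interclass_similarity(M)
  expect_equal(S["a", "b"], 1.0)     # identical means
  expect_equal(S["a", "c"], 0.0)     # opposite means
  expect_equal(S["a", "d"], 0.5)     # orthogonal means
  expect_equal(diag(unclass(S)), rep(1, 4), ignore_attr = TRUE)
  expect_error(interclass_similarity(rbind(a = c(0, 0), b = c(1, 1))),
               "zero-norm")
})

test_that("similarity matrix is symmetric, bounded and scale invariant", {
  set.seed(21)
  M <- matrix(rnorm(5 * 40), 5, dimnames = list(paste0("c", 1:5), NULL))
  S <- interclass_similarity(M)
  expect_true(all(S >= 0 & S <= 1))
  expect_lt(max(abs(S - t(S))), 1e-12)
  S3 <- interclass_similarity(M * 3)
  expect_lt(max(abs(unclass(S) - unclass(S3))), 1e-12)
})

test_that("top_confusable_pairs ranks deterministically", {
  S <- diag(3) * 0 + 1
  S[1, 2] <- S[2, 1] <- 0.97
  S[1, 3] <- S[3, 1] <- 0.60
  S[2, 3] <- S[3, 2] <- 0.40
  diag(S) <- 1
  dimnames(S) <- list(c("x", "y", "z"), c("x", "y", "z"))
  class(S) <- c("similarity_matrix", "matrix")
  tp <- top_confusable_pairs(S)
  expect_equal(tp$similarity, c(0.97, 0.60, 0.40))
  expect_equal(top_confusable_pairs(S, threshold = 0.95)$class_b, "y")
  # all-equal off-diagonals fall back to name order
  E <- matrix(0.5, 3, 3, dimnames = dimnames(S)); diag(E) <- 1
  class(E) <- c("similarity_matrix", "matrix")
  te <- top_confusable_pairs(E)
  expect_equal(paste(te$class_a, te$class_b),
               c("x y", "x z", "y z"))
})

test_that("look-alike pair dominates color-segment similarity", {
  fm <- fixture_lookalike_features()
  sep <- fixture_separable_features()$fm
  # build a 4-class matrix: the color-matched pair plus two distinct-hue
  # classes, on the color segment alone
  k <- 2
  Xa <- fm_segment(fm, "C1")
  base <- class_mean_vectors(Xa)
  other <- class_mean_vectors(fm_segment(sep, "C1"))[1:2, 1:ncol(base)]
  M <- rbind(base, other)
  S <- interclass_similarity(M)
  look <- S[1, 2]
  cross <- S[cbind(c(1, 1, 2, 2), c(3, 4, 3, 4))]
  expect_true(all(look > cross))
})
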