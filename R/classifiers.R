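#' Classifier specification
#'
#' Names one of the supported models and fills in the reference
#' hyperparameters: SVM (RBF kernel, `C = 10`, `gamma = 0.1`), random
#' forest (100 trees), KNN (5 neighbours), logistic regression (max_iter
#' 1000), decision tree (Gini, unlimited depth, min split 2, seed 42),
#' gradient boosting (100 stages, rate 0.1, depth 3, seed 42), AdaBoost
#' (50 stumps, rate 1.0, seed 42), Gaussian naive Bayes (no parameters),
#' and `SoftVote` (probability-averaging ensemble, default members SVM,
#' RandomForest, GradientBoost).
#'
#' @param name one of `"AdaBoost"`, `"DecisionTree"`, `"GradientBoost"`,
#'   `"KNN"`, `"LogisticRegression"`, `"NaiveBayes"`, `"SVM"`,
#'   `"RandomForest"`, `"SoftVote"`.
#' @param ... hyperparameter overrides (see defaults above).
#' @param seed integer seed for the model's own randomness.
#' @return a `classifier_spec` list.
#' @export
classifier_spec <- function(name, ..., seed = 42L) {
  valid <- c("AdaBoost", "DecisionTree", "GradientBoost", "KNN",
             "LogisticRegression", "NaiveBayes", "SVM", "RandomForest",
             "SoftVote")
  if (!name %in% valid)
    lf_abort("unknown classifier '", name, "'; valid names: ",
             paste(valid, collapse = ", "))
  defaults <- switch(name,
    SVM = list(kernel = "RBF", C = 10, gamma = 0.1),
    RandomForest = list(n_estimators = 100L),
    KNN = list(n_neighbors = 5L),
    LogisticRegression = list(max_iter = 1000L, lambda = 1e-4),
    NaiveBayes = list(),
    DecisionTree = list(criterion = "gini", max_depth = NULL,
                        min_samples_split = 2L),
    GradientBoost = list(n_estimators = 100L, learning_rate = 0.1,
                         max_depth = 3L),
    AdaBoost = list(n_estimators = 50L, learning_rate = 1.0),
    SoftVote = list(members = c("SVM", "RandomForest", "GradientBoost"),
                    weights = NULL))
  hyper <- utils::modifyList(defaults, list(...))
  structure(list(name = name, hyper = hyper, seed = as.integer(seed)),
            class = "classifier_spec")
}

# ---- handle plumbing --------------------------------------------------

new_handle <- function(spec, fit_fn, proba_fn) {
  e <- new.env(parent = emptyenv())
  e$model <- NULL
  h <- list(spec = spec,
    fit = function(X, y) {
      e$model <- fit_fn(as.matrix(X), as.integer(y))
      invisible(h)
    },
    predict_proba = function(X) {
      if (is.null(e$model)) lf_abort("model not fitted")
      p <- proba_fn(e$model, as.matrix(X))
      colnames(p) <- NULL
      p
    },
    predict = function(X) {
      p <- h$predict_proba(X)
      max.col(p, ties.method = "first") - 1L   # tie -> lowest class index
    },
    is_fitted = function() !is.null(e$model))
  class(h) <- "lf_classifier"
  h
}

#' @export
print.lf_classifier <- function(x, ...) {
  cat("<lf_classifier> ", x$spec$name,
      if (x$is_fitted()) " (fitted)" else " (unfitted)", "\n", sep = "")
  invisible(x)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# ---- tree-based models ------------------------------------------------

fit_cart_tree <- function(X, y, w, K, mtry, max_depth, min_split, seed) {
  cart_build(X, as.integer(y), numeric(nrow(X)), w, K, mtry,
             max_depth, min_split, seed, seq_len(nrow(X)) - 1L)
}

fit_decision_tree <- function(spec) function(X, y) {
  K <- max(y) + 1L
  md <- spec$hyper$max_depth %||% 1000000L
  tree <- fit_cart_tree(X, y, rep(1, nrow(X)), K, ncol(X), md,
                        spec$hyper$min_samples_split, spec$seed)
  list(tree = tree, K = K)
}

proba_decision_tree <- function(model, X) cart_values(model$tree, X)

fit_random_forest <- function(spec) function(X, y) {
  K <- max(y) + 1L
  n <- nrow(X)
  mtry <- max(1L, floor(sqrt(ncol(X))))
  trees <- vector("list", spec$hyper$n_estimators)
  for (t in seq_along(trees)) {
    s <- derive_seed(spec$seed, t)
    boot <- with_seed(s, sample.int(n, n, replace = TRUE))
    trees[[t]] <- cart_build(X, as.integer(y), numeric(n), rep(1, n), K,
                             mtry, 1000000L, 2L, s, boot - 1L)
  }
  list(trees = trees, K = K)
}

proba_random_forest <- function(model, X) {
  P <- matrix(0, nrow(X), model$K)
  for (tr in model$trees) P <- P + cart_values(tr, X)
  P / length(model$trees)
}

fit_gradient_boost <- function(spec) function(X, y) {
  K <- max(y) + 1L
  n <- nrow(X)
  nu <- spec$hyper$learning_rate
  prior <- pmax(tabulate(y + 1L, K) / n, 1e-12)
  F0 <- log(prior)
  Fm <- matrix(F0, n, K, byrow = TRUE)
  stages <- vector("list", spec$hyper$n_estimators)
  Ymat <- outer(y, 0:(K - 1), `==`) * 1
  ones <- rep(1, n)
  for (m in seq_along(stages)) {
    P <- softmax_rows(Fm)
    stage <- vector("list", K)
    for (k in seq_len(K)) {
      r <- Ymat[, k] - P[, k]
      tree <- cart_build(X, integer(n), r, ones, 0L, ncol(X),
                         spec$hyper$max_depth, 2L,
                         derive_seed(spec$seed, m, k), seq_len(n) - 1L)
      leaf <- cart_leaf(tree, X)
      # Friedman's Newton step per terminal region
      num <- tapply(r, leaf, sum)
      den <- tapply(abs(r) * (1 - abs(r)), leaf, sum)
      gamma <- (K - 1) / K * num / pmax(den, 1e-12)
      gmap <- stats::setNames(as.numeric(gamma), names(num))
      Fm[, k] <- Fm[, k] + nu * gmap[as.character(leaf)]
      stage[[k]] <- list(tree = tree, gamma = gmap)
    }
    stages[[m]] <- stage
  }
  list(stages = stages, F0 = F0, K = K, nu = nu)
}

proba_gradient_boost <- function(model, X) {
  Fm <- matrix(model$F0, nrow(X), model$K, byrow = TRUE)
  for (stage in model$stages)
    for (k in seq_len(model$K)) {
      st <- stage[[k]]
      leaf <- cart_leaf(st$tree, X)
      g <- st$gamma[as.character(leaf)]
      g[is.na(g)] <- 0
      Fm[, k] <- Fm[, k] + model$nu * g
    }
  softmax_rows(Fm)
}

fit_adaboost <- function(spec) function(X, y) {
  K <- max(y) + 1L
  n <- nrow(X)
  lr <- spec$hyper$learning_rate
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  for (m in seq_len(spec$hyper$n_estimators)) {
    tree <- fit_cart_tree(X, y, w, K, ncol(X), 1L, 2L,
                          derive_seed(spec$seed, m))
    pred <- max.col(cart_values(tree, X), ties.method = "first") - 1L
    miss <- pred != y
    err <- sum(w * miss)
    if (err >= 1 - 1 / K) break                 # worse than chance: stop
    err <- max(err, 1e-10)
    a <- lr * (log((1 - err) / err) + log(K - 1))
    stumps[[length(stumps) + 1]] <- tree
    alphas <- c(alphas, a)
    if (err <= 1e-10) break                     # perfect stump
    w <- w * exp(a * miss)
    w <- w / sum(w)
  }
  list(stumps = stumps, alphas = alphas, K = K)
}

proba_adaboost <- function(model, X) {
  V <- matrix(0, nrow(X), model$K)
  for (i in seq_along(model$stumps)) {
    pred <- max.col(cart_values(model$stumps[[i]], X),
                    ties.method = "first")
    V[cbind(seq_len(nrow(X)), pred)] <-
      V[cbind(seq_len(nrow(X)), pred)] + model$alphas[i]
  }
  s <- rowSums(V)
  s[s == 0] <- 1
  V / s
}

# ---- distance / probabilistic models ----------------------------------

fit_knn <- function(spec) function(X, y)
  list(X = X, y = y, K = max(y) + 1L, k = spec$hyper$n_neighbors)

proba_knn <- function(model, X) {
  k <- min(model$k, nrow(model$X))
  nn <- FNN::get.knnx(model$X, X, k = k)$nn.index
  P <- matrix(0, nrow(X), model$K)
  for (j in seq_len(k)) {
    lab <- model$y[nn[, j]] + 1L
    P[cbind(seq_len(nrow(X)), lab)] <- P[cbind(seq_len(nrow(X)), lab)] + 1
  }
  P / k
}

fit_naive_bayes <- function(spec) function(X, y) {
  K <- max(y) + 1L
  mu <- var_ <- matrix(0, K, ncol(X))
  prior <- numeric(K)
  for (k in seq_len(K)) {
    rows <- X[y == k - 1L, , drop = FALSE]
    mu[k, ] <- colMeans(rows)
    v <- apply(rows, 2, stats::var)
    v[!is.finite(v)] <- 0
    var_[k, ] <- v
    prior[k] <- nrow(rows) / nrow(X)
  }
  eps <- 1e-9 * max(var_, 1e-12)               # variance smoothing
  list(mu = mu, var = var_ + eps, prior = prior, K = K)
}

proba_naive_bayes <- function(model, X) {
  n <- nrow(X)
  L <- matrix(0, n, model$K)
  for (k in seq_len(model$K)) {
    v <- model$var[k, ]
    d <- sweep(X, 2, model$mu[k, ])
    L[, k] <- log(model$prior[k]) -
      0.5 * sum(log(2 * pi * v)) -
      0.5 * (d^2 %*% (1 / v))
  }
  softmax_rows(L)
}

fit_logistic <- function(spec) function(X, y) {
  K <- max(y) + 1L
  fit <- glmnet::glmnet(X, factor(y, levels = 0:(K - 1)),
                        family = "multinomial", alpha = 0,
                        lambda = spec$hyper$lambda,
                        standardize = FALSE,
                        maxit = spec$hyper$max_iter * 100)
  list(fit = fit, K = K, lambda = spec$hyper$lambda)
}

proba_logistic <- function(model, X) {
  p <- predict(model$fit, X, s = model$lambda, type = "response")
  matrix(p[, , 1], nrow(X), model$K)
}

# ---- RBF support vector machine ---------------------------------------

rbf_kernel <- function(A, B, gamma) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  D2 <- outer(an, bn, `+`) - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(D2, 0))
}

# binary soft-margin C-SVM dual solved as a QP (box + one equality)
svm_binary <- function(Kmat, t, C) {
  n <- length(t)
  Q <- (t %o% t) * Kmat + diag(1e-8, n)
  sol <- quadprog::solve.QP(
    Dmat = Q, dvec = rep(1, n),
    Amat = cbind(t, diag(n), -diag(n)),
    bvec = c(0, rep(0, n), rep(-C, n)), meq = 1)
  a <- pmin(pmax(sol$solution, 0), C)
  f_no_b <- as.vector(Kmat %*% (a * t))
  margin <- which(a > 1e-6 & a < C - 1e-6)
  b <- if (length(margin) > 0) mean(t[margin] - f_no_b[margin])
       else mean(t - f_no_b)
  list(coef = a * t, b = b)
}

fit_svm <- function(spec) function(X, y) {
  K <- max(y) + 1L
  gamma <- spec$hyper$gamma; C <- spec$hyper$C
  Kmat <- rbf_kernel(X, X, gamma)
  machines <- vector("list", K)
  platt <- vector("list", K)
  for (k in seq_len(K)) {                       # one-vs-rest
    t <- ifelse(y == k - 1L, 1, -1)
    m <- svm_binary(Kmat, t, C)
    f <- as.vector(Kmat %*% m$coef) + m$b
    # Platt scaling of the decision values to probabilities
    df <- data.frame(f = f, z = as.integer(t > 0))
    platt[[k]] <- suppressWarnings(
      glm(z ~ f, data = df, family = binomial()))
    machines[[k]] <- m
  }
  list(machines = machines, platt = platt, X = X, gamma = gamma, K = K)
}

proba_svm <- function(model, X) {
  Kx <- rbf_kernel(X, model$X, model$gamma)
  P <- matrix(0, nrow(X), model$K)
  for (k in seq_len(model$K)) {
    f <- as.vector(Kx %*% model$machines[[k]]$coef) + model$machines[[k]]$b
    P[, k] <- suppressWarnings(
      predict(model$platt[[k]], data.frame(f = f), type = "response"))
  }
  s <- rowSums(P)
  s[s <= 0] <- 1
  P / s
}

# ---- ensemble ----------------------------------------------------------

fit_softvote <- function(spec) function(X, y) {
  members <- lapply(seq_along(spec$hyper$members), function(i)
    build_classifier(classifier_spec(spec$hyper$members[i],
                                     seed = derive_seed(spec$seed, i))))
  for (m in members) m$fit(X, y)
  list(members = members, weights = spec$hyper$weights)
}

proba_softvote <- function(model, X) {
  blocks <- lapply(model$members, function(m) m$predict_proba(X))
  soft_vote_proba(blocks, model$weights)
}

#' Build a trainable classifier handle
#'
#' Returns a handle exposing `fit(X, y)`, `predict(X)` and
#' `predict_proba(X)`.  Labels are integer codes `0 .. k-1`; probability
#' matrices are `n x k` with rows summing to one.  All models produce
#' class probabilities (the SVM via per-class Platt scaling of its
#' decision values) so any of them can join the soft vote.
#'
#' @param spec a [classifier_spec()] (or a classifier name, which is
#'   wrapped with default hyperparameters).
#' @return an `lf_classifier` handle.
#' @export
build_classifier <- function(spec) {
  if (is.character(spec)) spec <- classifier_spec(spec)
  fns <- switch(spec$name,
    DecisionTree = list(fit_decision_tree(spec), proba_decision_tree),
    RandomForest = list(fit_random_forest(spec), proba_random_forest),
    GradientBoost = list(fit_gradient_boost(spec), proba_gradient_boost),
    AdaBoost = list(fit_adaboost(spec), proba_adaboost),
    KNN = list(fit_knn(spec), proba_knn),
    NaiveBayes = list(fit_naive_bayes(spec), proba_naive_bayes),
    LogisticRegression = list(fit_logistic(spec), proba_logistic),
    SVM = list(fit_svm(spec), proba_svm),
    SoftVote = list(fit_softvote(spec), proba_softvote))
  new_handle(spec, fns[[1]], fns[[2]])
}
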