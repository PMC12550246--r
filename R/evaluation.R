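#' Stratified train/validation/test split
#'
#' Splits per class with largest-remainder rounding so the subsets are
#' disjoint, exhaustive and as close to the requested fractions as integer
#' counts allow.  Deterministic given `seed`.
#'
#' @param data a [feature_matrix()].
#' @param fractions numeric triple `(train, val, test)` summing to 1.
#' @param seed integer seed.
#' @return list of three [feature_matrix()] objects (`train`, `val`,
#'   `test`) plus the index vectors used (`idx`).
#' @export
split_dataset <- function(data, fractions = c(0.7, 0.15, 0.15), seed = 1L) {
  if (any(fractions <= 0) || abs(sum(fractions) - 1) > 1e-9)
    lf_abort("fractions must be positive and sum to 1")
  idx <- list(train = integer(0), val = integer(0), test = integer(0))
  with_seed(seed, {
    for (cls in sort(unique(data$y))) {
      rows <- sample(which(data$y == cls))
      n <- length(rows)
      raw <- fractions * n
      cnt <- floor(raw)
      rem <- raw - cnt
      short <- n - sum(cnt)
      if (short > 0)
        cnt[order(rem, decreasing = TRUE)[seq_len(short)]] <-
          cnt[order(rem, decreasing = TRUE)[seq_len(short)]] + 1
      if (any(cnt == 0)) {
        warning("class ", data$class_names[cls + 1],
                " too small for all subsets; assigning to train",
                call. = FALSE)
      }
      br <- cumsum(cnt)
      idx$train <- c(idx$train, rows[seq_len(br[1])])
      if (br[2] > br[1]) idx$val <- c(idx$val, rows[(br[1] + 1):br[2]])
      if (br[3] > br[2]) idx$test <- c(idx$test, rows[(br[2] + 1):br[3]])
    }
  })
  list(train = fm_subset(data, idx$train),
       val = fm_subset(data, idx$val),
       test = fm_subset(data, idx$test),
       idx = idx)
}

# weighted mean of probability blocks (shared by soft_vote and the
# SoftVote classifier)
soft_vote_proba <- function(prob_blocks, weights = NULL) {
  if (length(prob_blocks) < 2) lf_abort("soft vote needs >= 2 members")
  dims <- vapply(prob_blocks, dim, c(1L, 1L))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    lf_abort("probability blocks have mismatched shapes")
  rs <- rowSums(prob_blocks[[1]])
  if (any(abs(rs - 1) > 1e-6))
    lf_abort("probability rows must sum to 1")
  weights <- weights %||% rep(1, length(prob_blocks))
  weights <- weights / sum(weights)
  Reduce(`+`, Map(function(P, w) P * w, prob_blocks, weights))
}

#' Soft-voting combination of probability matrices
#'
#' Averages the members' `n x k` class-probability matrices (uniform
#' weights unless given) and predicts the argmax per row; exact ties go to
#' the lowest class index.
#'
#' @param prob_blocks list of `n x k` probability matrices.
#' @param weights optional member weights.
#' @return integer vector of predicted labels (`0 .. k-1`).
#' @export
soft_vote <- function(prob_blocks, weights = NULL) {
  P <- soft_vote_proba(prob_blocks, weights)
  max.col(P, ties.method = "first") - 1L
}

#' Metrics from a confusion matrix
#'
#' Convention: rows = actual class, columns = predicted class.  Per-class
#' precision is the diagonal over the predicted-column sum, recall the
#' diagonal over the actual-row sum, F1 their harmonic mean, and accuracy
#' the trace over the total.  A zero denominator yields 0 (with a logged
#' note) rather than an error.
#'
#' @param CM square non-negative integer matrix.
#' @return list with `precision`, `recall`, `f1` (per class), `accuracy`,
#'   and macro averages `macro_precision`, `macro_recall`, `macro_f1`.
#' @export
confusion_metrics <- function(CM) {
  CM <- as.matrix(CM)
  if (nrow(CM) != ncol(CM) || any(CM < 0))
    lf_abort("confusion matrix must be square and non-negative")
  diagv <- diag(CM)
  colsum <- colSums(CM)   # predicted counts
  rowsum <- rowSums(CM)   # actual counts
  guard <- function(num, den, what) {
    bad <- den == 0
    if (any(bad))
      message("note: ", what, " undefined for ", sum(bad),
              " class(es); reported as 0")
    out <- ifelse(bad, 0, num / ifelse(bad, 1, den))
    out
  }
  P <- guard(diagv, colsum, "precision")
  R <- guard(diagv, rowsum, "recall")
  F1 <- ifelse(P + R == 0, 0, 2 * P * R / (P + R))
  list(precision = P, recall = R, f1 = F1,
       accuracy = sum(diagv) / max(sum(CM), 1),
       macro_precision = mean(P), macro_recall = mean(R),
       macro_f1 = mean(F1))
}

confusion_matrix <- function(actual, predicted, k) {
  CM <- matrix(0L, k, k)
  for (i in seq_along(actual))
    CM[actual[i] + 1L, predicted[i] + 1L] <- CM[actual[i] + 1L, predicted[i] + 1L] + 1L
  CM
}

# stratified fold assignment: returns fold id (1..k) per row
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      rows <- sample(which(y == cls))
      fold[rows] <- rep_len(seq_len(k), length(rows))
    }
  })
  fold
}

#' Stratified k-fold cross-validated evaluation
#'
#' For every fold the held-out part is scored by classifiers trained on
#' the remaining folds.  `smote_mode` controls the leakage policy:
#' `"guarded"` (default) applies SMOTE and fits the standardization on the
#' training folds only; `"paper_order"` balances and standardizes the full
#' matrix before folding (the pseudocode order, kept for comparison);
#' `"off"` skips balancing.  `CVp` for each metric is the unweighted mean
#' across folds.
#'
#' @param data a [feature_matrix()].
#' @param specs list of [classifier_spec()] objects (or classifier names).
#' @param k number of folds (>= 2).
#' @param seed integer root seed (folds, SMOTE and models all derive from
#'   it).
#' @param smote_mode `"guarded"`, `"paper_order"` or `"off"`.
#' @param smote_k SMOTE neighbour count.
#' @return an `evaluation_report`: per-classifier fold results (confusion
#'   matrix + metrics) and `cv` aggregates.
#' @export
kfold_evaluate <- function(data, specs, k = 5L, seed = 42L,
                           smote_mode = c("guarded", "paper_order", "off"),
                           smote_k = 5L) {
  smote_mode <- match.arg(smote_mode)
  if (k < 2) lf_abort("k must be >= 2")
  if (k > nrow(data$X)) lf_abort("k exceeds the number of samples")
  counts <- tabulate(data$y + 1L, length(data$class_names))
  if (any(counts > 0 & counts < k))
    warning("some classes have fewer than k samples; folds will be uneven",
            call. = FALSE)
  specs <- lapply(specs, function(s)
    if (is.character(s)) classifier_spec(s) else s)
  nk <- length(data$class_names)

  if (smote_mode == "paper_order") {
    data <- smote_resample(data, smote_k, seed = derive_seed(seed, 999))
    data <- standardize(data)$train
  }
  fold <- stratified_folds(data$y, k, derive_seed(seed, 1))

  results <- list()
  for (spec in specs) {
    per_fold <- vector("list", k)
    for (f in seq_len(k)) {
      tr <- fm_subset(data, which(fold != f))
      te <- fm_subset(data, which(fold == f))
      if (smote_mode == "guarded") {
        tr <- smote_resample(tr, smote_k, seed = derive_seed(seed, 2, f))
        std <- standardize(tr, list(te))
        tr <- std$train; te <- std$others[[1]]
      }
      h <- build_classifier(spec)
      h$fit(tr$X, tr$y)
      pred <- h$predict(te$X)
      CM <- confusion_matrix(te$y, pred, nk)
      per_fold[[f]] <- c(list(CM = CM, n_test = nrow(te$X)),
                         confusion_metrics(CM))
    }
    cv <- list(
      accuracy = mean(vapply(per_fold, `[[`, 1, "accuracy")),
      macro_precision = mean(vapply(per_fold, `[[`, 1, "macro_precision")),
      macro_recall = mean(vapply(per_fold, `[[`, 1, "macro_recall")),
      macro_f1 = mean(vapply(per_fold, `[[`, 1, "macro_f1")))
    results[[spec$name]] <- list(spec = spec, folds = per_fold, cv = cv)
  }
  structure(list(classifiers = results, k = k, seed = seed,
                 smote_mode = smote_mode,
                 class_names = data$class_names),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> ", x$k, "-fold CV (", x$smote_mode,
      " SMOTE), ", length(x$class_names), " classes\n", sep = "")
  for (nm in names(x$classifiers)) {
    cv <- x$classifiers[[nm]]$cv
    cat(sprintf("  %-20s acc %.4f  P %.4f  R %.4f  F1 %.4f\n", nm,
                cv$accuracy, cv$macro_precision, cv$macro_recall,
                cv$macro_f1))
  }
  invisible(x)
}
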