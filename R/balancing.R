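#' Feature matrix container
#'
#' The object the balancing, evaluation and similarity stages operate on:
#' an `n x d` matrix of fused features, integer class labels on the
#' `0 .. k-1` scale, the ordered class names, and a per-row provenance
#' flag separating real rows from SMOTE-synthesized ones.
#'
#' @param X numeric `n x d` matrix.
#' @param y integer labels in `0 .. k-1` (length `n`).
#' @param class_names ordered character vector, `class_names[code + 1]`
#'   names label `code`.
#' @param synthetic logical flag per row (default all `FALSE`).
#' @param segments optional descriptor segment map carried along from
#'   [fuse_features()].
#' @return a `feature_matrix` list.
#' @export
feature_matrix <- function(X, y, class_names, synthetic = NULL,
                           segments = NULL) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (nrow(X) != length(y)) lf_abort("X and y disagree on n")
  if (length(class_names) < max(c(y, -1L)) + 1L)
    lf_abort("labels exceed the class list")
  synthetic <- synthetic %||% rep(FALSE, nrow(X))
  structure(list(X = X, y = y, class_names = as.character(class_names),
                 synthetic = synthetic, segments = segments),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x$X), " x ", ncol(x$X), ", ",
      length(x$class_names), " classes, ", sum(x$synthetic),
      " synthetic rows\n", sep = "")
  invisible(x)
}

# row subset preserving metadata
fm_subset <- function(fm, idx) {
  feature_matrix(fm$X[idx, , drop = FALSE], fm$y[idx], fm$class_names,
                 fm$synthetic[idx], fm$segments)
}

# restrict to one descriptor segment (e.g. "C1" = color histogram)
#' Restrict a feature matrix to named descriptor segments
#' @param fm a [feature_matrix()] carrying a segment map.
#' @param which character vector of segment names (`"C1".."C4"`).
#' @return a [feature_matrix()] over the selected columns.
#' @export
fm_segment <- function(fm, which) {
  if (is.null(fm$segments)) lf_abort("feature matrix has no segment map")
  cols <- unlist(lapply(fm$segments[which], function(s)
    (s[["start"]] + 1):s[["end"]]))
  feature_matrix(fm$X[, cols, drop = FALSE], fm$y, fm$class_names,
                 fm$synthetic, NULL)
}

#' SMOTE minority oversampling
#'
#' Every class below the majority count is oversampled up to it: a seeded
#' random minority sample `x_i` is paired with one of its `k` nearest
#' same-class neighbours `x_z` (Euclidean distance) and the synthetic row
#' `x_i + delta * (x_z - x_i)` is emitted with `delta ~ U[0, 1]` drawn per
#' sample.  Original rows are retained untouched; synthetic rows carry
#' `synthetic = TRUE`.
#'
#' @param data a [feature_matrix()].
#' @param k_neighbors neighbour pool size (capped at class size - 1 with a
#'   warning).
#' @param seed integer seed.
#' @return a [feature_matrix()] with equal class counts.
#' @export
smote_resample <- function(data, k_neighbors = 5L, seed = 1L) {
  if (k_neighbors < 1) lf_abort("k_neighbors must be >= 1")
  counts <- tabulate(data$y + 1L, nbins = length(data$class_names))
  target <- max(counts)
  if (all(counts[counts > 0] == target)) return(data)   # already balanced
  with_seed(seed, {
    new_rows <- list(); new_y <- integer(0)
    for (cls in which(counts > 0 & counts < target) - 1L) {
      idx <- which(data$y == cls)
      if (length(idx) < 2)
        lf_abort("class '", data$class_names[cls + 1],
                 "' has a single sample; SMOTE needs a neighbor")
      k <- k_neighbors
      if (k > length(idx) - 1) {
        k <- length(idx) - 1
        warning("k_neighbors capped at ", k, " for class '",
                data$class_names[cls + 1], "'", call. = FALSE)
      }
      Xc <- data$X[idx, , drop = FALSE]
      nn <- FNN::get.knn(Xc, k = k)$nn.index       # same-class neighbours
      need <- target - length(idx)
      pick <- sample.int(length(idx), need, replace = TRUE)
      nbr <- vapply(pick, function(i) nn[i, sample.int(k, 1)], 1L)
      delta <- runif(need)
      syn <- Xc[pick, , drop = FALSE] +
             delta * (Xc[nbr, , drop = FALSE] - Xc[pick, , drop = FALSE])
      new_rows[[length(new_rows) + 1]] <- syn
      new_y <- c(new_y, rep(cls, need))
    }
    feature_matrix(rbind(data$X, do.call(rbind, new_rows)),
                   c(data$y, new_y), data$class_names,
                   c(data$synthetic, rep(TRUE, length(new_y))),
                   data$segments)
  })
}

#' Feature standardization (train-fitted z-score)
#'
#' Column means and standard deviations are estimated on `train` only and
#' the same affine transform is applied to every held-out matrix.
#' Zero-variance columns map to 0.
#'
#' @param train a [feature_matrix()].
#' @param others list of held-out [feature_matrix()] objects.
#' @return list with `train`, `others` (both transformed) and `scaler`
#'   (`center`, `scale` vectors) for later reuse via [apply_scaler()].
#' @export
standardize <- function(train, others = list()) {
  if (nrow(train$X) == 0) lf_abort("train matrix is empty")
  for (o in others)
    if (ncol(o$X) != ncol(train$X)) lf_abort("column count mismatch")
  ctr <- colMeans(train$X)
  scl <- apply(train$X, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- Inf      # constant columns -> 0
  scaler <- list(center = ctr, scale = scl)
  list(train = apply_scaler(train, scaler),
       others = lapply(others, apply_scaler, scaler = scaler),
       scaler = scaler)
}

#' @rdname standardize
#' @param data a [feature_matrix()] or plain matrix to transform.
#' @param scaler the `scaler` element returned by [standardize()].
#' @export
apply_scaler <- function(data, scaler) {
  tr <- function(M) sweep(sweep(M, 2, scaler$center), 2, scaler$scale, `/`)
  if (inherits(data, "feature_matrix"))
    feature_matrix(tr(data$X), data$y, data$class_names, data$synthetic,
                   data$segments)
  else tr(as.matrix(data))
}
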