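#' Per-class mean feature vectors
#'
#' Arithmetic column means per class.  By default SMOTE-synthesized rows
#' are excluded so interpolated points do not drag the means toward
#' segment midpoints; set `include_synthetic = TRUE` to reproduce the
#' balance-first variant.
#'
#' @param data a [feature_matrix()].
#' @param include_synthetic include synthetic rows in the means.
#' @return `k x d` matrix of class means, rownames = class names.
#' @export
class_mean_vectors <- function(data, include_synthetic = FALSE) {
  keep <- if (include_synthetic) rep(TRUE, nrow(data$X)) else !data$synthetic
  present <- sort(unique(data$y))
  M <- matrix(0, length(present), ncol(data$X))
  rownames(M) <- data$class_names[present + 1]
  for (i in seq_along(present)) {
    rows <- which(data$y == present[i] & keep)
    if (length(rows) == 0)
      lf_abort("class '", data$class_names[present[i] + 1],
               "' has no rows for the mean")
    M[i, ] <- colMeans(data$X[rows, , drop = FALSE])
  }
  M
}

#' Inter-class cosine similarity matrix
#'
#' Cosine similarity between every pair of class means, mapped linearly
#' from `[-1, 1]` onto `[0, 1]` via `(c + 1) / 2`.  Values near 1 flag
#' confusable (look-alike) class pairs.
#'
#' @param means `k x d` matrix of class mean vectors (rownames = classes),
#'   e.g. from [class_mean_vectors()].
#' @return a `similarity_matrix`: `k x k` numeric matrix in `[0, 1]` with
#'   class names on both dimnames.
#' @export
interclass_similarity <- function(means) {
  if (nrow(means) < 2) lf_abort("need at least 2 classes")
  nrm <- sqrt(rowSums(means^2))
  zero <- which(nrm == 0)
  if (length(zero) > 0)
    lf_abort("zero-norm mean for class '", rownames(means)[zero[1]], "'")
  unit <- means / nrm
  S <- clamp(tcrossprod(unit), -1, 1)
  S <- (S + 1) / 2
  dimnames(S) <- list(rownames(means), rownames(means))
  structure(S, class = c("similarity_matrix", "matrix"))
}

#' Ranked confusable class pairs
#'
#' Off-diagonal pairs sorted by similarity (descending); ties broken by
#' class-name order, so the ranking is deterministic.
#'
#' @param S a `similarity_matrix`.
#' @param threshold keep only pairs with similarity >= threshold.
#' @param top_n keep only the first `top_n` pairs after ranking.
#' @return data.frame with columns `class_a`, `class_b`, `similarity`.
#' @export
top_confusable_pairs <- function(S, threshold = NULL, top_n = NULL) {
  k <- nrow(S)
  nm <- rownames(S)
  pairs <- which(upper.tri(S), arr.ind = TRUE)
  df <- data.frame(class_a = nm[pairs[, 1]], class_b = nm[pairs[, 2]],
                   similarity = S[pairs], stringsAsFactors = FALSE)
  df <- df[order(-df$similarity, df$class_a, df$class_b), , drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(threshold)) df <- df[df$similarity >= threshold, , drop = FALSE]
  if (!is.null(top_n)) df <- head(df, top_n)
  df
}

#' Write a similarity heatmap as a PNG
#'
#' Renders the matrix directly as pixels (nearest-neighbor upscaled)
#' using a white-to-red ramp; no graphics device needed, so it works
#' headless.
#'
#' @param S a `similarity_matrix`.
#' @param path output PNG path.
#' @param cell pixel size of one matrix cell.
#' @export
write_similarity_heatmap <- function(S, path, cell = 24L) {
  k <- nrow(S)
  up <- matrix(0, k * cell, k * cell)
  for (i in seq_len(k)) for (j in seq_len(k))
    up[(i - 1) * cell + seq_len(cell), (j - 1) * cell + seq_len(cell)] <- S[i, j]
  img <- array(1, c(k * cell, k * cell, 3))
  img[, , 2] <- 1 - up          # white (0) -> red (1)
  img[, , 3] <- 1 - up
  png::writePNG(img, path)
  invisible(path)
}
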