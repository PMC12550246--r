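#' Evaluation-time image perturbations
#'
#' The stress harness degrades evaluation images while leaving the
#' trained model and its train-fitted preprocessing untouched:
#' `apply_noise` adds seeded zero-mean Gaussian noise per pixel per
#' channel (rounded, clipped to `[0, 255]`); `apply_scale` bilinearly
#' resizes to `target x target` (feature extraction later resizes back to
#' the working resolution, modeling the information loss); `apply_rotation`
#' performs exact lossless grid rotation by 90/180/270 degrees clockwise;
#' `apply_occlusion` blanks one seeded axis-aligned rectangle covering the
#' requested area fraction with a fill color.
#'
#' @param img RGB array (rotation and scaling also accept grayscale).
#' @param sigma noise stddev in intensity units (>= 0; 0 is the identity).
#' @param seed integer seed.
#' @return perturbed image of the same kind.
#' @export
apply_noise <- function(img, sigma, seed = 1L) {
  if (sigma < 0) lf_abort("sigma must be >= 0")
  if (sigma == 0) return(img)
  with_seed(seed, {
    noise <- array(rnorm(length(img), 0, sigma), dim(img))
    structure(clamp(round_half_up(unclass(img) + noise), 0, 255),
              class = class(img))
  })
}

#' @rdname apply_noise
#' @param target output side length in pixels.
#' @export
apply_scale <- function(img, target) {
  resize_bilinear(img, target, target)
}

#' @rdname apply_noise
#' @param angle clockwise rotation angle: 90, 180 or 270.
#' @export
apply_rotation <- function(img, angle) {
  if (!angle %in% c(90, 180, 270))
    lf_abort("angle must be one of 90, 180, 270")
  rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])
  rot <- function(m, times) { for (i in seq_len(times)) m <- rot90cw(m); m }
  times <- angle / 90
  if (is_rgb(img)) {
    planes <- lapply(1:3, function(ch) rot(img[, , ch], times))
    out <- array(0, c(nrow(planes[[1]]), ncol(planes[[1]]), 3))
    for (ch in 1:3) out[, , ch] <- planes[[ch]]
    structure(out, class = class(img))
  } else {
    structure(rot(unclass(img), times), class = class(img))
  }
}

#' @rdname apply_noise
#' @param fraction occluded area fraction in `[0, 1)`.
#' @param fill RGB triple (or scalar for grayscale) of the occluding patch.
#' @export
apply_occlusion <- function(img, fraction, seed = 1L, fill = c(0, 0, 0)) {
  if (fraction < 0 || fraction >= 1) lf_abort("fraction must lie in [0, 1)")
  if (fraction == 0) return(img)
  d <- dim(img)
  h <- d[1]; w <- d[2]
  with_seed(seed, {
    # near-square rectangle of the requested area
    rh <- clamp(round(sqrt(fraction * h * w * runif(1, 0.8, 1.25))), 1, h)
    rw <- clamp(round(fraction * h * w / rh), 1, w)
    r0 <- sample.int(h - rh + 1, 1); c0 <- sample.int(w - rw + 1, 1)
    out <- unclass(img)
    if (is_rgb(img)) {
      for (ch in 1:3)
        out[r0:(r0 + rh - 1), c0:(c0 + rw - 1), ch] <- fill[min(ch, length(fill))]
    } else {
      out[r0:(r0 + rh - 1), c0:(c0 + rw - 1)] <- fill[1]
    }
    structure(out, class = class(img))
  })
}

# parse "noise:10" / "scale:64" / "rot:180" / "occ:0.2" strings
parse_conditions <- function(txt) {
  lapply(strsplit(txt, ",")[[1]], function(s) {
    kv <- strsplit(trimws(s), ":")[[1]]
    kind <- switch(kv[1], noise = "noise", scale = "scale",
                   rot = , rotation = "rotation", occ = ,
                   occlusion = "occlusion",
                   lf_abort("unknown stress condition: ", kv[1]))
    stress_condition(kind, as.numeric(kv[2]))
  })
}

#' Stress condition descriptor
#'
#' @param kind `"noise"`, `"scale"`, `"rotation"` or `"occlusion"`.
#' @param parameter noise sigma / target size / angle / area fraction.
#' @param seed integer seed for the condition's randomness.
#' @return a `stress_condition` list.
#' @export
stress_condition <- function(kind, parameter, seed = 1L) {
  kind <- match.arg(kind, c("noise", "scale", "rotation", "occlusion"))
  if (kind == "rotation" && !parameter %in% c(90, 180, 270))
    lf_abort("rotation angle must be 90, 180 or 270")
  structure(list(kind = kind, parameter = parameter, seed = as.integer(seed)),
            class = "stress_condition")
}

apply_condition <- function(img, cond, img_seed) {
  switch(cond$kind,
    noise = apply_noise(img, cond$parameter, seed = img_seed),
    scale = apply_scale(img, cond$parameter),
    rotation = apply_rotation(img, cond$parameter),
    occlusion = apply_occlusion(img, cond$parameter, seed = img_seed))
}

#' Train a classifier on clean images for stress testing
#'
#' Extracts fused features for the dataset, makes a stratified
#' train/test split, optionally SMOTE-balances the training part, fits
#' the train-side standardization and the classifier.  The returned
#' object carries everything [stress_suite()] needs to re-extract and
#' re-score perturbed evaluation images with the identical configuration.
#'
#' @param dataset a `labelled_dataset`.
#' @param spec a [classifier_spec()] (or name).
#' @param cfg a [descriptor_config()].
#' @param fractions train/val/test fractions.
#' @param seed root seed.
#' @param smote apply SMOTE to the training part.
#' @param segment optional descriptor segment restriction (e.g. `"C1"`
#'   for a color-histogram-only model); stress scoring applies the same
#'   restriction.
#' @return a `stress_fit` list.
#' @export
fit_pipeline <- function(dataset, spec = "RandomForest",
                         cfg = descriptor_config(),
                         fractions = c(0.7, 0.15, 0.15), seed = 42L,
                         smote = TRUE, segment = NULL) {
  if (is.character(spec)) spec <- classifier_spec(spec)
  fm <- extract_features(dataset, cfg)
  fm_used <- if (is.null(segment)) fm else fm_segment(fm, segment)
  sp <- split_dataset(fm_used, fractions, seed = derive_seed(seed, 1))
  tr <- sp$train
  if (smote) tr <- smote_resample(tr, seed = derive_seed(seed, 2))
  std <- standardize(tr, list(sp$test))
  h <- build_classifier(spec)
  h$fit(std$train$X, std$train$y)
  structure(list(model = h, scaler = std$scaler, cfg = cfg, spec = spec,
                 dataset = dataset, test_idx = sp$idx$test,
                 test_y = sp$test$y, seed = seed, segment = segment,
                 clean_test = std$others[[1]],
                 class_names = fm$class_names, segments = fm$segments),
            class = "stress_fit")
}

#' Stress-test a trained model
#'
#' For every condition the evaluation images are perturbed, features are
#' re-extracted with the identical descriptor configuration, the
#' train-fitted standardization is applied, and accuracy is tabulated
#' next to the clean baseline.
#'
#' @param fit a `stress_fit` from [fit_pipeline()].
#' @param conditions list of [stress_condition()] objects (or a spec
#'   string like `"noise:10,scale:64,rot:180,occ:0.2"`).
#' @return data.frame with columns `condition`, `parameter`, `accuracy`.
#' @export
stress_suite <- function(fit, conditions = list()) {
  if (!inherits(fit, "stress_fit")) lf_abort("fit must come from fit_pipeline()")
  if (!fit$model$is_fitted()) lf_abort("model is not trained")
  if (is.character(conditions)) conditions <- parse_conditions(conditions)
  segment <- fit$segment
  recs <- fit$dataset$records[fit$test_idx, , drop = FALSE]
  score <- function(X) {
    pred <- fit$model$predict(X)
    mean(pred == fit$test_y)
  }
  rows <- list(data.frame(condition = "clean", parameter = NA_real_,
                          accuracy = score(fit$clean_test$X)))
  for (cond in conditions) {
    feats <- vector("list", nrow(recs))
    for (i in seq_len(nrow(recs))) {
      img <- read_image(recs$path[i])
      img <- apply_condition(img, cond, derive_seed(cond$seed, i))
      feats[[i]] <- extract_image_features(img, fit$cfg)
    }
    X <- do.call(rbind, feats)
    if (!is.null(segment)) {
      fmx <- feature_matrix(X, fit$test_y, fit$class_names,
                            segments = fit$segments)
      X <- fm_segment(fmx, segment)$X
    }
    X <- apply_scaler(X, fit$scaler)
    rows[[length(rows) + 1]] <-
      data.frame(condition = cond$kind, parameter = cond$parameter,
                 accuracy = score(X))
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}
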