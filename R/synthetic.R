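#' Synthetic leaf class specification
#'
#' Describes one synthetic species as a stylized leaf: a super-ellipse
#' silhouette (optionally serrated) over a near-uniform background, filled
#' with a base color modulated by a sinusoidal "vein" texture.  The knobs
#' map onto the visual axes the feature descriptors probe: `base_color`
#' drives the color histogram, `vein_frequency` / `vein_orientation` drive
#' LBP and Gabor, `blob_elongation` / `margin_serration` drive HOG.
#'
#' @param class_name species name (folder name on disk).
#' @param base_color RGB triple in `[0, 255]`.
#' @param color_jitter stddev (intensity units) of the per-image color shift
#'   and per-pixel noise; 0 gives noise-free images.
#' @param blob_elongation leaf aspect ratio (height/width of the blob), > 0.
#' @param margin_serration integer number of marginal teeth (0 = smooth).
#' @param vein_frequency vein texture frequency in cycles per image width, > 0.
#' @param vein_orientation vein direction in degrees, `[0, 180)`.
#' @param vein_amplitude amplitude (intensity units) of the vein sinusoid.
#' @param background_color RGB triple of the backdrop.
#' @return a `leaf_class_spec` list.
#' @export
leaf_class_spec <- function(class_name, base_color,
                            color_jitter = 8, blob_elongation = 1.4,
                            margin_serration = 0L, vein_frequency = 8,
                            vein_orientation = 60, vein_amplitude = 20,
                            background_color = c(235, 235, 230)) {
  stopifnot(length(base_color) == 3, length(background_color) == 3)
  if (any(base_color < 0 | base_color > 255))
    lf_abort("base_color components must lie in [0, 255]")
  if (vein_frequency <= 0) lf_abort("vein_frequency must be positive")
  if (blob_elongation <= 0) lf_abort("blob_elongation must be positive")
  if (margin_serration < 0) lf_abort("margin_serration must be >= 0")
  structure(list(class_name = as.character(class_name),
                 base_color = as.numeric(base_color),
                 color_jitter = color_jitter,
                 blob_elongation = blob_elongation,
                 margin_serration = as.integer(margin_serration),
                 vein_frequency = vein_frequency,
                 vein_orientation = vein_orientation %% 180,
                 vein_amplitude = vein_amplitude,
                 background_color = as.numeric(background_color)),
            class = "leaf_class_spec")
}

#' Synthetic dataset specification
#'
#' @param class_specs list of [leaf_class_spec()] objects (>= 2).
#' @param images_per_class images generated per class (>= 1).
#' @param image_size `(h, w)` in pixels, each >= 32.
#' @param seed root seed; every image derives its own stream from
#'   `(seed, class index, image index)`.
#' @param imbalance optional named integer vector subsampling the stated
#'   classes to the stated counts (for exercising SMOTE).
#' @return a `synthetic_dataset_spec` list.
#' @export
synthetic_dataset_spec <- function(class_specs, images_per_class = 40L,
                                   image_size = c(128L, 128L), seed = 1L,
                                   imbalance = NULL) {
  if (length(class_specs) < 2) lf_abort("need at least 2 class specs")
  if (images_per_class < 1) lf_abort("images_per_class must be >= 1")
  nm <- vapply(class_specs, `[[`, "", "class_name")
  if (anyDuplicated(nm)) lf_abort("class names must be unique")
  if (!is.null(imbalance) && !all(names(imbalance) %in% nm))
    lf_abort("imbalance names must match class names")
  structure(list(class_specs = class_specs,
                 images_per_class = as.integer(images_per_class),
                 image_size = as.integer(image_size),
                 seed = as.integer(seed),
                 imbalance = imbalance),
            class = "synthetic_dataset_spec")
}

#' Render one synthetic leaf image
#'
#' Deterministic given `(spec, size, seed)`.  The silhouette is a
#' super-ellipse in polar form with a sinusoidal margin perturbation for
#' serration; the fill is `base_color` plus an additive 2-D sinusoid along
#' `vein_orientation`, a per-image global color shift and per-pixel noise
#' (both scaled by `color_jitter`), all clipped to `[0, 255]`.
#'
#' @param spec a [leaf_class_spec()].
#' @param size `(h, w)`, each >= 32.
#' @param seed integer seed for this image's random stream.
#' @return an [rgb_image()].
#' @export
generate_leaf_image <- function(spec, size = c(128L, 128L), seed = 1L) {
  if (length(size) != 2 || any(size < 32)) lf_abort("size must be >= 32 x 32")
  h <- as.integer(size[1]); w <- as.integer(size[2])
  with_seed(seed, {
    # centered pixel grid in [-1, 1]
    yy <- matrix(seq(-1, 1, length.out = h), h, w)
    xx <- matrix(seq(-1, 1, length.out = w), h, w, byrow = TRUE)
    # mild seeded pose variation: scale and in-plane center offset
    scale <- runif(1, 0.85, 1.0)
    cx <- runif(1, -0.06, 0.06); cy <- runif(1, -0.06, 0.06)
    a <- 0.80 * scale                       # semi-axis along x
    b <- clamp(a * spec$blob_elongation, 0.2, 0.95)  # along y
    n_exp <- 2.5                            # super-ellipse exponent
    px <- xx - cx; py <- yy - cy
    r <- sqrt(px^2 + py^2)
    phi <- atan2(py, px)
    # polar radius of the super-ellipse boundary at angle phi
    r0 <- (abs(cos(phi) / a)^n_exp + abs(sin(phi) / b)^n_exp)^(-1 / n_exp)
    if (spec$margin_serration > 0)
      r0 <- r0 * (1 + 0.06 * sin(spec$margin_serration * phi))
    mask <- r <= r0

    theta <- spec$vein_orientation * pi / 180
    # cycles per image width along the vein direction
    u <- (px * cos(theta) + py * sin(theta)) / 2   # in [-0.5, 0.5] units of width
    vein <- spec$vein_amplitude * sin(2 * pi * spec$vein_frequency * u)

    shift <- if (spec$color_jitter > 0) rnorm(3, 0, spec$color_jitter) else c(0, 0, 0)
    img <- array(0, c(h, w, 3))
    for (ch in 1:3) {
      bg <- matrix(spec$background_color[ch], h, w)
      fg <- spec$base_color[ch] + vein + shift[ch]
      plane <- ifelse(mask, fg, bg)
      if (spec$color_jitter > 0)
        plane <- plane + matrix(rnorm(h * w, 0, spec$color_jitter), h, w)
      img[, , ch] <- clamp(round_half_up(plane), 0, 255)
    }
    rgb_image(img)
  })
}

#' Generate a synthetic dataset on disk
#'
#' Writes `out_dir/<class>/<class>_<idx>.png` for every class and returns
#' the dataset index.  Regeneration from the same spec is byte-identical:
#' each image uses a stream derived from `(spec$seed, class index, image
#' index)`, so neither insertion order nor the imbalance option perturbs
#' the remaining images.
#'
#' @param spec a [synthetic_dataset_spec()].
#' @param out_dir output directory (created if missing).
#' @return a `labelled_dataset` (see [load_dataset()]).
#' @export
generate_dataset <- function(spec, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) lf_abort("cannot create output directory: ", out_dir)
  for (ci in seq_along(spec$class_specs)) {
    cs <- spec$class_specs[[ci]]
    n <- spec$images_per_class
    if (!is.null(spec$imbalance) && cs$class_name %in% names(spec$imbalance))
      n <- as.integer(spec$imbalance[[cs$class_name]])
    cdir <- file.path(out_dir, cs$class_name)
    dir.create(cdir, showWarnings = FALSE)
    for (ii in seq_len(n)) {
      img <- generate_leaf_image(cs, spec$image_size,
                                 seed = derive_seed(spec$seed, ci, ii))
      write_image(img, file.path(cdir, sprintf("%s_%03d.png", cs$class_name, ii)))
    }
  }
  load_dataset(out_dir)
}

#' Ready-made class palettes for the synthetic generator
#'
#' `demo_class_specs()` returns `k` well-separated species spanning the
#' hue circle with distinct textures and shapes (the "separable" regime).
#' `lookalike_class_specs()` returns a color-matched pair that differs only
#' in vein texture frequency/orientation -- the high inter-class-similarity
#' regime where color histograms saturate and texture descriptors must do
#' the work.
#'
#' @param k number of classes (2..8 for the demo palette).
#' @return list of [leaf_class_spec()].
#' @export
demo_class_specs <- function(k = 5L) {
  stopifnot(k >= 2, k <= 8)
  hues <- list(c(60, 150, 60), c(160, 120, 40), c(40, 100, 170),
               c(170, 60, 60), c(120, 170, 160), c(200, 170, 60),
               c(90, 60, 140), c(60, 170, 120))
  specs <- vector("list", k)
  for (i in seq_len(k)) {
    specs[[i]] <- leaf_class_spec(
      class_name = sprintf("species_%02d", i),
      base_color = hues[[i]],
      color_jitter = 8,
      blob_elongation = 0.9 + 0.25 * ((i - 1) %% 4),
      margin_serration = c(0L, 9L, 0L, 14L, 6L, 0L, 11L, 4L)[i],
      vein_frequency = 4 + 3 * ((i - 1) %% 5),
      vein_orientation = (i - 1) * 37 %% 180)
  }
  specs
}

#' @rdname demo_class_specs
#' @param base_color shared RGB triple of the color-matched pair.
#' @export
lookalike_class_specs <- function(base_color = c(70, 150, 70)) {
  list(
    leaf_class_spec("lookalike_fine",   base_color, color_jitter = 6,
                    blob_elongation = 1.3, margin_serration = 0L,
                    vein_frequency = 16, vein_orientation = 45),
    leaf_class_spec("lookalike_coarse", base_color, color_jitter = 6,
                    blob_elongation = 1.3, margin_serration = 0L,
                    vein_frequency = 4, vein_orientation = 135))
}
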