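test_that("generate_leaf_image is deterministic and validates size", {
  sp <- demo_class_specs(3)[[1]]
  a <- generate_leaf_image(sp, c(48, 48), seed = 7)
  b <- generate_leaf_image(sp, c(48, 48), seed = 7)
  expect_identical(unclass(a), unclass(b))
  c <- generate_leaf_image(sp, c(48, 48), seed = 8)
  expect_false(identical(unclass(a), unclass(c)))
  expect_error(generate_leaf_image(sp, c(16, 16)), "32")
})

test_that("noise-free spec renders foreground exactly at base_color", {
  sp <- leaf_class_spec("x", c(40, 160, 60), color_jitter = 0,
                        vein_amplitude = 0, background_color = c(250, 250, 250))
  img <- generate_leaf_image(sp, c(64, 64), seed = 3)
  fg <- img[, , 2] == 160
  expect_gt(sum(fg), 500)              # leaf occupies a real area
  expect_true(all(img[, , 1][fg] == 40))
  expect_true(all(img[, , 3][fg] == 60))
  bg_vals <- unique(as.vector(img[, , 1][!fg]))
  expect_true(all(bg_vals == 250))
})

test_that("jittered foreground mean tracks base_color across seeds", {
  # Monte-Carlo: per-image shift sd=10 -> mean-of-means se = 10/sqrt(50)
  sp <- leaf_class_spec("x", c(40, 160, 60), color_jitter = 10,
                        vein_amplitude = 0, background_color = c(250, 250, 250))
  ref <- leaf_class_spec("x", c(40, 160, 60), color_jitter = 0,
                         vein_amplitude = 0, background_color = c(250, 250, 250))
  means <- vapply(1:50, function(s) {
    img <- generate_leaf_image(sp, c(64, 64), seed = s)
    msk <- generate_leaf_image(ref, c(64, 64), seed = s)[, , 2] == 160
    mean(img[, , 2][msk])
  }, 1)
  expect_lt(abs(mean(means) - 160), 5)
})

test_that("generate_dataset writes the expected folder layout", {
  dir <- file.path(tempdir(), "lf_counts")
  unlink(dir, recursive = TRUE)
  spec <- synthetic_dataset_spec(demo_class_specs(3), images_per_class = 10,
                                 image_size = c(32, 32), seed = 77)
  ds <- generate_dataset(spec, dir)
  expect_equal(length(list.dirs(dir, recursive = FALSE)), 3)
  expect_equal(length(list.files(dir, recursive = TRUE, pattern = "png$")), 30)
  expect_equal(unname(table(ds$records$class)), rep(10L, 3),
               ignore_attr = TRUE)
})

test_that("imbalance option subsamples only the stated class", {
  dir <- file.path(tempdir(), "lf_imb")
  unlink(dir, recursive = TRUE)
  specs <- demo_class_specs(2)
  spec <- synthetic_dataset_spec(specs, images_per_class = 10,
                                 image_size = c(32, 32), seed = 77,
                                 imbalance = c(species_01 = 4L))
  ds <- generate_dataset(spec, dir)
  tab <- table(ds$records$class)
  expect_equal(unname(tab[["species_01"]]), 4L)
  expect_equal(unname(tab[["species_02"]]), 10L)
  # undersampled class images equal the balanced run's first four images
  dir2 <- file.path(tempdir(), "lf_imb_ref")
  unlink(dir2, recursive = TRUE)
  generate_dataset(synthetic_dataset_spec(specs, images_per_class = 10,
                                          image_size = c(32, 32), seed = 77),
                   dir2)
  f1 <- file.path(dir, "species_01", "species_01_003.png")
  f2 <- file.path(dir2, "species_01", "species_01_003.png")
  expect_identical(read_image(f1), read_image(f2))
})

test_that("separability dial: distinct hues are linearly separable on color", {
  fxf <- fixture_separable_features()
  c1 <- fm_segment(fxf$fm, "C1")
  std <- standardize(c1)
  h <- build_classifier("LogisticRegression")
  h$fit(std$train$X, std$train$y)
  expect_equal(mean(h$predict(std$train$X) == std$train$y), 1.0)
})

test_that("look-alike dial: color-matched pair confusable on color only", {
  fm <- fixture_lookalike_features()
  raw_cos <- function(fmx) {
    S <- interclass_similarity(class_mean_vectors(fmx))
    2 * S[1, 2] - 1
  }
  expect_gt(raw_cos(fm_segment(fm, "C1")), 0.95)
  expect_lt(raw_cos(fm), 0.95)
  # texture descriptors separate what color cannot
  mc <- class_mean_vectors(fm_segment(fm, "C1"))
  ml <- class_mean_vectors(fm_segment(fm, "C2"))
  expect_gt(mean(abs(ml[1, ] - ml[2, ])), mean(abs(mc[1, ] - mc[2, ])))
})
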