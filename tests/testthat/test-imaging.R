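test_that("to_grayscale applies BT.601 weights with half-up rounding", {
  px <- function(r, g, b) to_grayscale(array(c(r, g, b), c(1, 1, 3)))[1, 1]
  expect_equal(px(255, 255, 255), 255)
  expect_equal(px(0, 0, 0), 0)
  expect_equal(px(100, 150, 200), 141)   # 29.9 + 88.05 + 22.8 = 140.75
})

test_that("to_grayscale is monotone in every channel", {
  set.seed(11)
  for (i in 1:50) {
    base <- sample(0:254, 3, replace = TRUE)
    ch <- sample(1:3, 1)
    up <- base; up[ch] <- up[ch] + 1
    g0 <- to_grayscale(array(base, c(1, 1, 3)))[1, 1]
    g1 <- to_grayscale(array(up, c(1, 1, 3)))[1, 1]
    expect_gte(g1, g0)
  }
})

test_that("resize_bilinear handles identity, constants and the 2x2 case", {
  m <- rand_gray(5, 7, seed = 1)
  expect_identical(resize_bilinear(m, 5, 7), m)
  cst <- matrix(100, 4, 4)
  expect_true(all(resize_bilinear(cst, 9, 3) == 100))
  # [[0,100],[50,150]] upscaled 3x3, corner-aligned: center is the 4-mean
  m2 <- matrix(c(0, 50, 100, 150), 2, 2)
  expect_equal(resize_bilinear(m2, 3, 3, align = "corners")[2, 2], 75)
  expect_error(resize_bilinear(m2, 0, 3), "positive")
})

test_that("resize_bilinear preserves linear ramps within rounding", {
  src <- matrix(rep(0:31, each = 8), 8, 32, byrow = FALSE)
  src <- t(src)  # I(r, c) = c - 1 pattern along columns
  src <- matrix(rep(seq(0, 124, by = 4), times = 8), 8, 32, byrow = TRUE)
  for (tw in c(16, 48, 64)) {
    out <- resize_bilinear(src, 8, tw)
    # columns must be an affine function of index away from the clamped edge
    core <- out[1, 3:(tw - 2)]
    d <- diff(core)
    expect_lt(max(abs(d - mean(d))), 0.5 + 1e-9)
  }
})

test_that("rgb channels are resized independently", {
  img <- rand_rgb(6, 6, seed = 2)
  out <- resize_bilinear(img, 12, 9)
  for (ch in 1:3)
    expect_equal(out[, , ch], resize_bilinear(img[, , ch], 12, 9))
})

test_that("encode_labels sorts lexicographically with set semantics", {
  expect_identical(encode_labels(c("Neem", "Aloe", "Tulsi")),
                   c(Aloe = 0L, Neem = 1L, Tulsi = 2L))
  expect_identical(encode_labels("X"), c(X = 0L))
  expect_identical(encode_labels(c("A", "A", "B")), c(A = 0L, B = 1L))
  expect_error(encode_labels(character(0)), "empty")
})

test_that("load_dataset indexes class folders deterministically", {
  fx <- fixture_separable()
  ds <- fx$dataset
  expect_s3_class(ds, "labelled_dataset")
  expect_equal(nrow(ds$records), 30)
  expect_identical(unname(ds$label_map), 0:2)
  expect_identical(names(ds$label_map), sort(names(ds$label_map)))
  ds2 <- load_dataset(fx$dir)
  expect_identical(ds$records, ds2$records)
})

test_that("load_dataset skips corrupt files and rejects bad layouts", {
  root <- file.path(tempdir(), "lf_corrupt")
  unlink(root, recursive = TRUE)
  for (cl in c("a", "b")) {
    dir.create(file.path(root, cl), recursive = TRUE)
    for (i in 1:3)
      write_image(rand_rgb(8, 8, seed = i), file.path(root, cl, paste0(i, ".png")))
  }
  writeLines("not a png", file.path(root, "a", "broken.png"))
  expect_warning(ds <- load_dataset(root), "unreadable")
  expect_equal(nrow(ds$records), 6)
  # single-class root is structural error
  one <- file.path(tempdir(), "lf_oneclass")
  unlink(one, recursive = TRUE)
  dir.create(file.path(one, "only"), recursive = TRUE)
  expect_error(load_dataset(one), "2 class")
})

test_that("png round trip preserves pixels", {
  img <- rand_rgb(10, 9, seed = 3)
  p <- tempfile(fileext = ".png")
  write_image(img, p)
  expect_equal(read_image(p), img)
})
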