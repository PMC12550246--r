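test_that("color histogram puts single-color mass in one joint bin", {
  img <- array(0, c(4, 4, 3)); img[, , 1] <- 255
  h <- color_histogram_3d(img, c(8, 8, 8))
  expect_equal(length(h), 512)
  expect_equal(h[7 * 64 + 0 * 8 + 0 + 1], 1.0)   # bin (7,0,0), R-major
  expect_equal(sum(h != 0), 1)
  # two equal-mass bins
  img2 <- array(c(0, 255), c(1, 2, 3))
  img2[1, 1, ] <- 0; img2[1, 2, ] <- 255
  h2 <- color_histogram_3d(img2, c(8, 8, 8))
  expect_equal(h2[1], 0.5)
  expect_equal(h2[512], 0.5)
})

test_that("color histogram sums to 1 and matches marginal mode lengths", {
  for (s in 1:5) {
    img <- rand_rgb(9, 11, seed = s)
    expect_equal(sum(color_histogram_3d(img)), 1, tolerance = 1e-12)
    expect_equal(length(color_histogram_3d(img, c(8, 8, 8), "marginal")), 24)
    expect_equal(sum(color_histogram_3d(img, c(8, 8, 8), "marginal")), 3,
                 tolerance = 1e-12)
  }
})

test_that("color histogram is invariant to spatial permutation", {
  img <- rand_rgb(8, 8, seed = 42)
  set.seed(1)
  perm <- sample(64)
  shuffled <- array(0, dim(img))
  for (ch in 1:3) shuffled[, , ch] <- matrix(img[, , ch][perm], 8, 8)
  expect_identical(color_histogram_3d(img), color_histogram_3d(shuffled))
})

test_that("LBP-riu2 bin count and constant-image behavior", {
  expect_equal(length(lbp_riu2_histogram(rand_gray(16, 16, 1), 24, 3)), 26)
  h <- lbp_riu2_histogram(matrix(7, 9, 9), 8, 1)
  expect_equal(h[9], 1.0)          # all-ones pattern -> bin P
  expect_equal(sum(h), 1)
  expect_error(lbp_riu2_histogram(matrix(0, 5, 5), 24, 3), "neighborhood")
})

test_that("LBP matches the brute-force oracle on random images", {
  for (s in 1:6) {
    g <- rand_gray(9, 9, seed = s)
    expect_equal(lbp_riu2_histogram(g, 8, 1), oracle_lbp_riu2(g, 8, 1),
                 tolerance = 1e-12)
  }
  g <- rand_gray(14, 14, seed = 99)
  expect_equal(lbp_riu2_histogram(g, 24, 3), oracle_lbp_riu2(g, 24, 3),
               tolerance = 1e-12)
})

test_that("LBP-riu2 histogram is stable under exact right-angle rotation", {
  fx <- fixture_separable()
  paths <- fx$dataset$records$path[c(1, 11, 21)]
  for (p in paths) {
    g <- to_grayscale(read_image(p))
    h0 <- lbp_riu2_histogram(g, 24, 3)
    for (ang in c(90, 180, 270)) {
      hr <- lbp_riu2_histogram(apply_rotation(g, ang), 24, 3)
      expect_lt(sum(abs(hr - h0)) / 2, 0.02)
    }
  }
})

test_that("gabor features match layout and linearity contracts", {
  g <- rand_gray(16, 16, seed = 5)
  f <- gabor_features(g)
  expect_equal(length(f), 24)      # 2 * 4 orientations * 3 sigmas
  # homogeneity in the input intensities
  f2 <- gabor_features(g / 2)
  expect_equal(2 * f2, f, tolerance = 1e-9)
  # constant image: mean = v * sum(kernel), sd = 0
  v <- 0.4
  fc <- gabor_features(matrix(v * 255, 16, 16))
  expected_means <- as.vector(vapply(c(0, 45, 90, 135), function(th)
    vapply(1:3, function(s) sum(gabor_kernel(th, s, 0.6)), 1), numeric(3)))
  expect_equal(fc[seq(1, 24, 2)], v * expected_means, tolerance = 1e-9)
  expect_equal(fc[seq(2, 24, 2)], rep(0, 12), tolerance = 1e-12)
})

test_that("gabor kernel has 180-degree parity for psi = 0", {
  for (th in c(0, 30, 45, 120)) for (sg in c(1, 2))
    expect_equal(gabor_kernel(th, sg, 0.6), gabor_kernel(th + 180, sg, 0.6),
                 tolerance = 1e-12)
})

test_that("HOG geometry, zero-gradient and ramp cases", {
  cfg <- descriptor_config()
  expect_equal(length(hog_features(rand_gray(128, 128, 2), cfg)), 8100)
  expect_true(all(hog_features(matrix(55, 32, 32), cfg) == 0))
  # horizontal ramp: all mass in bin 0, unit block norms
  ramp <- matrix(seq_len(24) * 1.0, 24, 24, byrow = TRUE)   # I(r, c) = c
  f <- hog_features(ramp, cfg)
  M <- matrix(f, nrow = 36)        # one block per column
  expect_equal(unname(colSums(M^2)), rep(1, ncol(M)), tolerance = 1e-12)
  bins_hit <- which(rowSums(M) > 1e-12)
  expect_true(all((bins_hit - 1) %% 9 == 0))   # only bin 0 of each cell
  expect_error(hog_features(matrix(0, 8, 8), cfg), "block")
})

test_that("HOG block norms are 0 or 1 after L2-Hys", {
  for (s in 1:5) {
    f <- hog_features(rand_gray(40, 40, seed = s))
    M <- matrix(f, nrow = 36)
    n2 <- colSums(M^2)
    expect_true(all(abs(n2 - 1) < 1e-9 | n2 == 0))
  }
})

test_that("HOG matches the definition-level oracle", {
  cfg <- cfg16()
  for (s in 1:6) {
    g <- rand_gray(16, 16, seed = 30 + s)
    expect_equal(hog_features(g, cfg), oracle_hog(g, cfg), tolerance = 1e-9)
  }
})

test_that("gabor matches the dense convolution oracle", {
  cfg <- cfg16()
  for (s in 1:3) {
    g <- rand_gray(16, 16, seed = 60 + s)
    got <- gabor_features(g, cfg)
    want <- oracle_gabor(g, cfg)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("fusion preserves order, segments and locality", {
  c1 <- runif(512); c2 <- runif(26); c3 <- runif(24); c4 <- runif(8100)
  f <- fuse_features(c1, c2, c3, c4)
  expect_equal(length(f), 8662)
  seg <- attr(f, "segments")
  expect_equal(seg$C1, c(start = 0L, end = 512L))
  expect_equal(seg$C2, c(start = 512L, end = 538L))
  expect_equal(seg$C3, c(start = 538L, end = 562L))
  expect_equal(seg$C4, c(start = 562L, end = 8662L))
  expect_identical(f[1:512], c1)
  f2 <- fuse_features(c1, rep(0, 26), c3, c4)
  expect_identical(f2[539:562], f[539:562])
  expect_error(fuse_features(c1, numeric(0), c3, c4), "non-empty")
})

test_that("descriptor histograms are non-negative and normalized everywhere", {
  for (s in 1:10) {
    img <- rand_rgb(12, 12, seed = 100 + s)
    ch <- color_histogram_3d(img)
    lh <- lbp_riu2_histogram(to_grayscale(img), 8, 1)
    expect_true(all(ch >= 0) && all(lh >= 0))
    expect_equal(sum(ch), 1, tolerance = 1e-12)
    expect_equal(sum(lh), 1, tolerance = 1e-12)
  }
})
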