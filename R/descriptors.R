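#' Descriptor configuration
#'
#' Bundles every tunable of the four descriptors.  Defaults follow the
#' reference configuration of the fusion model: joint `[8, 8, 8]` color
#' histogram, rotation-invariant uniform LBP with `P = 24`, `R = 3`
#' (`P + 2 = 26` bins), a Gabor bank at orientations 0/45/90/135 degrees
#' with frequency 0.6 cycles/pixel and sigmas 1..3, and HOG with 9 unsigned
#' orientation bins, 8x8-pixel cells, 2x2-cell blocks, L2-Hys block
#' normalization.
#'
#' @param color_bins integer triple of bins per RGB channel.
#' @param color_mode `"joint"` (3-D cube, length `prod(bins)`) or
#'   `"marginal"` (three concatenated per-channel histograms).
#' @param lbp_neighbors,lbp_radius circular LBP sampling geometry.
#' @param gabor_orientations orientations in degrees.
#' @param gabor_frequency spatial frequency in cycles/pixel (wavelength
#'   `lambda = 1/frequency`).
#' @param gabor_sigmas Gaussian envelope stddevs, one filter scale each.
#' @param gabor_phase,gabor_aspect phase offset psi (radians) and spatial
#'   aspect ratio gamma of the kernel.
#' @param hog_orientations,hog_cell,hog_block HOG geometry (bins over
#'   `[0, 180)`, cell side in pixels, block side in cells).
#' @param hog_norm `"L2-Hys"` (clip at 0.2, renormalize) or `"L2"`.
#' @param hog_vote `"bilinear"` (split between adjacent bin centers) or
#'   `"hard"`.
#' @param resize working resolution `(h, w)` applied before extraction.
#' @return a `descriptor_config` list.
#' @export
descriptor_config <- function(color_bins = c(8L, 8L, 8L),
                              color_mode = c("joint", "marginal"),
                              lbp_neighbors = 24L, lbp_radius = 3,
                              gabor_orientations = c(0, 45, 90, 135),
                              gabor_frequency = 0.6,
                              gabor_sigmas = c(1, 2, 3),
                              gabor_phase = 0, gabor_aspect = 0.5,
                              hog_orientations = 9L, hog_cell = 8L,
                              hog_block = 2L,
                              hog_norm = c("L2-Hys", "L2"),
                              hog_vote = c("bilinear", "hard"),
                              resize = c(128L, 128L)) {
  color_mode <- match.arg(color_mode)
  hog_norm <- match.arg(hog_norm)
  hog_vote <- match.arg(hog_vote)
  if (any(color_bins < 1) || lbp_neighbors < 4 || lbp_radius <= 0 ||
      gabor_frequency <= 0 || hog_orientations < 1 || hog_cell < 1 ||
      hog_block < 1)
    lf_abort("invalid descriptor configuration")
  if (length(gabor_orientations) == 0 || length(gabor_sigmas) == 0)
    lf_abort("gabor orientation and sigma lists must be non-empty")
  structure(list(color_bins = as.integer(color_bins), color_mode = color_mode,
                 lbp_neighbors = as.integer(lbp_neighbors),
                 lbp_radius = lbp_radius,
                 lbp_bins = as.integer(lbp_neighbors) + 2L,
                 gabor_orientations = gabor_orientations,
                 gabor_frequency = gabor_frequency,
                 gabor_sigmas = gabor_sigmas,
                 gabor_phase = gabor_phase, gabor_aspect = gabor_aspect,
                 hog_orientations = as.integer(hog_orientations),
                 hog_cell = as.integer(hog_cell),
                 hog_block = as.integer(hog_block),
                 hog_norm = hog_norm, hog_vote = hog_vote,
                 resize = as.integer(resize)),
            class = "descriptor_config")
}

#' Normalized color histogram (C1)
#'
#' Joint mode discretizes the RGB cube into `b1 x b2 x b3` cells: channel
#' value `v` falls in bin `floor(v * b / 256)`, and the cube is flattened
#' R-major (R slowest, then G, then B).  Marginal mode concatenates the
#' three per-channel histograms instead.  Either way the result is divided
#' by `h * w`, so it sums to one.
#'
#' @param img RGB array, intensities in `[0, 255]`.
#' @param bins integer triple of bins per channel.
#' @param mode `"joint"` or `"marginal"`.
#' @return numeric vector of length `prod(bins)` (joint) or `sum(bins)`.
#' @export
color_histogram_3d <- function(img, bins = c(8L, 8L, 8L),
                               mode = c("joint", "marginal")) {
  mode <- match.arg(mode)
  if (!is_rgb(img)) lf_abort("color_histogram_3d() expects an RGB image")
  if (any(bins < 1)) lf_abort("bins must be >= 1")
  n <- dim(img)[1] * dim(img)[2]
  idx <- function(v, b) pmin(floor(v * b / 256), b - 1)
  r <- idx(img[, , 1], bins[1]); g <- idx(img[, , 2], bins[2])
  b <- idx(img[, , 3], bins[3])
  if (mode == "joint") {
    flat <- r * (bins[2] * bins[3]) + g * bins[3] + b       # R-major, 0-based
    as.vector(tabulate(flat + 1, nbins = prod(bins))) / n
  } else {
    c(tabulate(r + 1, nbins = bins[1]),
      tabulate(g + 1, nbins = bins[2]),
      tabulate(b + 1, nbins = bins[3])) / n
  }
}

# Interpolated circular neighbor stack: for each of the P sampling points
# returns the bilinearly interpolated neighbor plane over the valid
# interior (border of width ceiling(R) excluded).  Neighbor n sits at
# angle 2*pi*n/P, with +x to the right (columns) and +y upwards (rows
# decreasing), n = 0 pointing east.
lbp_neighbor_planes <- function(g, P, R) {
  h <- nrow(g); w <- ncol(g)
  m <- ceiling(R)
  rows <- (m + 1):(h - m); cols <- (m + 1):(w - m)
  planes <- vector("list", P)
  for (n in seq_len(P) - 1) {
    ang <- 2 * pi * n / P
    dx <- R * cos(ang); dy <- -R * sin(ang)
    # snap near-integer offsets to kill FP fuzz at the 4 axial samples
    if (abs(dx - round(dx)) < 1e-9) dx <- round(dx)
    if (abs(dy - round(dy)) < 1e-9) dy <- round(dy)
    y0 <- floor(dy); x0 <- floor(dx)
    fy <- dy - y0;   fx <- dx - x0
    y1 <- if (fy > 0) y0 + 1 else y0       # zero-weight corners must still index
    x1 <- if (fx > 0) x0 + 1 else x0       # inside the valid interior
    sub <- function(oy, ox) g[rows + oy, cols + ox, drop = FALSE]
    planes[[n + 1]] <-
      (1 - fy) * (1 - fx) * sub(y0, x0) + (1 - fy) * fx * sub(y0, x1) +
      fy       * (1 - fx) * sub(y1, x0) + fy       * fx * sub(y1, x1)
  }
  list(planes = planes, center = g[rows, cols, drop = FALSE])
}

#' Rotation-invariant uniform LBP histogram (C2)
#'
#' For every pixel with a full circular neighborhood, `P` neighbors are
#' sampled at radius `R` by bilinear interpolation and thresholded against
#' the center (`S(t) = 1` for `t >= 0`, so exact ties count as 1).
#' Patterns with at most two circular 0/1 transitions ("uniform") map to
#' their number of ones (bins `0..P`); everything else goes to the
#' residual bin `P + 1`.  The returned occupancy histogram over the
#' `P + 2` bins is normalized to sum one.
#'
#' @param img grayscale matrix.
#' @param P number of circular neighbors (>= 4).
#' @param R sampling radius in pixels.
#' @return numeric vector of length `P + 2`.
#' @export
lbp_riu2_histogram <- function(img, P = 24L, R = 3) {
  g <- unclass(img)
  if (!is.matrix(g)) lf_abort("lbp_riu2_histogram() expects a grayscale matrix")
  m <- ceiling(R)
  if (nrow(g) < 2 * m + 1 || ncol(g) < 2 * m + 1)
    lf_abort("image smaller than the (2R+1)^2 neighborhood")
  if (P < 4) lf_abort("P must be >= 4")
  nb <- lbp_neighbor_planes(g, P, R)
  npx <- length(nb$center)
  # bits[i, n]: neighbor n of pixel i >= center (tolerance guards exact
  # ties against interpolation round-off)
  bits <- matrix(0L, npx, P)
  for (n in seq_len(P))
    bits[, n] <- as.integer(nb$planes[[n]] - nb$center >= -1e-9)
  ones <- rowSums(bits)
  trans <- rowSums(bits != bits[, c(2:P, 1), drop = FALSE])
  bin <- ifelse(trans <= 2, ones, P + 1)            # 0 .. P+1
  as.vector(tabulate(bin + 1, nbins = P + 2)) / npx
}

#' Rotation-invariant uniform bin of every P-bit LBP pattern
#'
#' Enumerates the codes `0 .. 2^P - 1` and maps each to its riu2 bin:
#' patterns with at most two circular 0/1 transitions map to their
#' ones-count, all others to the residual bin `P + 1`.  Vectorized with a
#' 12-bit popcount table, so the full `P = 24` enumeration (16.7M
#' patterns) runs in seconds.
#'
#' @param P number of neighbors (4..24).
#' @return integer vector of length `2^P`; `out[code + 1]` is the bin of
#'   `code`.  The number of distinct bins is `P + 2`.
#' @export
lbp_pattern_bins <- function(P = 24L) {
  if (P < 4 || P > 24) lf_abort("P must be in 4..24")
  pc12 <- integer(4096)
  for (b in 0:11) pc12 <- pc12 + bitwAnd(bitwShiftR(0:4095, b), 1L)
  popcnt <- function(v) pc12[bitwAnd(v, 4095L) + 1L] +
                        pc12[bitwShiftR(v, 12L) + 1L]
  x <- 0:(2^P - 1)
  mask <- as.integer(2^P - 1)
  rot <- bitwOr(bitwAnd(bitwShiftL(x, 1L), mask), bitwShiftR(x, P - 1L))
  trans <- popcnt(bitwXor(x, rot))
  ones <- popcnt(x)
  ifelse(trans <= 2L, ones, P + 1L)
}

# 2-D convolution with reflect padding via FFT.  `ker` must have odd side
# lengths.  Equivalent to direct spatial convolution (Eq.-style sum of
# I(i,j) * g(x-i, y-j)) up to FP round-off.
conv2_reflect <- function(img, ker) {
  kh <- nrow(ker); kw <- ncol(ker)
  ph <- (kh - 1) %/% 2; pw <- (kw - 1) %/% 2
  h <- nrow(img); w <- ncol(img)
  # reflect-pad (edge mirror without repeating the border pixel)
  ridx <- function(n, p) {
    i <- c(rev(seq_len(p) + 1), seq_len(n), n - seq_len(p))
    pmin(pmax(i, 1), n)
  }
  pad <- img[ridx(h, ph), ridx(w, pw), drop = FALSE]
  H <- nrow(pad); W <- ncol(pad)
  kf <- matrix(0, H, W)
  kf[1:kh, 1:kw] <- ker[kh:1, kw:1]       # flipped kernel for convolution
  out <- Re(stats::fft(stats::fft(pad) * stats::fft(kf), inverse = TRUE)) / (H * W)
  # alignment: full convolution offset = kernel size - 1
  out[(2 * ph + 1):(2 * ph + h), (2 * pw + 1):(2 * pw + w), drop = FALSE]
}

#' Real Gabor kernel
#'
#' `g(x, y) = exp(-(x'^2 + gamma^2 y'^2) / (2 sigma^2)) *
#'  cos(2 pi x' / lambda + psi)` with `x' = x cos(theta) + y sin(theta)`,
#' `y' = -x sin(theta) + y cos(theta)`, sampled on an odd grid of
#' half-width `ceiling(3 sigma)`.
#'
#' @param theta orientation in degrees.
#' @param sigma Gaussian envelope stddev (pixels).
#' @param frequency spatial frequency in cycles/pixel.
#' @param psi phase offset in radians.
#' @param gamma spatial aspect ratio.
#' @return numeric matrix (rows = y, columns = x).
#' @export
gabor_kernel <- function(theta, sigma, frequency, psi = 0, gamma = 0.5) {
  k <- ceiling(3 * sigma)
  lambda <- 1 / frequency
  th <- theta * pi / 180
  xs <- matrix(-k:k, 2 * k + 1, 2 * k + 1, byrow = TRUE)
  ys <- matrix(-k:k, 2 * k + 1, 2 * k + 1)
  xp <- xs * cos(th) + ys * sin(th)
  yp <- -xs * sin(th) + ys * cos(th)
  exp(-(xp^2 + gamma^2 * yp^2) / (2 * sigma^2)) * cos(2 * pi * xp / lambda + psi)
}

#' Gabor filter bank features (C3)
#'
#' Intensities are rescaled to `[0, 1]`, the image is convolved (reflect
#' padding) with the real Gabor kernel for every `(orientation, sigma)`
#' pair, and each response contributes its mean and standard deviation.
#' Output order: orientation outer, sigma inner, mean before sd --
#' `2 * |orientations| * |sigmas|` values.
#'
#' @param img grayscale matrix, intensities in `[0, 255]`.
#' @param cfg a [descriptor_config()].
#' @return numeric feature vector.
#' @export
gabor_features <- function(img, cfg = descriptor_config()) {
  g <- unclass(img)
  if (!is.matrix(g)) lf_abort("gabor_features() expects a grayscale matrix")
  g <- g / 255
  out <- numeric(0)
  for (th in cfg$gabor_orientations) for (sg in cfg$gabor_sigmas) {
    ker <- gabor_kernel(th, sg, cfg$gabor_frequency,
                        cfg$gabor_phase, cfg$gabor_aspect)
    r <- conv2_reflect(g, ker)
    out <- c(out, mean(r), stats::sd(as.vector(r)))
  }
  out
}

#' Histogram of oriented gradients (C4)
#'
#' Central-difference gradients with edge replication; unsigned
#' orientation in `[0, 180)`; per-cell histograms with magnitude-weighted
#' votes split bilinearly between the two nearest bin centers (centers at
#' `i * 180 / nbins`, wrapping at 180); blocks of `hog_block^2` cells at
#' 1-cell stride, each block vector L2-normalized (then clipped at 0.2 and
#' renormalized for `"L2-Hys"`; all-zero blocks stay zero); blocks
#' concatenated row-major.  If the image is not divisible by the cell
#' size it is cropped to the largest multiple with a warning.
#'
#' @param img grayscale matrix.
#' @param cfg a [descriptor_config()].
#' @return numeric vector of length
#'   `(cells_r - block + 1) * (cells_c - block + 1) * block^2 * orientations`.
#' @export
hog_features <- function(img, cfg = descriptor_config()) {
  g <- unclass(img)
  if (!is.matrix(g)) lf_abort("hog_features() expects a grayscale matrix")
  cell <- cfg$hog_cell; blk <- cfg$hog_block; nb <- cfg$hog_orientations
  h <- nrow(g); w <- ncol(g)
  if (h < cell * blk || w < cell * blk)
    lf_abort("image smaller than one HOG block")
  ch <- (h %/% cell) * cell; cw <- (w %/% cell) * cell
  if (ch != h || cw != w) {
    warning("cropping image from ", h, "x", w, " to ", ch, "x", cw,
            " (largest cell multiple)", call. = FALSE)
    g <- g[1:ch, 1:cw]; h <- ch; w <- cw
  }

  up <- g[c(1, 1:(h - 1)), , drop = FALSE]     # edge-replicated shifts
  dn <- g[c(2:h, h), , drop = FALSE]
  lf <- g[, c(1, 1:(w - 1)), drop = FALSE]
  rt <- g[, c(2:w, w), drop = FALSE]
  gr <- dn - up                                # d/d(row)
  gc <- rt - lf                                # d/d(col)
  mag <- sqrt(gr^2 + gc^2)
  ang <- (atan2(gr, gc) * 180 / pi) %% 180     # unsigned, [0, 180)

  binw <- 180 / nb
  pos <- ang / binw                            # continuous bin coordinate
  b0 <- floor(pos) %% nb
  frac <- pos - floor(pos)
  if (cfg$hog_vote == "hard") { b0 <- round(pos) %% nb; frac <- frac * 0 }
  b1 <- (b0 + 1) %% nb

  cells_r <- h %/% cell; cells_c <- w %/% cell
  cell_of <- (((row(g) - 1) %/% cell) * cells_c + ((col(g) - 1) %/% cell))
  # accumulate magnitude-weighted votes into (cell, bin) table
  acc <- function(bin, wgt) {
    key <- cell_of * nb + bin + 1
    v <- numeric(cells_r * cells_c * nb)
    t <- tapply(wgt, key, sum)
    v[as.integer(names(t))] <- t
    v
  }
  hist_flat <- acc(b0, mag * (1 - frac)) + acc(b1, mag * frac)
  # cell_hist[bin, cell] with cells indexed row-major
  cell_hist <- matrix(hist_flat, nrow = nb)

  out <- numeric(0)
  blocks <- vector("list", (cells_r - blk + 1) * (cells_c - blk + 1))
  bi <- 1
  for (br in 0:(cells_r - blk)) for (bc in 0:(cells_c - blk)) {
    ids <- as.vector(t(outer((br):(br + blk - 1) * cells_c,
                             (bc + 1):(bc + blk), `+`)))
    v <- as.vector(cell_hist[, ids])
    nv <- sqrt(sum(v^2))
    if (nv > 0) {
      v <- v / nv
      if (cfg$hog_norm == "L2-Hys") {
        v <- pmin(v, 0.2)
        nv2 <- sqrt(sum(v^2))
        if (nv2 > 0) v <- v / nv2
      }
    }
    blocks[[bi]] <- v; bi <- bi + 1
  }
  unlist(blocks, use.names = FALSE)
}

#' Fuse the four descriptors into one feature vector
#'
#' Concatenates C1 (color), C2 (LBP), C3 (Gabor), C4 (HOG) in that fixed
#' order and records the half-open index range of every segment.
#'
#' @param c1,c2,c3,c4 non-empty numeric vectors.
#' @return numeric vector with attribute `segments`: a named list of
#'   0-based `[start, end)` ranges.
#' @export
fuse_features <- function(c1, c2, c3, c4) {
  parts <- list(C1 = c1, C2 = c2, C3 = c3, C4 = c4)
  if (any(vapply(parts, length, 1L) == 0))
    lf_abort("all four descriptor vectors must be non-empty")
  lens <- vapply(parts, length, 1L)
  ends <- cumsum(lens); starts <- c(0L, ends[-4])
  seg <- Map(function(s, e) c(start = s, end = e),
             as.integer(starts), as.integer(ends))
  names(seg) <- names(parts)
  structure(unlist(parts, use.names = FALSE), segments = seg)
}

#' Extract the fused descriptor for one image
#'
#' Resizes to the working resolution, converts to grayscale, and computes
#' and fuses all four descriptors.
#'
#' @param img RGB array.
#' @param cfg a [descriptor_config()].
#' @return fused feature vector (see [fuse_features()]).
#' @export
extract_image_features <- function(img, cfg = descriptor_config()) {
  img <- resize_bilinear(img, cfg$resize[1], cfg$resize[2])
  g <- to_grayscale(img)
  fuse_features(color_histogram_3d(img, cfg$color_bins, cfg$color_mode),
                lbp_riu2_histogram(g, cfg$lbp_neighbors, cfg$lbp_radius),
                gabor_features(g, cfg),
                hog_features(g, cfg))
}

#' Extract fused features for a whole dataset
#'
#' @param dataset a `labelled_dataset` (from [load_dataset()] or
#'   [generate_dataset()]).
#' @param cfg a [descriptor_config()].
#' @param verbose print progress.
#' @return a [feature_matrix()] with one row per image, in dataset order.
#' @export
extract_features <- function(dataset, cfg = descriptor_config(),
                             verbose = FALSE) {
  recs <- dataset$records
  rows <- vector("list", nrow(recs))
  for (i in seq_len(nrow(recs))) {
    if (verbose && i %% 25 == 1)
      message("extracting ", i, "/", nrow(recs))
    rows[[i]] <- extract_image_features(read_image(recs$path[i]), cfg)
  }
  X <- do.call(rbind, rows)
  feature_matrix(X, recs$label, names(dataset$label_map),
                 segments = attr(rows[[1]], "segments"))
}
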