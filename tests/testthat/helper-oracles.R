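# Independent brute-force reference implementations of the descriptors.
# Deliberately loop-based and definition-level; they share no code with
# the package internals they check.

oracle_color_hist <- function(img, bins = c(8, 8, 8)) {
  h <- dim(img)[1]; w <- dim(img)[2]
  H <- array(0, bins)
  for (y in seq_len(h)) for (x in seq_len(w)) {
    b <- integer(3)
    for (ch in 1:3) b[ch] <- min(floor(img[y, x, ch] * bins[ch] / 256), bins[ch] - 1)
    H[b[1] + 1, b[2] + 1, b[3] + 1] <- H[b[1] + 1, b[2] + 1, b[3] + 1] + 1
  }
  # R-major flattening: R slowest
  out <- numeric(prod(bins))
  i <- 1
  for (r in seq_len(bins[1])) for (g in seq_len(bins[2])) for (b in seq_len(bins[3])) {
    out[i] <- H[r, g, b]; i <- i + 1
  }
  out / (h * w)
}

# bilinear sample of matrix m at fractional (row, col), 1-based
oracle_bilinear_at <- function(m, rr, cc) {
  r0 <- floor(rr); c0 <- floor(cc)
  fr <- rr - r0; fc <- cc - c0
  r1 <- min(r0 + 1, nrow(m)); c1 <- min(c0 + 1, ncol(m))
  (1 - fr) * (1 - fc) * m[r0, c0] + (1 - fr) * fc * m[r0, c1] +
    fr * (1 - fc) * m[r1, c0] + fr * fc * m[r1, c1]
}

oracle_lbp_riu2 <- function(g, P, R) {
  m <- ceiling(R)
  h <- nrow(g); w <- ncol(g)
  hist <- numeric(P + 2)
  for (y in (m + 1):(h - m)) for (x in (m + 1):(w - m)) {
    bits <- integer(P)
    for (n in 0:(P - 1)) {
      ang <- 2 * pi * n / P
      dx <- R * cos(ang); dy <- -R * sin(ang)
      if (abs(dx - round(dx)) < 1e-9) dx <- round(dx)
      if (abs(dy - round(dy)) < 1e-9) dy <- round(dy)
      v <- oracle_bilinear_at(g, y + dy, x + dx)
      bits[n + 1] <- as.integer(v - g[y, x] >= -1e-9)
    }
    trans <- sum(bits != c(bits[-1], bits[1]))
    bin <- if (trans <= 2) sum(bits) else P + 1
    hist[bin + 1] <- hist[bin + 1] + 1
  }
  hist / sum(hist)
}

# dense spatial convolution with symmetric-reflect padding: per output
# pixel, the sum I(i, j) * g(y - i, x - j) over the kernel support,
# realized as a patch product against the flipped kernel
oracle_conv2 <- function(img, ker) {
  kh <- nrow(ker); kw <- ncol(ker)
  ph <- (kh - 1) %/% 2; pw <- (kw - 1) %/% 2
  h <- nrow(img); w <- ncol(img)
  refl <- function(i, n) {
    i <- ifelse(i < 1, 2 - i, i)
    ifelse(i > n, 2 * n - i, i)
  }
  pad <- img[refl((1 - ph):(h + ph), h), refl((1 - pw):(w + pw), w)]
  kflip <- ker[kh:1, kw:1]
  out <- matrix(0, h, w)
  for (y in seq_len(h)) for (x in seq_len(w))
    out[y, x] <- sum(pad[y:(y + kh - 1), x:(x + kw - 1)] * kflip)
  out
}

oracle_gabor <- function(g, cfg) {
  g <- g / 255
  out <- numeric(0)
  for (th in cfg$gabor_orientations) for (sg in cfg$gabor_sigmas) {
    ker <- gabor_kernel(th, sg, cfg$gabor_frequency,
                        cfg$gabor_phase, cfg$gabor_aspect)
    r <- oracle_conv2(g, ker)
    out <- c(out, mean(r), sd(as.vector(r)))
  }
  out
}

oracle_hog <- function(g, cfg) {
  cell <- cfg$hog_cell; blk <- cfg$hog_block; nb <- cfg$hog_orientations
  h <- nrow(g); w <- ncol(g)
  cells_r <- h %/% cell; cells_c <- w %/% cell
  hist <- array(0, c(cells_r, cells_c, nb))
  for (y in seq_len(h)) for (x in seq_len(w)) {
    gr <- g[min(y + 1, h), x] - g[max(y - 1, 1), x]
    gc <- g[y, min(x + 1, w)] - g[y, max(x - 1, 1)]
    mag <- sqrt(gr^2 + gc^2)
    ang <- (atan2(gr, gc) * 180 / pi) %% 180
    pos <- ang / (180 / nb)
    b0 <- floor(pos) %% nb; frac <- pos - floor(pos)
    b1 <- (b0 + 1) %% nb
    cr <- (y - 1) %/% cell + 1; cc <- (x - 1) %/% cell + 1
    hist[cr, cc, b0 + 1] <- hist[cr, cc, b0 + 1] + mag * (1 - frac)
    hist[cr, cc, b1 + 1] <- hist[cr, cc, b1 + 1] + mag * frac
  }
  out <- numeric(0)
  for (br in 0:(cells_r - blk)) for (bc in 0:(cells_c - blk)) {
    v <- numeric(0)
    for (r in (br + 1):(br + blk)) for (c in (bc + 1):(bc + blk))
      v <- c(v, hist[r, c, ])
    nv <- sqrt(sum(v^2))
    if (nv > 0) {
      v <- v / nv
      if (cfg$hog_norm == "L2-Hys") {
        v <- pmin(v, 0.2)
        v <- v / sqrt(sum(v^2))
      }
    }
    out <- c(out, v)
  }
  out
}
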