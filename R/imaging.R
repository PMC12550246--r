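#' Image containers
#'
#' Images are stored as plain numeric arrays of 8-bit intensities:
#' an RGB image is an `h x w x 3` array and a grayscale image an `h x w`
#' matrix, both with values in `[0, 255]` (row 1 = top of the image).
#' `rgb_image()` / `gray_image()` validate and tag an array; most package
#' functions accept untagged arrays of the right shape as well.
#'
#' @param x numeric array (`h x w x 3`) or matrix (`h x w`).
#' @return the validated array with class `"rgb_image"` / `"gray_image"`.
#' @export
rgb_image <- function(x) {
  if (length(dim(x)) != 3L || dim(x)[3] != 3L)
    lf_abort("an RGB image must be an h x w x 3 array")
  if (dim(x)[1] < 1L || dim(x)[2] < 1L)
    lf_abort("image must have positive height and width")
  if (anyNA(x) || min(x) < 0 || max(x) > 255)
    lf_abort("intensities must lie in [0, 255]")
  structure(x, class = "rgb_image")
}

#' @rdname rgb_image
#' @export
gray_image <- function(x) {
  if (!is.matrix(x)) lf_abort("a grayscale image must be an h x w matrix")
  if (anyNA(x) || min(x) < 0 || max(x) > 255)
    lf_abort("intensities must lie in [0, 255]")
  structure(x, class = "gray_image")
}

is_rgb <- function(x) length(dim(x)) == 3L && dim(x)[3] == 3L
is_gray <- function(x) is.matrix(x)

#' Read / write an image file
#'
#' PNG and JPEG are supported.  Pixels are returned on the 0--255 scale.
#' Grayscale files come back as a matrix, color files as an `h x w x 3`
#' array (an alpha channel, if present, is dropped).
#'
#' @param path file path; format inferred from the extension.
#' @return numeric array or matrix of intensities in `[0, 255]`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png  = png::readPNG(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    lf_abort("unsupported image format: ", ext))
  x <- round_half_up(raw * 255)
  if (length(dim(x)) == 3L && dim(x)[3] >= 3L) x <- x[, , 1:3, drop = FALSE]
  if (length(dim(x)) == 3L && dim(x)[3] == 1L) x <- x[, , 1]
  x
}

#' @rdname read_image
#' @param img image array or matrix with intensities in `[0, 255]`.
#' @export
write_image <- function(img, path) {
  scaled <- clamp(unclass(img), 0, 255) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(scaled, path),
    jpg  = ,
    jpeg = jpeg::writeJPEG(scaled, path, quality = 0.95),
    lf_abort("unsupported image format: ", ext))
  invisible(path)
}

#' Bilinear image resize
#'
#' Standard bilinear interpolation: every target pixel is the fractional-
#' weight combination of the four enclosing source pixels, channels handled
#' independently, results clipped to `[0, 255]`.  With `align = "scale"`
#' (the default) the source coordinate of target index `i` (0-based) is
#' `i * src / target` with edge clamping; `align = "corners"` maps the
#' first and last sample exactly onto the image corners
#' (`i * (src - 1) / (target - 1)`).
#'
#' @param img RGB array or grayscale matrix, intensities in `[0, 255]`.
#' @param target_h,target_w positive integer output size.
#' @param align `"scale"` or `"corners"` coordinate mapping.
#' @return resized image of the same kind as the input.
#' @export
resize_bilinear <- function(img, target_h, target_w,
                            align = c("scale", "corners")) {
  align <- match.arg(align)
  if (target_h < 1 || target_w < 1)
    lf_abort("target size must be positive")
  target_h <- as.integer(target_h); target_w <- as.integer(target_w)
  d <- dim(img)
  src_h <- d[1]; src_w <- d[2]
  if (src_h == target_h && src_w == target_w) return(img)

  coords <- function(n_src, n_tgt) {
    i <- seq_len(n_tgt) - 1
    if (align == "corners" && n_tgt > 1) i * (n_src - 1) / (n_tgt - 1)
    else clamp(i * n_src / n_tgt, 0, n_src - 1)
  }
  ry <- coords(src_h, target_h); rx <- coords(src_w, target_w)
  y0 <- pmin(floor(ry), src_h - 1); x0 <- pmin(floor(rx), src_w - 1)
  y1 <- pmin(y0 + 1, src_h - 1);    x1 <- pmin(x0 + 1, src_w - 1)
  fy <- ry - y0; fx <- rx - x0

  one_plane <- function(p) {
    # separable gather: rows first, then columns
    top <- p[y0 + 1, , drop = FALSE] * (1 - fy) + p[y1 + 1, , drop = FALSE] * fy
    out <- top[, x0 + 1, drop = FALSE] * rep(1 - fx, each = target_h) +
           top[, x1 + 1, drop = FALSE] * rep(fx, each = target_h)
    clamp(out, 0, 255)
  }

  if (is_rgb(img)) {
    out <- array(0, c(target_h, target_w, 3))
    for (ch in 1:3) out[, , ch] <- one_plane(img[, , ch])
    structure(out, class = if (inherits(img, "rgb_image")) "rgb_image")
  } else {
    structure(one_plane(unclass(img)),
              class = if (inherits(img, "gray_image")) "gray_image")
  }
}

#' RGB to grayscale conversion
#'
#' ITU-R BT.601 luma: `0.299 R + 0.587 G + 0.114 B`, rounded half-up to an
#' integer intensity.
#'
#' @param img RGB array with intensities in `[0, 255]`.
#' @return grayscale matrix (class `"gray_image"`).
#' @export
to_grayscale <- function(img) {
  if (!is_rgb(img)) lf_abort("to_grayscale() expects an h x w x 3 array")
  g <- round_half_up(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
  gray_image(matrix(clamp(g, 0, 255), dim(img)[1], dim(img)[2]))
}

#' Integer label encoding
#'
#' Distinct class names are sorted lexicographically (C locale) and mapped
#' to the codes `0 .. k-1`.
#'
#' @param names character vector of class names (duplicates allowed).
#' @return named integer vector: `label_map[class] == code`.
#' @export
encode_labels <- function(names) {
  if (length(names) == 0) lf_abort("cannot encode an empty label set")
  u <- sort(unique(as.character(names)), method = "radix")
  stats::setNames(seq_along(u) - 1L, u)
}

#' Index an on-disk leaf image dataset
#'
#' Expects a `class-per-folder` layout: `root/<class>/<image>.{png,jpg}`.
#' Records are sorted by (class, file name) so the index, and therefore
#' every seed-driven step downstream, is platform independent.  Unreadable
#' image files are skipped with a warning.
#'
#' @param root dataset directory.
#' @param group_manifest optional path to a two-column CSV
#'   (`class,group`) assigning classes to morphological groups.
#' @return a `labelled_dataset`: list with `records` (data.frame of
#'   `path`, `class`, `label`, `group`) and `label_map`.
#' @export
load_dataset <- function(root, group_manifest = NULL) {
  if (!dir.exists(root)) lf_abort("dataset root not found: ", root)
  classes <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE),
                  method = "radix")
  if (length(classes) < 2) lf_abort("need at least 2 class folders, found ",
                                    length(classes))
  groups <- NULL
  if (!is.null(group_manifest)) {
    gm <- utils::read.csv(group_manifest, stringsAsFactors = FALSE)
    groups <- stats::setNames(gm[[2]], gm[[1]])
  }
  label_map <- encode_labels(classes)
  recs <- list()
  for (cl in classes) {
    files <- sort(list.files(file.path(root, cl),
                             pattern = "\\.(png|jpg|jpeg)$",
                             ignore.case = TRUE, full.names = TRUE),
                  method = "radix")
    ok <- logical(length(files))
    for (i in seq_along(files)) {
      ok[i] <- tryCatch({ read_image(files[i]); TRUE },
                        error = function(e) {
                          warning("skipping unreadable image: ", files[i],
                                  call. = FALSE)
                          FALSE
                        })
    }
    files <- files[ok]
    if (length(files) == 0) lf_abort("class folder has no readable image: ", cl)
    recs[[cl]] <- data.frame(path = files, class = cl,
                             label = unname(label_map[cl]),
                             group = if (is.null(groups)) NA_character_
                                     else as.character(groups[cl] %||% NA),
                             stringsAsFactors = FALSE)
  }
  structure(list(records = do.call(rbind, c(recs, make.row.names = FALSE)),
                 label_map = label_map),
            class = "labelled_dataset")
}

#' @export
print.labelled_dataset <- function(x, ...) {
  k <- length(x$label_map)
  cat("<labelled_dataset> ", nrow(x$records), " images, ", k, " classes\n",
      sep = "")
  print(table(x$records$class))
  invisible(x)
}
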