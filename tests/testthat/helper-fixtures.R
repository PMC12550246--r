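# Memoized fixtures shared across test files; generated once per session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# seeded random grayscale / rgb test images
rand_gray <- function(h, w, seed) {
  set.seed(seed)
  matrix(sample(0:255, h * w, replace = TRUE), h, w)
}
rand_rgb <- function(h, w, seed) {
  set.seed(seed)
  array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3))
}

# 3 well-separated classes, 10 images each, written to disk at 64x64
fixture_separable <- function() fixture("separable", function() {
  dir <- file.path(tempdir(), "lf_separable")
  spec <- synthetic_dataset_spec(demo_class_specs(3), images_per_class = 10,
                                 image_size = c(64, 64), seed = 101)
  list(dataset = generate_dataset(spec, dir), spec = spec, dir = dir)
})

# color-matched, texture-differing pair at full working resolution
fixture_lookalike <- function() fixture("lookalike", function() {
  dir <- file.path(tempdir(), "lf_lookalike")
  spec <- synthetic_dataset_spec(lookalike_class_specs(),
                                 images_per_class = 12,
                                 image_size = c(128, 128), seed = 202)
  list(dataset = generate_dataset(spec, dir), spec = spec, dir = dir)
})

# fused features of the separable fixture at 64x64 working resolution
fixture_separable_features <- function() fixture("separable_fm", function() {
  cfg <- descriptor_config(resize = c(64, 64))
  list(fm = extract_features(fixture_separable()$dataset, cfg), cfg = cfg)
})

# fused features of the look-alike pair at full 128x128 resolution
fixture_lookalike_features <- function() fixture("lookalike_fm", function() {
  extract_features(fixture_lookalike()$dataset)
})

cfg16 <- function(...) descriptor_config(resize = c(16L, 16L), ...)
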