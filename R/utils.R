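#' @useDynLib leaffusion, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd var predict glm binomial coef quantile
#' @importFrom utils write.csv head
NULL

# Evaluate expr under a fixed RNG state without disturbing the caller's
# stream.  All stochastic entry points in the package funnel through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic sub-seed derivation, insertion-order independent: each
# (class, image) pair gets its own stream keyed on the root seed.  Kept
# below 2^31 - 2 so set.seed() accepts it on 32-bit R integers.
derive_seed <- function(root, ...) {
  parts <- c(as.numeric(root), as.numeric(c(...)))
  h <- 0
  for (p in parts) h <- (h * 1000003 + (p %% 2147483647)) %% 2147483629
  as.integer(h %% 2147483629) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# round-half-up (base round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

lf_abort <- function(..., class = "leaffusion_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
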