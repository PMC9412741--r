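#' @importFrom rlang abort warn
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm runif prcomp
NULL

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. All stochastic operations in the package route
# their randomness through this helper so no call mutates global RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, expr)
}

# Derive a child seed from a parent seed and a stream index, staying within
# 32-bit integer range.
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 69069 + as.numeric(index) * 1013) %% 2147483647)
}

assert_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min),
          class = "elytra_invalid_argument")
  }
  as.integer(x)
}

assert_fraction <- function(x, name, lo = 0, hi = 1, open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) &&
    (if (open) x > lo && x < hi else x >= lo && x <= hi)
  if (!ok) {
    abort(sprintf("`%s` must be a number in %s%g, %g%s.",
                  name, if (open) "(" else "[", lo, hi, if (open) ")" else "]"),
          class = "elytra_invalid_argument")
  }
  as.numeric(x)
}

# Convert an H x W x 3 array (or H x W matrix) to grayscale H x W.
to_gray <- function(pixels) {
  if (length(dim(pixels)) == 3) {
    (pixels[, , 1] + pixels[, , 2] + pixels[, , 3]) / 3
  } else {
    pixels
  }
}

clip01 <- function(x) pmin(pmax(x, 0), 1)
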