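#' Stochastic affine augmentation policy
#'
#' Configuration of the geometric augmentation applied to training tiles
#' (and only to training tiles): random rotation, horizontal/vertical
#' shifts, shear, zoom and horizontal flips, with out-of-image samples
#' filled from the nearest edge pixel. Defaults are the study policy:
#' rotations up to 40 degrees, shifts up to 20% of the tile side, shear up
#' to 0.2 degrees, zoom in `[0.8, 1.2]`, horizontal flips on, nearest
#' fill.
#'
#' @param rotation_range Maximum absolute rotation, degrees.
#' @param width_shift_range,height_shift_range Maximum absolute shift as a
#'   fraction of tile width/height.
#' @param shear_range Maximum absolute shear angle, degrees
#'   (counterclockwise).
#' @param zoom_range Zoom is drawn from `[1 - zoom_range, 1 + zoom_range]`.
#' @param horizontal_flip Enable random horizontal flips (probability 0.5).
#' @param fill_mode Only `"nearest"` is supported.
#' @return A list of class `"augmentation_config"`.
#' @export
augmentation_config <- function(rotation_range = 40,
                                width_shift_range = 0.2,
                                height_shift_range = 0.2,
                                shear_range = 0.2,
                                zoom_range = 0.2,
                                horizontal_flip = TRUE,
                                fill_mode = "nearest") {
  for (nm in c("rotation_range", "width_shift_range", "height_shift_range",
               "shear_range", "zoom_range")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0) {
      abort(sprintf("`%s` must be a single non-negative number.", nm),
            class = "elytra_invalid_argument")
    }
  }
  fill_mode <- match.arg(fill_mode, "nearest")
  structure(list(rotation_range = rotation_range,
                 width_shift_range = width_shift_range,
                 height_shift_range = height_shift_range,
                 shear_range = shear_range,
                 zoom_range = zoom_range,
                 horizontal_flip = isTRUE(horizontal_flip),
                 fill_mode = fill_mode),
            class = "augmentation_config")
}

#' Draw one set of augmentation parameters
#'
#' Each parameter is drawn uniformly from its symmetric interval; the flip
#' indicator is Bernoulli(0.5) when flips are enabled. Uses the current R
#' RNG state, so draws are deterministic under a seeded caller. A zero
#' config with flips off always yields the exact identity parameters.
#'
#' @param config An [augmentation_config()].
#' @param size Tile side in pixels (shift fractions are converted to pixel
#'   offsets).
#' @return A list of class `"augmentation_params"` with `angle` (deg),
#'   `dx`, `dy` (px), `shear` (deg), `zoom` (scale), `flip` (logical).
#' @export
sample_augmentation <- function(config, size) {
  stopifnot(inherits(config, "augmentation_config"))
  size <- assert_scalar_count(size, "size", min = 1L)
  structure(list(
    angle = runif(1, -config$rotation_range, config$rotation_range),
    dx = runif(1, -config$width_shift_range, config$width_shift_range) * size,
    dy = runif(1, -config$height_shift_range, config$height_shift_range) * size,
    shear = runif(1, -config$shear_range, config$shear_range),
    zoom = runif(1, 1 - config$zoom_range, 1 + config$zoom_range),
    flip = config$horizontal_flip && runif(1) < 0.5
  ), class = "augmentation_params")
}

#' Explicit augmentation parameters
#' @param angle,dx,dy,shear,zoom,flip See [sample_augmentation()].
#' @return A list of class `"augmentation_params"`.
#' @export
augmentation_params <- function(angle = 0, dx = 0, dy = 0, shear = 0,
                                zoom = 1, flip = FALSE) {
  structure(list(angle = angle, dx = dx, dy = dy, shear = shear,
                 zoom = zoom, flip = isTRUE(flip)),
            class = "augmentation_params")
}

#' Apply one affine augmentation to a square tile
#'
#' A single affine resampling composed, about the tile center, of rotation,
#' then shear (along x), then isotropic zoom, then translation; an optional
#' horizontal flip is applied last as an exact mirror. Interpolation is
#' bilinear; source coordinates falling outside the tile are clamped to the
#' nearest edge pixel ("nearest" fill). Identity parameters reproduce the
#' input bit-exactly, and output dimensions always equal input dimensions.
#'
#' @param pixels S x S x C (or S x S) numeric array.
#' @param params An [augmentation_params()] /
#'   [sample_augmentation()] result.
#' @return Array of the same dimensions.
#' @export
apply_augmentation <- function(pixels, params) {
  stopifnot(inherits(params, "augmentation_params"))
  d <- dim(pixels)
  if (is.null(d) || d[1] != d[2] || d[1] < 1) {
    abort("tile must be a non-empty square array.", class = "elytra_invalid_argument")
  }
  S <- d[1]
  identity_affine <- params$angle == 0 && params$shear == 0 &&
    params$zoom == 1 && params$dx == 0 && params$dy == 0
  if (identity_affine) {
    out <- pixels
  } else {
    th <- params$angle * pi / 180
    sh <- params$shear * pi / 180
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    Sh <- matrix(c(1, 0, tan(sh), 1), 2, 2)
    A <- params$zoom * (Sh %*% R)      # forward: p' = A (p - c) + c + t
    Ai <- solve(A)
    cc <- (S + 1) / 2
    xo <- rep(seq_len(S) - cc, each = S)      # output x (col), column-major order
    yo <- rep(seq_len(S) - cc, times = S)     # output y (row)
    u <- xo - params$dx
    v <- yo - params$dy
    xs <- Ai[1, 1] * u + Ai[1, 2] * v + cc
    ys <- Ai[2, 1] * u + Ai[2, 2] * v + cc
    xs <- pmin(pmax(xs, 1), S)                # nearest-edge fill via clamping
    ys <- pmin(pmax(ys, 1), S)
    x0 <- pmin(floor(xs), S - 1); y0 <- pmin(floor(ys), S - 1)
    fx <- xs - x0; fy <- ys - y0
    i00 <- (x0 - 1) * S + y0
    i01 <- x0 * S + y0
    i10 <- i00 + 1
    i11 <- i01 + 1
    w00 <- (1 - fx) * (1 - fy); w01 <- fx * (1 - fy)
    w10 <- (1 - fx) * fy; w11 <- fx * fy
    resample <- function(plane) {
      p <- as.numeric(plane)
      matrix(w00 * p[i00] + w01 * p[i01] + w10 * p[i10] + w11 * p[i11], S, S)
    }
    if (length(d) == 3) {
      out <- array(0, d)
      for (ch in seq_len(d[3])) out[, , ch] <- resample(pixels[, , ch])
    } else {
      out <- resample(pixels)
    }
  }
  if (params$flip) {
    if (length(d) == 3) out <- out[, S:1, , drop = FALSE] else out <- out[, S:1, drop = FALSE]
  }
  out
}
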