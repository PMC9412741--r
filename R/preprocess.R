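#' Detect the elytral border and build a foreground mask
#'
#' Specimen photographs place the elytron at the center of a near-white
#' background. The border is recovered in three steps: (1) after a 2 px
#' Gaussian smoothing, pixels with grayscale above 0.92 are marked as
#' candidate background and the largest complementary connected component
#' is kept with holes filled; (2) the boundary is then snapped toward the
#' line of maximum change in contrast by re-thresholding at the midpoint
#' between the mean foreground and mean background intensity (the midpoint
#' of a smoothed edge ramp is its maximum-gradient locus); (3) the
#' refinement is confined to a +/- 3 px band around the initial boundary so
#' it can only sharpen the border, never relocate it.
#'
#' @param image H x W x 3 (or H x W) numeric array with intensities in
#'   `[0, 1]`.
#' @return An object of class `"foreground_mask"`: a list with `mask`
#'   (H x W logical), `bounding_box` (`c(row_min, col_min, row_max,
#'   col_max)`, 1-based inclusive), and `area` (foreground pixel count).
#' @seealso [crop_to_foreground()], [sample_tiles()]
#' @export
detect_elytra_border <- function(image) {
  gray <- to_gray(image)
  if (any(gray < 0) || any(gray > 1)) {
    abort("image intensities must lie in [0, 1].", class = "elytra_invalid_argument")
  }
  gray_s <- as.matrix(EBImage::gblur(gray, sigma = 2))
  cand <- gray_s <= 0.92
  if (!any(cand)) {
    abort("no pixel below the background threshold: image appears to be all background.",
          class = "elytra_no_foreground")
  }
  mask <- largest_component(cand)

  if (any(!mask)) {
    fg_mean <- mean(gray_s[mask])
    bg_mean <- mean(gray_s[!mask])
    tstar <- (fg_mean + bg_mean) / 2
    band <- EBImage::makeBrush(7, shape = "disc")  # radius 3
    dilated <- as.matrix(EBImage::dilate(mask * 1, band)) > 0
    eroded <- as.matrix(EBImage::erode(mask * 1, band)) > 0
    refined <- ((gray_s <= tstar) & dilated) | eroded
    if (any(refined)) mask <- largest_component(refined)
  }

  new_foreground_mask(mask)
}

largest_component <- function(binary) {
  lab <- EBImage::bwlabel(binary * 1)
  tab <- tabulate(as.integer(lab))
  keep <- which.max(tab)
  comp <- matrix(as.integer(lab) == keep, nrow(binary), ncol(binary))
  as.matrix(EBImage::fillHull(comp * 1)) > 0
}

new_foreground_mask <- function(mask) {
  stopifnot(is.logical(mask), any(mask))
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  structure(
    list(mask = mask,
         bounding_box = c(row_min = rows[1], col_min = cols[1],
                          row_max = rows[2], col_max = cols[2]),
         area = sum(mask)),
    class = "foreground_mask"
  )
}

#' @export
print.foreground_mask <- function(x, ...) {
  bb <- x$bounding_box
  cat(sprintf("<foreground_mask> %d x %d, area %d px, bbox rows %d..%d cols %d..%d\n",
              nrow(x$mask), ncol(x$mask), x$area, bb[1], bb[3], bb[2], bb[4]))
  invisible(x)
}

#' Crop an image to its foreground bounding box
#'
#' Removes the background: the image is cropped to the tight bounding box
#' of the mask and any pixel inside the box but outside the mask is set to
#' pure white.
#'
#' @param image H x W x 3 (or H x W) numeric array.
#' @param mask A [detect_elytra_border()] result with matching dimensions.
#' @return The cropped array (box height x box width x channels).
#' @export
crop_to_foreground <- function(image, mask) {
  stopifnot(inherits(mask, "foreground_mask"))
  dm <- dim(image)
  if (dm[1] != nrow(mask$mask) || dm[2] != ncol(mask$mask)) {
    abort("image and mask dimensions differ.", class = "elytra_invalid_argument")
  }
  bb <- mask$bounding_box
  rows <- bb[1]:bb[3]; cols <- bb[2]:bb[4]
  sub_mask <- mask$mask[rows, cols, drop = FALSE]
  if (length(dm) == 3) {
    out <- image[rows, cols, , drop = FALSE]
    for (ch in seq_len(dm[3])) {
      plane <- out[, , ch]
      plane[!sub_mask] <- 1
      out[, , ch] <- plane
    }
  } else {
    out <- image[rows, cols, drop = FALSE]
    out[!sub_mask] <- 1
  }
  out
}

# Valid top-left tile origins: positions whose full size x size footprint is
# mask-true, found by an exact integral-image (summed-area table) test.
tile_positions <- function(mask, size) {
  H <- nrow(mask); W <- ncol(mask)
  if (H < size || W < size) return(matrix(integer(0), 0, 2))
  sat <- matrix(0, H + 1, W + 1)
  sat[-1, -1] <- apply(apply(mask, 2, cumsum), 1, cumsum) |> t()
  nr <- H - size + 1; nc <- W - size + 1
  win <- sat[(1 + size):(H + 1), (1 + size):(W + 1)] -
    sat[1:nr, (1 + size):(W + 1)] -
    sat[(1 + size):(H + 1), 1:nc] +
    sat[1:nr, 1:nc]
  ok <- which(win == size * size, arr.ind = TRUE)
  colnames(ok) <- c("row", "col")
  ok
}

#' Randomly sample fixed-size tiles inside the elytral border
#'
#' Simulated fragmentation: samples `n` square tiles whose full
#' `size x size` footprints lie strictly inside the foreground mask,
#' uniformly over all valid top-left positions, with replacement (tiles may
#' overlap or repeat — the number of crops is fixed regardless of elytron
#' area). Containment is verified exactly through an integral image: the
#' count of mask-true pixels under each footprint equals `size^2`.
#'
#' @param image H x W x 3 numeric array.
#' @param mask A [detect_elytra_border()] result (or the generator's truth
#'   mask wrapped by `as_foreground_mask()`).
#' @param n Number of tiles (>= 0); the default study setting uses 100.
#' @param size Tile side in pixels (default 448).
#' @param seed Integer seed; sampling is deterministic given the seed.
#' @param source_image_id,species_id Optional provenance labels stamped on
#'   every tile.
#' @return A list of `"tile"` objects, each with `pixels` (size x size x
#'   channels), `origin` (`c(row, col)`, 1-based top-left),
#'   `source_image_id` and `species_id`.
#' @export
sample_tiles <- function(image, mask, n = 100, size = 448, seed = 1L,
                         source_image_id = NA_character_,
                         species_id = NA_character_) {
  stopifnot(inherits(mask, "foreground_mask"))
  n <- assert_scalar_count(n, "n", min = 0L)
  size <- assert_scalar_count(size, "size", min = 1L)
  if (n == 0L) return(list())
  pos <- tile_positions(mask$mask, size)
  if (nrow(pos) == 0) {
    abort(sprintf("no %d x %d tile fits inside the foreground.", size, size),
          class = "elytra_insufficient_foreground")
  }
  idx <- with_seed(seed, sample.int(nrow(pos), n, replace = TRUE))
  lapply(idx, function(i) {
    r <- unname(pos[i, 1]); c <- unname(pos[i, 2])
    structure(
      list(pixels = image[r:(r + size - 1), c:(c + size - 1), , drop = FALSE],
           origin = c(row = r, col = c),
           source_image_id = source_image_id,
           species_id = species_id),
      class = "tile"
    )
  })
}

#' Wrap a known-good logical mask as a foreground mask
#'
#' Mainly for using the synthetic generator's ground-truth masks directly
#' in place of detected ones.
#'
#' @param mask H x W logical matrix with at least one `TRUE` pixel.
#' @return A `"foreground_mask"` object.
#' @export
as_foreground_mask <- function(mask) {
  new_foreground_mask(mask)
}

#' Intersection-over-union of two masks
#'
#' @param a,b Logical matrices of identical dimensions, or
#'   `"foreground_mask"` objects.
#' @return IoU in `[0, 1]`.
#' @export
mask_iou <- function(a, b) {
  if (inherits(a, "foreground_mask")) a <- a$mask
  if (inherits(b, "foreground_mask")) b <- b$mask
  stopifnot(identical(dim(a), dim(b)))
  sum(a & b) / sum(a | b)
}
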