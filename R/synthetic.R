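#' Draw a set of synthetic species texture specifications
#'
#' Each beetle species carries a characteristic pattern on its elytra
#' (longitudinal striae, punctures/spots, overall pigmentation). This
#' generator draws one parameter set per synthetic species, spread out in
#' parameter space so that the rendered textures are mutually distinct and
#' learnable: base gray levels and stria orientations are sampled on
#' jittered evenly-spaced grids, periods and spot statistics uniformly.
#'
#' @param seed Integer seed; the same seed reproduces identical specs.
#' @param n_species Number of species specifications to draw (>= 1).
#' @param separation In `[0, 1]`, scales how far apart base intensities and
#'   stria orientations are placed. 1 (default) spreads species across the
#'   full usable range; 0 collapses all species onto one texture family
#'   (useful for chance-level controls).
#' @return A tibble with one row per species and columns `species_id`,
#'   `base_intensity` (gray level of the elytron in `(0, 0.9)`),
#'   `ridge_period` (stria period, px), `ridge_orientation` (degrees),
#'   `spot_density` (spots per 1e4 px^2), `spot_radius` (px) and
#'   `texture_seed`.
#' @examples
#' specs <- make_species_spec(seed = 7, n_species = 3)
#' specs$species_id
#' @export
make_species_spec <- function(seed, n_species, separation = 1) {
  n_species <- assert_scalar_count(n_species, "n_species", min = 1L)
  assert_fraction(separation, "separation")
  with_seed(seed, {
    mid_b <- 0.45
    base_slots <- mid_b + (seq(0.18, 0.72, length.out = n_species) - mid_b) * separation
    mid_o <- 90
    orient_slots <- mid_o + (seq(0, 180, length.out = n_species + 1)[seq_len(n_species)] - mid_o) * separation
    perm <- sample.int(n_species)
    tibble(
      species_id = sprintf("SYN%02d", seq_len(n_species)),
      base_intensity = clip01(base_slots[perm] + rnorm(n_species, 0, 0.01 * separation)),
      ridge_period = runif(n_species, 6, 18),
      ridge_orientation = (orient_slots[sample.int(n_species)] +
                             rnorm(n_species, 0, 2 * separation)) %% 180,
      spot_density = runif(n_species, 0.5, 4),
      spot_radius = runif(n_species, 3, 8),
      texture_seed = sample.int(1000000L, n_species)
    )
  })
}

#' Intraspecies variation profile
#'
#' Bundles the three modes of within-species image variation the generator
#' can emulate, each scaled in `[0, 1]`:
#' `maturity_darkening` (global darkening with amplified pattern contrast,
#' as older beetles develop darker, more prominent elytra), `variegation`
#' (a smooth spatial field modulating pattern contrast across the elytron,
#' so some regions appear faint and others prominent) and
#' `background_fiber` (opacity of a fibrous filter-paper texture bleeding
#' into the background, an artifact of imaging thin elytra on filter
#' paper). The zero profile leaves the base texture unchanged.
#'
#' @param maturity_darkening,variegation,background_fiber Numbers in `[0, 1]`.
#' @return A list of class `"variation_profile"`.
#' @export
variation_profile <- function(maturity_darkening = 0, variegation = 0,
                              background_fiber = 0) {
  structure(
    list(
      maturity_darkening = assert_fraction(maturity_darkening, "maturity_darkening"),
      variegation = assert_fraction(variegation, "variegation"),
      background_fiber = assert_fraction(background_fiber, "background_fiber")
    ),
    class = "variation_profile"
  )
}

# Smooth low-frequency random field in [0,1]: bilinear interpolation of a
# coarse uniform grid with smoothstep easing (Perlin-style value noise).
smooth_field <- function(H, W, cells = 6) {
  g <- matrix(runif((cells + 1)^2), cells + 1, cells + 1)
  ry <- seq(1, cells + 1, length.out = H)
  rx <- seq(1, cells + 1, length.out = W)
  y0 <- pmin(floor(ry), cells); x0 <- pmin(floor(rx), cells)
  fy <- ry - y0; fx <- rx - x0
  fy <- fy * fy * (3 - 2 * fy); fx <- fx * fx * (3 - 2 * fx)
  outer(1 - fy, 1 - fx) * g[y0, x0] +
    outer(1 - fy, fx) * g[y0, x0 + 1] +
    outer(fy, 1 - fx) * g[y0 + 1, x0] +
    outer(fy, fx) * g[y0 + 1, x0 + 1]
}

#' Render one synthetic elytron image
#'
#' Draws an elongated convex elytron (a superellipse footprint with mild
#' random boundary perturbation) centered on a near-white background, fills
#' it with a species texture (sinusoidal striae + scattered darker discs +
#' low-amplitude smooth noise), applies the variation profile, and returns
#' the pixels together with the ground-truth foreground mask.
#'
#' The stria phase is derived from the species' `texture_seed` only, so all
#' individuals of a species share pattern alignment statistics, while spot
#' placement, boundary shape and noise are per-image. The whole render is a
#' pure function of `(spec, profile, image_size, seed)`.
#'
#' @param spec One row of [make_species_spec()] output (or a list with the
#'   same fields).
#' @param profile A [variation_profile()].
#' @param image_size `c(H, W)` in pixels; the default mirrors the
#'   acquisition resolution of the microscope camera (1944 x 2592).
#' @param seed Integer seed for the per-image randomness.
#' @return A list of class `"synthetic_image"` with `pixels` (H x W x 3 in
#'   `[0, 1]`), `truth_mask` (H x W logical), `species_id`, `image_id`.
#' @export
render_elytra_image <- function(spec, profile = variation_profile(),
                                image_size = c(1944, 2592), seed = 1L) {
  if (is.data.frame(spec)) {
    stopifnot(nrow(spec) == 1)
    spec <- as.list(spec)
  }
  stopifnot(inherits(profile, "variation_profile"))
  H <- assert_scalar_count(image_size[1], "image_size[1]")
  W <- assert_scalar_count(image_size[2], "image_size[2]")
  if (H < 32 || W < 32) {
    abort("image_size too small to contain an elytron footprint.",
          class = "elytra_invalid_argument")
  }

  # species-level randomness: stria phase offset
  phase <- with_seed(child_seed(spec$texture_seed, 0L), runif(1, 0, 2 * pi))

  with_seed(child_seed(seed, spec$texture_seed), {
    cy <- (H + 1) / 2; cx <- (W + 1) / 2
    ax <- 0.42 * W; ay <- 0.36 * H; p <- 2.5
    yy <- matrix(seq_len(H), H, W)
    xx <- matrix(seq_len(W), H, W, byrow = TRUE)
    u <- (xx - cx) / ax; v <- (yy - cy) / ay
    r <- (abs(u)^p + abs(v)^p)^(1 / p)
    th <- atan2(v, u)
    a1 <- runif(1, 0, 0.02); a2 <- runif(1, 0, 0.02)
    ph1 <- runif(1, 0, 2 * pi); ph2 <- runif(1, 0, 2 * pi)
    rho <- 1 + a1 * cos(th + ph1) + a2 * cos(2 * th + ph2)
    mask <- r <= rho

    # striae: sinusoid perpendicular to the ridge orientation
    ang <- spec$ridge_orientation * pi / 180
    coord <- xx * cos(ang) + yy * sin(ang)
    stria <- 0.12 * sin(2 * pi * coord / spec$ridge_period + phase)

    # spots: darker soft discs scattered over the footprint
    spot <- matrix(0, H, W)
    area <- sum(mask)
    n_spots <- stats::rpois(1, spec$spot_density * area / 1e4)
    if (n_spots > 0) {
      rr <- spec$spot_radius
      sy <- runif(n_spots, 1, H); sx <- runif(n_spots, 1, W)
      keep <- mask[cbind(pmax(1, pmin(H, round(sy))), pmax(1, pmin(W, round(sx))))]
      sy <- sy[keep]; sx <- sx[keep]
      half <- ceiling(2 * rr)
      for (k in seq_along(sy)) {
        ys <- max(1, floor(sy[k]) - half):min(H, floor(sy[k]) + half)
        xs <- max(1, floor(sx[k]) - half):min(W, floor(sx[k]) + half)
        d2 <- outer((ys - sy[k])^2, (xs - sx[k])^2, "+")
        spot[ys, xs] <- pmin(spot[ys, xs] + 0.15 * pmax(0, 1 - d2 / rr^2), 0.25)
      }
    }

    noise <- 0.05 * (2 * smooth_field(H, W, cells = 12) - 1)

    pattern <- stria - spot + noise
    if (profile$variegation > 0) {
      vf <- 1 + profile$variegation * (2 * smooth_field(H, W, cells = 4) - 1)
      pattern <- pattern * vf
    }
    m <- profile$maturity_darkening
    tex <- spec$base_intensity * (1 - 0.45 * m) + pattern * (1 + 0.6 * m)
    tex <- pmin(pmax(tex, 0.02), 0.9)

    # near-white background, optionally with fibrous paper texture
    bg <- matrix(0.97, H, W) + 0.006 * (2 * smooth_field(H, W, cells = 16) - 1)
    if (profile$background_fiber > 0) {
      fib <- fiber_field(H, W)
      bg <- bg - profile$background_fiber * fib
    }
    bg <- pmin(pmax(bg, 0.9), 1)

    tint <- c(1, 0.88, 0.72)
    pixels <- array(0, c(H, W, 3))
    for (ch in 1:3) {
      plane <- bg
      plane[mask] <- (tex * tint[ch])[mask]
      pixels[, , ch] <- plane
    }
    structure(
      list(pixels = pixels, truth_mask = mask,
           species_id = spec$species_id,
           image_id = sprintf("%s_i%06d", spec$species_id, as.integer(seed) %% 1000000L)),
      class = "synthetic_image"
    )
  })
}

# Fibrous filter-paper texture: oriented random line segments rasterized
# into a dip field; values are the depth subtracted from the background at
# full opacity.
fiber_field <- function(H, W) {
  f <- matrix(0, H, W)
  n_seg <- max(8L, round(H * W / 6000))
  base_ang <- runif(1, 0, pi)
  for (k in seq_len(n_seg)) {
    ang <- base_ang + rnorm(1, 0, 0.5)
    len <- runif(1, 0.1, 0.3) * min(H, W)
    y0 <- runif(1, 1, H); x0 <- runif(1, 1, W)
    t <- seq(0, len, by = 0.7)
    ys <- round(y0 + t * sin(ang)); xs <- round(x0 + t * cos(ang))
    ok <- ys >= 1 & ys <= H & xs >= 1 & xs <= W
    idx <- cbind(ys[ok], xs[ok])
    f[idx] <- pmax(f[idx], runif(1, 0.08, 0.2))
  }
  f
}

#' Generate a labeled synthetic dataset on disk
#'
#' Renders `images_per_species` images for every species spec, writing one
#' folder per species containing 8-bit RGB PNGs plus single-channel
#' ground-truth mask PNGs, and a manifest (CSV and JSON twin) listing every
#' image. The layout mirrors the class-labeled directory convention used
#' for training (labels inherited from folder names).
#'
#' @param specs Tibble from [make_species_spec()].
#' @param images_per_species Number of images per species (>= 1).
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed; the same seed reproduces byte-identical files.
#' @param profile_sampler Either `NULL` (no variation), a single
#'   [variation_profile()] applied to every image, or a function
#'   `(species_index, image_index) -> variation_profile` for per-image
#'   variation.
#' @param image_size `c(H, W)` of every rendered image.
#' @return A tibble manifest with columns `image_id`, `species_id`, `path`,
#'   `mask_path`.
#' @export
generate_dataset <- function(specs, images_per_species, out_dir, seed = 1L,
                             profile_sampler = NULL,
                             image_size = c(1944, 2592)) {
  images_per_species <- assert_scalar_count(images_per_species, "images_per_species")
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create output directory '%s'", out_dir),
                   class = "elytra_io_error")
  }
  get_profile <- if (is.null(profile_sampler)) {
    function(s, i) variation_profile()
  } else if (inherits(profile_sampler, "variation_profile")) {
    function(s, i) profile_sampler
  } else {
    stopifnot(is.function(profile_sampler))
    profile_sampler
  }

  rows <- vector("list", nrow(specs) * images_per_species)
  k <- 0L
  for (s in seq_len(nrow(specs))) {
    sp <- specs[s, ]
    sp_dir <- file.path(out_dir, sp$species_id)
    dir.create(sp_dir, showWarnings = FALSE)
    for (i in seq_len(images_per_species)) {
      img <- render_elytra_image(sp, get_profile(s, i), image_size,
                                 seed = child_seed(seed, s * 10000L + i))
      path <- file.path(sp_dir, paste0(img$image_id, ".png"))
      mask_path <- file.path(sp_dir, paste0(img$image_id, "_mask.png"))
      png::writePNG(img$pixels, path)
      png::writePNG(img$truth_mask * 1, mask_path)
      k <- k + 1L
      rows[[k]] <- tibble(image_id = img$image_id, species_id = sp$species_id,
                          path = path, mask_path = mask_path)
    }
  }
  manifest <- dplyr::bind_rows(rows)
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", pretty = TRUE)
  manifest
}
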