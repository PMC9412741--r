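#' Build a dataset manifest from a class-labeled directory tree
#'
#' Scans `root_dir`, which must contain one subdirectory per species, and
#' lists every image file. Class labels are inherited from folder names;
#' the species list is the lexicographic order of those names. Ground-truth
#' mask companions (`*_mask.png`) written by [generate_dataset()] are
#' paired, not listed as images; files that are not readable raster images
#' are skipped with a warning.
#'
#' @param root_dir Directory with one subfolder per species.
#' @return A tibble with columns `image_id`, `species_id`, `path` (and
#'   `mask_path`, `NA` when absent), carrying the sorted species vector in
#'   attribute `"species_list"`.
#' @export
build_manifest <- function(root_dir) {
  if (!dir.exists(root_dir)) {
    abort(sprintf("'%s' is not a directory.", root_dir), class = "elytra_malformed_dataset")
  }
  sp_dirs <- list.dirs(root_dir, recursive = FALSE)
  if (length(sp_dirs) == 0) {
    abort("root directory contains no species folders.", class = "elytra_malformed_dataset")
  }
  sp_dirs <- sp_dirs[order(basename(sp_dirs))]
  rows <- lapply(sp_dirs, function(d) {
    files <- list.files(d, full.names = TRUE)
    files <- files[!dir.exists(files)]
    is_mask <- grepl("_mask\\.[^.]+$", files)
    is_img <- grepl("\\.(png|tif|tiff)$", files, ignore.case = TRUE) & !is_mask
    skipped <- files[!is_img & !is_mask]
    if (length(skipped) > 0) {
      warn(sprintf("skipping %d non-image file(s) in '%s': %s",
                   length(skipped), basename(d),
                   paste(basename(skipped), collapse = ", ")))
    }
    imgs <- files[is_img]
    if (length(imgs) == 0) {
      abort(sprintf("species folder '%s' contains no images.", basename(d)),
            class = "elytra_malformed_dataset")
    }
    ids <- sub("\\.[^.]+$", "", basename(imgs))
    masks <- file.path(d, paste0(ids, "_mask.png"))
    tibble(image_id = ids, species_id = basename(d), path = imgs,
           mask_path = ifelse(file.exists(masks), masks, NA_character_))
  })
  manifest <- dplyr::bind_rows(rows)
  if (anyDuplicated(manifest$image_id)) {
    manifest$image_id <- paste(manifest$species_id, manifest$image_id, sep = "/")
  }
  attr(manifest, "species_list") <- sort(unique(manifest$species_id))
  manifest
}

#' Species labels of a manifest
#' @param manifest A manifest tibble.
#' @return Sorted character vector of species ids.
#' @export
species_levels <- function(manifest) {
  sl <- attr(manifest, "species_list")
  if (is.null(sl)) sort(unique(manifest$species_id)) else sl
}

#' Blind image-level train/test split
#'
#' Partitions whole images — never tiles — into train and test sets,
#' independently within each species, so that all tiles later cut from one
#' image land in exactly one partition (preventing information leak between
#' train and test). Per species, the test set holds
#' `round(test_fraction * n)` images, clamped to `[1, n - 1]` so both
#' partitions are non-empty; the default fraction 0.2 realizes the 4:1
#' train:test ratio (16/4 from 20 images).
#'
#' @param manifest A [build_manifest()] tibble (or any tibble with
#'   `image_id` and `species_id`).
#' @param test_fraction Fraction of each species' images assigned to test,
#'   in `(0, 1)`.
#' @param seed Integer seed; identical seeds give identical assignments.
#' @return A tibble `(image_id, species_id, partition)` with `partition`
#'   in `{"train", "test"}`, plus attributes `test_fraction` and `seed`.
#' @export
blind_split <- function(manifest, test_fraction = 0.2, seed = 1L) {
  assert_fraction(test_fraction, "test_fraction", open = TRUE)
  counts <- table(manifest$species_id)
  if (any(counts < 2)) {
    abort(sprintf("every species needs >= 2 images; offending: %s",
                  paste(names(counts)[counts < 2], collapse = ", ")),
          class = "elytra_invalid_dataset")
  }
  out <- with_seed(seed, {
    parts <- lapply(sort(unique(manifest$species_id)), function(sp) {
      rows <- manifest[manifest$species_id == sp, c("image_id", "species_id")]
      n <- nrow(rows)
      n_test <- min(max(round(test_fraction * n), 1L), n - 1L)
      test_idx <- sample.int(n, n_test)
      rows$partition <- "train"
      rows$partition[test_idx] <- "test"
      rows
    })
    dplyr::bind_rows(parts)
  })
  attr(out, "test_fraction") <- test_fraction
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Tile-count arithmetic without touching pixels
#'
#' Computes how many tiles each partition would contain for a given split
#' and tiles-per-image setting — the fast "count-only" mode used to check
#' the split/tiling arithmetic (e.g. 27 species x 20 images, fraction 0.2,
#' 100 tiles/image gives 10,800 test tiles).
#'
#' @param split A [blind_split()] tibble.
#' @param tiles_per_image Tiles sampled per image.
#' @return A tibble `(species_id, partition, n_images, n_tiles)`.
#' @export
count_split_tiles <- function(split, tiles_per_image = 100) {
  tiles_per_image <- assert_scalar_count(tiles_per_image, "tiles_per_image", min = 0L)
  split |>
    dplyr::count(.data$species_id, .data$partition, name = "n_images") |>
    dplyr::mutate(n_tiles = .data$n_images * tiles_per_image)
}

read_image <- function(path) {
  if (grepl("\\.(tif|tiff)$", path, ignore.case = TRUE)) {
    EBImage::imageData(EBImage::readImage(path))
  } else {
    px <- png::readPNG(path)
    if (length(dim(px)) == 3 && dim(px)[3] == 4) px <- px[, , 1:3]
    px
  }
}

ensure_rgb <- function(px) {
  if (length(dim(px)) == 2) px <- array(rep(px, 3), c(dim(px), 3))
  px
}

#' Cut and export train/test tiles for a whole dataset
#'
#' For every manifest image: detects the elytral border, samples
#' `tiles_per_image` tiles fully inside it, and writes them as PNGs under
#' `out_dir/train/<species>/` or `out_dir/test/<species>/` according to the
#' image's split partition — so every tile inherits its source image's
#' partition and the export is leak-free by construction. Images whose
#' border detection fails are recorded in an exclusion report and the run
#' continues.
#'
#' @param manifest A [build_manifest()] tibble.
#' @param split A [blind_split()] tibble for the same manifest.
#' @param out_dir Output directory.
#' @param tiles_per_image,tile_size Tile sampling parameters.
#' @param seed Integer seed (one deterministic child seed per image).
#' @param use_truth_mask If `TRUE`, use the manifest's ground-truth mask
#'   files instead of running border detection (synthetic data only).
#' @return A list of class `"tile_export"`: `summary` (per
#'   species/partition tile counts), `index` (one row per tile:
#'   `tile_id, image_id, species_id, partition, row, col, path`),
#'   `exclusions` (tibble of failed images with reasons).
#' @export
export_split_tiles <- function(manifest, split, out_dir, tiles_per_image = 100,
                               tile_size = 448, seed = 1L,
                               use_truth_mask = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  joined <- dplyr::inner_join(manifest, split[, c("image_id", "partition")],
                              by = "image_id")
  stopifnot(nrow(joined) == nrow(manifest))
  idx_rows <- list(); excl_rows <- list()
  for (i in seq_len(nrow(joined))) {
    rec <- joined[i, ]
    res <- tryCatch({
      px <- ensure_rgb(read_image(rec$path))
      fm <- if (use_truth_mask && !is.na(rec$mask_path)) {
        as_foreground_mask(to_gray(read_image(rec$mask_path)) > 0.5)
      } else {
        detect_elytra_border(px)
      }
      tiles <- sample_tiles(px, fm, n = tiles_per_image, size = tile_size,
                            seed = child_seed(seed, i),
                            source_image_id = rec$image_id,
                            species_id = rec$species_id)
      dest <- file.path(out_dir, rec$partition, rec$species_id)
      dir.create(dest, recursive = TRUE, showWarnings = FALSE)
      rows <- vector("list", length(tiles))
      for (k in seq_along(tiles)) {
        tile_id <- sprintf("%s_t%03d", gsub("/", "_", rec$image_id), k)
        p <- file.path(dest, paste0(tile_id, ".png"))
        png::writePNG(tiles[[k]]$pixels, p)
        rows[[k]] <- tibble(tile_id = tile_id, image_id = rec$image_id,
                            species_id = rec$species_id,
                            partition = rec$partition,
                            row = tiles[[k]]$origin[["row"]],
                            col = tiles[[k]]$origin[["col"]], path = p)
      }
      dplyr::bind_rows(rows)
    }, error = function(e) {
      tibble(image_id = rec$image_id, species_id = rec$species_id,
             reason = conditionMessage(e))
    })
    if ("reason" %in% names(res)) excl_rows[[length(excl_rows) + 1]] <- res
    else idx_rows[[length(idx_rows) + 1]] <- res
  }
  index <- dplyr::bind_rows(idx_rows)
  exclusions <- dplyr::bind_rows(excl_rows)
  summary <- if (nrow(index)) {
    dplyr::count(index, .data$species_id, .data$partition, name = "n_tiles")
  } else {
    tibble(species_id = character(), partition = character(), n_tiles = integer())
  }
  readr::write_csv(index, file.path(out_dir, "tile_index.csv"))
  if (nrow(exclusions)) readr::write_csv(exclusions, file.path(out_dir, "exclusions.csv"))
  structure(list(summary = summary, index = index, exclusions = exclusions,
                 out_dir = out_dir),
            class = "tile_export")
}

#' Check an exported tile set for train/test leakage
#'
#' @param export A [export_split_tiles()] result (or a tile index tibble
#'   with `image_id` and `partition`).
#' @return `TRUE` invisibly if the source-image sets of train and test
#'   tiles are disjoint; aborts otherwise.
#' @export
assert_leak_free <- function(export) {
  index <- if (inherits(export, "tile_export")) export$index else export
  tr <- unique(index$image_id[index$partition == "train"])
  te <- unique(index$image_id[index$partition == "test"])
  shared <- intersect(tr, te)
  if (length(shared) > 0) {
    abort(sprintf("information leak: %d image(s) contribute tiles to both partitions.",
                  length(shared)), class = "elytra_leak_error")
  }
  invisible(TRUE)
}

#' Harvest tiles from in-memory synthetic images
#'
#' Convenience path for fully in-memory experiments: samples tiles from a
#' list of [render_elytra_image()] results (using their ground-truth masks
#' or detected borders) and stacks them into one array.
#'
#' @param images List of `"synthetic_image"` objects.
#' @param tiles_per_image,tile_size Sampling parameters.
#' @param seed Integer seed.
#' @param detect If `TRUE`, run [detect_elytra_border()] instead of using
#'   the truth masks.
#' @return List with `x` (size x size x 3 x N array), `species`
#'   (character, length N), `image_id` (character, length N).
#' @export
harvest_tiles <- function(images, tiles_per_image, tile_size, seed = 1L,
                          detect = FALSE) {
  all_tiles <- list()
  for (i in seq_along(images)) {
    im <- images[[i]]
    fm <- if (detect) detect_elytra_border(im$pixels) else as_foreground_mask(im$truth_mask)
    all_tiles <- c(all_tiles, sample_tiles(im$pixels, fm, n = tiles_per_image,
                                           size = tile_size,
                                           seed = child_seed(seed, i),
                                           source_image_id = im$image_id,
                                           species_id = im$species_id))
  }
  tile_array(all_tiles)
}

#' Stack a list of tiles into a single array
#'
#' @param tiles List of `"tile"` objects of identical size.
#' @return List with `x` (S x S x C x N), `species`, `image_id`.
#' @export
tile_array <- function(tiles) {
  stopifnot(length(tiles) > 0)
  d <- dim(tiles[[1]]$pixels)
  x <- array(0, c(d[1], d[2], d[3], length(tiles)))
  for (k in seq_along(tiles)) x[, , , k] <- tiles[[k]]$pixels
  list(x = x,
       species = vapply(tiles, function(t) t$species_id, character(1)),
       image_id = vapply(tiles, function(t) t$source_image_id, character(1)))
}
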