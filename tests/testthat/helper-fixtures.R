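# Shared fixtures and independent oracles, built in code at test time.

# Render a small in-memory image set: `images_per_species` images for each
# of `n_species` species. Returns list(images, manifest).
render_image_set <- function(n_species, images_per_species, seed,
                             image_size = c(160, 224), separation = 1,
                             profile_fun = NULL) {
  specs <- make_species_spec(seed, n_species, separation = separation)
  images <- list()
  for (s in seq_len(n_species)) {
    for (i in seq_len(images_per_species)) {
      prof <- if (is.null(profile_fun)) variation_profile() else profile_fun(s, i)
      images[[length(images) + 1]] <- render_elytra_image(
        specs[s, ], prof, image_size,
        seed = 100000 * s + i + seed)
    }
  }
  manifest <- tibble::tibble(
    image_id = vapply(images, function(x) x$image_id, character(1)),
    species_id = vapply(images, function(x) x$species_id, character(1)))
  list(specs = specs, images = images, manifest = manifest)
}

# Split an in-memory image set and harvest train/test tile arrays.
split_and_harvest <- function(set, test_fraction, tiles_per_image, tile_size,
                              split_seed, tile_seed, detect = FALSE) {
  split <- blind_split(set$manifest, test_fraction, seed = split_seed)
  tr_ids <- split$image_id[split$partition == "train"]
  in_train <- set$manifest$image_id %in% tr_ids
  list(
    split = split,
    train = harvest_tiles(set$images[in_train], tiles_per_image, tile_size,
                          seed = tile_seed, detect = detect),
    test = harvest_tiles(set$images[!in_train], tiles_per_image, tile_size,
                         seed = tile_seed + 1, detect = detect)
  )
}

# Brute-force one-vs-rest metrics from raw label/prediction lists, counting
# each pair directly with integer arithmetic. Independent of the package's
# confusion-matrix path.
brute_force_metrics <- function(truth, pred, classes) {
  do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    tn <- sum(truth != cl & pred != cl)
    den <- function(x) if (x == 0) 0 else x
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    spec <- if (tn + fp == 0) 0 else tn / (tn + fp)
    mden <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
    mcc <- if (mden == 0) 0 else (as.numeric(tp) * tn - as.numeric(fp) * fn) / mden
    data.frame(class = cl, TP = tp, FP = fp, TN = tn, FN = fn,
               precision = prec, recall = rec, specificity = spec, mcc = mcc,
               stringsAsFactors = FALSE)
  }))
}

# Block-wise contrast spread: standard deviation across blocks of the
# per-block pixel standard deviation, restricted to blocks fully inside the
# mask. Oracle for the variegation mode.
blockwise_contrast_sd <- function(img, block = 16) {
  g <- (img$pixels[, , 1] + img$pixels[, , 2] + img$pixels[, , 3]) / 3
  H <- nrow(g); W <- ncol(g)
  sds <- c()
  for (r in seq(1, H - block + 1, by = block)) {
    for (cl in seq(1, W - block + 1, by = block)) {
      sub_m <- img$truth_mask[r:(r + block - 1), cl:(cl + block - 1)]
      if (all(sub_m)) {
        sds <- c(sds, stats::sd(g[r:(r + block - 1), cl:(cl + block - 1)]))
      }
    }
  }
  stats::sd(sds)
}
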