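#' @importFrom rlang %||% .data
NULL

log_line <- function(path, stage, ...) {
  entry <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage = stage),
             list(...))
  line <- jsonlite::toJSON(entry, auto_unbox = TRUE)
  if (!is.null(path)) cat(line, "\n", file = path, append = TRUE, sep = "")
  invisible(entry)
}

# Read a run configuration from a YAML file or pass a list through.
read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  config
}

tiles_from_index <- function(index, partition) {
  rows <- index[index$partition == partition, , drop = FALSE]
  stopifnot(nrow(rows) > 0)
  first <- ensure_rgb(read_image(rows$path[1]))
  x <- array(0, c(dim(first), nrow(rows)))
  x[, , , 1] <- first
  if (nrow(rows) > 1) {
    for (k in 2:nrow(rows)) x[, , , k] <- ensure_rgb(read_image(rows$path[k]))
  }
  list(x = x, species = rows$species_id, image_id = rows$image_id)
}

synthetic_profile_sampler <- function(syn) {
  spread <- syn$maturity_spread %||% 0
  npm <- syn$images_per_species
  function(s, i) {
    m <- if (npm > 1) spread * (i - 1) / (npm - 1) else 0
    variation_profile(maturity_darkening = m,
                      variegation = syn$variegation %||% 0,
                      background_fiber = syn$background_fiber %||% 0)
  }
}

#' Run the full experiment from one configuration
#'
#' Orchestrates the pipeline end to end: optional synthetic-data
#' generation, manifest construction, blind image-level split, border
#' detection + tile export, training with augmentation, and evaluation.
#' Every stage's artifacts are persisted under `output_dir` and the stages
#' are logged as line-delimited JSON. Re-running with an identical
#' configuration reproduces counts exactly and metrics to floating-point
#' tolerance.
#'
#' The configuration is a nested list (or path to a YAML file) with
#' blocks:
#' \describe{
#'   \item{input_root / synthetic}{either a class-labeled image directory,
#'     or a `synthetic` block (`n_species`, `images_per_species`,
#'     `image_size`, `seed`, optional `separation`, `maturity_spread`,
#'     `variegation`, `background_fiber`).}
#'   \item{tile_params}{`n` tiles per image and tile `size` (px).}
#'   \item{split}{`test_fraction` (default 0.2), `seed`, optional
#'     `repeats` for repeated independent splits.}
#'   \item{augmentation}{[augmentation_config()] fields, or `enabled:
#'     false`.}
#'   \item{model}{`conv_filters`, `dropout_rate`.}
#'   \item{train}{`epochs`, `batch_size`, `learning_rate`, `seed`.}
#'   \item{output_dir}{where artifacts land; must differ from the input
#'     root.}
#'   \item{count_only}{if `TRUE`, stop after computing the exact
#'     split/tile count arithmetic — no pixels are touched.}
#'   \item{use_truth_mask}{use generator ground-truth masks instead of
#'     border detection (synthetic data only).}
#' }
#'
#' @param config A list or YAML file path.
#' @return A list of class `"elytra_run_report"`; on stage failure the
#'   report is partial, with `success = FALSE` and the failing stage and
#'   message recorded.
#' @export
run_experiment <- function(config) {
  config <- read_run_config(config)
  out_dir <- config$output_dir
  stopifnot(!is.null(out_dir))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run_log.jsonl")
  report <- list(config = config, success = FALSE, stage = NULL,
                 package_version = as.character(utils::packageVersion("elytra")))
  class(report) <- "elytra_run_report"

  fail <- function(stage, err) {
    report$stage <<- stage
    report$error <<- conditionMessage(err)
    log_line(log_path, stage, status = "failed", error = conditionMessage(err))
    report
  }

  # --- input images -------------------------------------------------------
  stage <- "input"
  res <- tryCatch({
    if (!is.null(config$synthetic) && isTRUE(config$count_only)) {
      # split/tiling arithmetic only: no pixel is rendered
      syn <- config$synthetic
      grid <- expand.grid(i = seq_len(syn$images_per_species),
                          s = seq_len(syn$n_species))
      virtual_manifest <- tibble(
        image_id = sprintf("SYN%02d_i%03d", grid$s, grid$i),
        species_id = sprintf("SYN%02d", grid$s),
        path = NA_character_)
      attr(virtual_manifest, "species_list") <- sort(unique(virtual_manifest$species_id))
      virtual_manifest
    } else if (!is.null(config$synthetic)) {
      syn <- config$synthetic
      img_dir <- file.path(out_dir, "images")
      specs <- make_species_spec(seed = syn$seed %||% 1L,
                                 n_species = syn$n_species,
                                 separation = syn$separation %||% 1)
      generate_dataset(specs, syn$images_per_species, img_dir,
                       seed = syn$seed %||% 1L,
                       profile_sampler = synthetic_profile_sampler(syn),
                       image_size = syn$image_size %||% c(1944, 2592))
      img_dir
    } else {
      stopifnot(!is.null(config$input_root))
      config$input_root
    }
  }, error = function(e) e)
  if (inherits(res, "error")) return(fail(stage, res))
  input_root <- res
  if (is.character(input_root) && is.null(config$synthetic) &&
      normalizePath(input_root, mustWork = FALSE) ==
      normalizePath(out_dir, mustWork = FALSE)) {
    return(fail(stage, simpleError("output_dir must differ from the input root.")))
  }
  log_line(log_path, stage, status = "ok",
           input_root = if (is.character(input_root)) input_root else "<virtual>")

  # --- manifest + split ---------------------------------------------------
  stage <- "split"
  res <- tryCatch({
    manifest <- if (is.data.frame(input_root)) input_root else build_manifest(input_root)
    split_seed <- config$split$seed %||% 1L
    frac <- config$split$test_fraction %||% 0.2
    split <- blind_split(manifest, frac, seed = split_seed)
    readr::write_csv(
      dplyr::mutate(split, seed = split_seed),
      file.path(out_dir, "split_assignment.csv"))
    list(manifest = manifest, split = split)
  }, error = function(e) e)
  if (inherits(res, "error")) return(fail(stage, res))
  manifest <- res$manifest; split <- res$split
  n_tiles <- config$tile_params$n %||% 100
  counts <- count_split_tiles(split, n_tiles)
  readr::write_csv(counts, file.path(out_dir, "tile_counts.csv"))
  report$tile_counts <- counts
  log_line(log_path, stage, status = "ok",
           n_images = nrow(manifest),
           n_species = length(species_levels(manifest)))

  if (isTRUE(config$count_only)) {
    report$success <- TRUE
    report$stage <- "count_only"
    log_line(log_path, "count_only", status = "ok",
             train_tiles = sum(counts$n_tiles[counts$partition == "train"]),
             test_tiles = sum(counts$n_tiles[counts$partition == "test"]))
    return(report)
  }

  # --- tiles --------------------------------------------------------------
  stage <- "tiles"
  res <- tryCatch({
    export <- export_split_tiles(
      manifest, split, file.path(out_dir, "tiles"),
      tiles_per_image = n_tiles,
      tile_size = config$tile_params$size %||% 448,
      seed = config$tile_params$seed %||% 1L,
      use_truth_mask = isTRUE(config$use_truth_mask))
    assert_leak_free(export)
    export
  }, error = function(e) e)
  if (inherits(res, "error")) return(fail(stage, res))
  export <- res
  report$exclusions <- export$exclusions
  report$tile_summary <- export$summary
  log_line(log_path, stage, status = "ok", n_tiles = nrow(export$index),
           n_excluded = nrow(export$exclusions))

  # --- train --------------------------------------------------------------
  stage <- "train"
  res <- tryCatch({
    tr <- tiles_from_index(export$index, "train")
    te <- tiles_from_index(export$index, "test")
    size <- dim(tr$x)[1]
    mcfg <- model_config(
      input_size = size,
      n_classes = length(species_levels(manifest)),
      conv_filters = config$model$conv_filters %||% c(32, 64, 128, 256),
      dropout_rate = config$model$dropout_rate %||% 0.5)
    aug <- if (isFALSE(config$augmentation$enabled)) NULL else {
      ab <- config$augmentation %||% list()
      ab$enabled <- NULL
      do.call(augmentation_config, ab)
    }
    tcfg <- train_config(
      epochs = config$train$epochs %||% 100,
      batch_size = config$train$batch_size %||% 32,
      learning_rate = config$train$learning_rate %||% 1e-3,
      seed = config$train$seed %||% 1L)
    model <- build_model(mcfg, seed = config$train$seed %||% 1L)
    model <- train_model(model, tr, te, aug = aug, tc = tcfg)
    readr::write_csv(model$history, file.path(out_dir, "history.csv"))
    list(model = model, tr = tr, te = te)
  }, error = function(e) e)
  if (inherits(res, "error")) return(fail(stage, res))
  model <- res$model; te <- res$te
  report$history_path <- file.path(out_dir, "history.csv")
  report$audit <- model$audit
  log_line(log_path, stage, status = "ok", epochs = nrow(model$history))

  # --- evaluate -----------------------------------------------------------
  stage <- "evaluate"
  res <- tryCatch({
    probs <- predict(model, te)
    cmx <- confusion_from_predictions(probs, te$species, model$classes)
    metrics <- compute_metrics(cmx)
    utils::write.csv(cmx$counts, file.path(out_dir, "confusion_counts.csv"))
    utils::write.csv(round(confusion_percent(cmx), 2),
                     file.path(out_dir, "confusion_percent.csv"))
    mtab <- dplyr::bind_rows(
      metrics,
      tibble(class = "macro_average",
             precision = mean(metrics$precision), recall = mean(metrics$recall),
             specificity = mean(metrics$specificity), mcc = mean(metrics$mcc)))
    readr::write_csv(mtab, file.path(out_dir, "metrics.csv"))
    if (!isFALSE(config$embedding)) {
      emb <- embed_2d(extract_features(model, te), te$species)
      emb$tile_id <- paste0(te$image_id, "_", seq_len(nrow(emb)))
      readr::write_csv(emb, file.path(out_dir, "embedding.csv"))
    }
    list(cm = cmx, metrics = metrics)
  }, error = function(e) e)
  if (inherits(res, "error")) return(fail(stage, res))
  report$confusion <- res$cm
  report$metrics <- res$metrics
  report$macro_average_accuracy <- macro_accuracy(res$metrics)
  report$metrics_path <- file.path(out_dir, "metrics.csv")
  report$confusion_path <- file.path(out_dir, "confusion_counts.csv")
  report$success <- TRUE
  report$stage <- "done"
  report$seeds <- list(synthetic = config$synthetic$seed %||% NA,
                       split = config$split$seed %||% 1L,
                       tiles = config$tile_params$seed %||% 1L,
                       train = config$train$seed %||% 1L)
  log_line(log_path, stage, status = "ok",
           macro_average_accuracy = report$macro_average_accuracy)
  report_json <- report[c("success", "stage", "macro_average_accuracy", "seeds",
                          "package_version")]
  report_json$tile_counts <- counts
  jsonlite::write_json(report_json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows")
  report
}

#' @export
print.elytra_run_report <- function(x, ...) {
  if (isTRUE(x$success)) {
    cat(sprintf("<elytra_run_report> success (stage: %s)\n", x$stage))
    if (!is.null(x$macro_average_accuracy)) {
      cat(sprintf("  macro average accuracy: %.3f\n", x$macro_average_accuracy))
    }
    if (!is.null(x$tile_counts)) {
      tc <- x$tile_counts
      cat(sprintf("  tiles: %d train / %d test\n",
                  sum(tc$n_tiles[tc$partition == "train"]),
                  sum(tc$n_tiles[tc$partition == "test"])))
    }
  } else {
    cat(sprintf("<elytra_run_report> FAILED at stage '%s': %s\n",
                x$stage %||% "?", x$error %||% "unknown error"))
  }
  invisible(x)
}
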