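#' Convolutional classifier configuration
#'
#' The network is fixed in shape: four blocks of 3x3 convolution (ReLU)
#' followed by 2x2 max pooling, then flatten, a 128-unit dense layer
#' (ReLU), dropout, and a softmax output layer with one unit per species.
#' Only the input side, the per-block filter counts and the dropout rate
#' vary.
#'
#' @param input_size Tile side in pixels; must reduce evenly through the
#'   four pooling stages (divisible by 16). Default 448
#'   (448 -> 224 -> 112 -> 56 -> 28).
#' @param n_classes Number of species (output units).
#' @param conv_filters Integer vector of exactly 4 filter counts, one per
#'   conv block. Default `c(32, 64, 128, 256)`.
#' @param dropout_rate Dropout on the 128-unit dense layer during
#'   training, in `[0, 1)`. Default 0.5.
#' @param rescale If `TRUE` (default), inputs with values above 1 are
#'   divided by 255 so 8-bit images reach the network in `[0, 1]`.
#' @return A list of class `"model_config"`.
#' @export
model_config <- function(input_size = 448, n_classes, conv_filters = c(32, 64, 128, 256),
                         dropout_rate = 0.5, rescale = TRUE) {
  input_size <- assert_scalar_count(input_size, "input_size", min = 16L)
  n_classes <- assert_scalar_count(n_classes, "n_classes", min = 2L)
  if (input_size %% 16 != 0) {
    abort("input_size must be divisible by 16 to pass four 2x2 pooling stages evenly.",
          class = "elytra_invalid_config")
  }
  if (length(conv_filters) != 4 || any(conv_filters < 1)) {
    abort("conv_filters must give exactly 4 positive filter counts.",
          class = "elytra_invalid_config")
  }
  assert_fraction(dropout_rate, "dropout_rate")
  if (dropout_rate >= 1) {
    abort("dropout_rate must be < 1.", class = "elytra_invalid_config")
  }
  structure(list(input_size = input_size, n_classes = n_classes,
                 conv_filters = as.integer(conv_filters),
                 kernel = 3L, pool = 2L, dense_units = 128L,
                 dropout_rate = dropout_rate, rescale = isTRUE(rescale)),
            class = "model_config")
}

#' Training configuration
#'
#' @param epochs Number of epochs (>= 0). The study setting is 100; desk-
#'   scale experiments use far fewer.
#' @param batch_size Minibatch size; default 32 (the framework default the
#'   study relied on).
#' @param optimizer Only `"adam"` is supported.
#' @param loss Only `"categorical_crossentropy"` is supported.
#' @param learning_rate Adam step size; default 1e-3.
#' @param seed Seed for shuffling, augmentation draws and dropout masks.
#' @return A list of class `"train_config"`.
#' @export
train_config <- function(epochs = 100, batch_size = 32, optimizer = "adam",
                         loss = "categorical_crossentropy",
                         learning_rate = 1e-3, seed = 1L) {
  epochs <- assert_scalar_count(epochs, "epochs", min = 0L)
  batch_size <- assert_scalar_count(batch_size, "batch_size", min = 1L)
  optimizer <- match.arg(optimizer, "adam")
  loss <- match.arg(loss, "categorical_crossentropy")
  structure(list(epochs = epochs, batch_size = batch_size,
                 optimizer = optimizer, loss = loss,
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "train_config")
}

#' Build (initialize) the convolutional classifier
#'
#' Allocates He-initialized weights for the architecture described in
#' [model_config()]. A forward pass on a batch of B tiles yields a
#' B x n_classes probability matrix whose rows sum to 1.
#'
#' @param config A [model_config()].
#' @param seed Seed for weight initialization (default 1).
#' @return An object of class `"elytra_cnn"`.
#' @export
build_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  S <- config$input_size
  f <- config$conv_filters
  cins <- c(3L, f[1:3])
  side <- S / 16L
  D <- side * side * f[4]
  params <- with_seed(seed, {
    p <- list()
    for (l in 1:4) {
      fan_in <- 9 * cins[l]
      p[[paste0("Wc", l)]] <- matrix(rnorm(fan_in * f[l], 0, sqrt(2 / fan_in)),
                                     fan_in, f[l])
      p[[paste0("bc", l)]] <- numeric(f[l])
    }
    p$W1 <- matrix(rnorm(D * 128, 0, sqrt(2 / D)), D, 128)
    p$b1 <- numeric(128)
    p$W2 <- matrix(rnorm(128 * config$n_classes, 0, sqrt(2 / 128)),
                   128, config$n_classes)
    p$b2 <- numeric(config$n_classes)
    p
  })
  structure(list(config = config, params = params, classes = NULL,
                 history = empty_history(), trained = FALSE,
                 init_seed = as.integer(seed)),
            class = "elytra_cnn")
}

empty_history <- function() {
  tibble(epoch = integer(), train_loss = numeric(), train_accuracy = numeric(),
         val_loss = numeric(), val_accuracy = numeric())
}

#' @export
print.elytra_cnn <- function(x, ...) {
  cfg <- x$config
  n_par <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<elytra_cnn> input %dx%dx3, conv filters %s, dense 128, %d classes, %s (%s parameters)\n",
              cfg$input_size, cfg$input_size,
              paste(cfg$conv_filters, collapse = "-"), cfg$n_classes,
              if (x$trained) sprintf("trained %d epochs", nrow(x$history)) else "untrained",
              format(n_par, big.mark = ",")))
  invisible(x)
}

# Full forward pass. Returns probabilities plus (when `keep = TRUE`) the
# caches needed for backprop. `drop_mask` is the inverted-dropout mask for
# the dense layer (NULL at inference).
cnn_forward <- function(model, x, keep = FALSE, drop_mask = NULL) {
  p <- model$params
  caches <- list()
  h <- x
  for (l in 1:4) {
    cv <- conv_forward(h, p[[paste0("Wc", l)]], p[[paste0("bc", l)]])
    a <- relu(cv$out)
    pl <- pool_forward(a)
    if (keep) caches[[l]] <- list(conv = cv, act = a, pool = pl)
    h <- pl$out
  }
  d <- dim(h)
  N <- d[4]
  flat <- t(matrix(h, d[1] * d[2] * d[3], N))       # N x D
  z1 <- flat %*% p$W1 + matrix(p$b1, N, 128, byrow = TRUE)
  a1 <- relu(z1)                                     # features, pre-dropout
  a1d <- if (is.null(drop_mask)) a1 else a1 * drop_mask
  z2 <- a1d %*% p$W2 + matrix(p$b2, N, ncol(p$W2), byrow = TRUE)
  probs <- softmax_rows(z2)
  out <- list(probs = probs, features = a1)
  if (keep) {
    out$caches <- caches
    out$flat <- flat; out$z1 <- z1; out$a1 <- a1; out$a1d <- a1d
    out$pool_dim <- d
  }
  out
}

# Backward pass from softmax + cross-entropy. `y` is the one-hot N x K
# matrix. Returns gradients named like the parameters.
cnn_backward <- function(model, fw, y, drop_mask = NULL) {
  p <- model$params
  N <- nrow(y)
  g <- list()
  dz2 <- (fw$probs - y) / N
  g$W2 <- crossprod(fw$a1d, dz2)
  g$b2 <- colSums(dz2)
  da1 <- dz2 %*% t(p$W2)
  if (!is.null(drop_mask)) da1 <- da1 * drop_mask
  dz1 <- da1 * (fw$z1 > 0)
  g$W1 <- crossprod(fw$flat, dz1)
  g$b1 <- colSums(dz1)
  dflat <- dz1 %*% t(p$W1)
  d <- fw$pool_dim
  dh <- array(t(dflat), d)
  for (l in 4:1) {
    ca <- fw$caches[[l]]
    da <- pool_backward(dh, ca$pool)
    dconv <- da * (ca$conv$out > 0)
    bk <- conv_backward(dconv, ca$conv, p[[paste0("Wc", l)]])
    g[[paste0("Wc", l)]] <- bk$dW
    g[[paste0("bc", l)]] <- bk$db
    dh <- bk$dx
  }
  g
}

prepare_tiles <- function(tiles, config) {
  if (is.list(tiles) && !is.null(tiles$x)) tiles <- tiles$x
  if (inherits(tiles, "tile")) tiles <- list(tiles)
  if (is.list(tiles) && !is.array(tiles)) tiles <- tile_array(tiles)$x
  d <- dim(tiles)
  if (length(d) == 3) { tiles <- array(tiles, c(d, 1)); d <- dim(tiles) }
  if (d[1] != config$input_size || d[2] != config$input_size || d[3] != 3) {
    abort(sprintf("tiles must be %d x %d x 3; got %s.",
                  config$input_size, config$input_size,
                  paste(d, collapse = " x ")),
          class = "elytra_invalid_argument")
  }
  if (config$rescale && max(tiles) > 1.5) tiles <- tiles / 255
  tiles
}

#' Predict class probabilities for tiles
#'
#' @param object A (trained) `"elytra_cnn"`.
#' @param tiles An S x S x 3 x N array, a `harvest_tiles()` result, or a
#'   list of tiles.
#' @param type `"prob"` for the N x n_classes probability matrix (rows sum
#'   to 1), `"class"` for the argmax species labels (ties broken toward the
#'   lowest class index).
#' @param batch_size Forward-pass batch size.
#' @param ... Unused.
#' @return A probability matrix (with class labels as column names when
#'   known) or a character vector of predicted labels.
#' @export
predict.elytra_cnn <- function(object, tiles, type = c("prob", "class"),
                               batch_size = 64, ...) {
  type <- match.arg(type)
  x <- prepare_tiles(tiles, object$config)
  N <- dim(x)[4]
  probs <- matrix(0, N, object$config$n_classes)
  for (start in seq(1, N, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, N)
    probs[idx, ] <- cnn_forward(object, x[, , , idx, drop = FALSE])$probs
  }
  if (!is.null(object$classes)) colnames(probs) <- object$classes
  if (type == "class") {
    j <- max.col(probs, ties.method = "first")
    if (!is.null(object$classes)) object$classes[j] else j
  } else {
    probs
  }
}

#' Extract the 128-dimensional feature layer
#'
#' Returns the penultimate dense activations (post-ReLU, pre-dropout), one
#' 128-vector per tile — the learned feature representation used for
#' low-dimensional embedding and inspection.
#'
#' @inheritParams predict.elytra_cnn
#' @return An N x 128 non-negative matrix.
#' @export
extract_features <- function(object, tiles, batch_size = 64) {
  stopifnot(inherits(object, "elytra_cnn"))
  x <- prepare_tiles(tiles, object$config)
  N <- dim(x)[4]
  feats <- matrix(0, N, 128)
  for (start in seq(1, N, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, N)
    feats[idx, ] <- cnn_forward(object, x[, , , idx, drop = FALSE])$features
  }
  feats
}

#' Train the convolutional classifier
#'
#' Minimizes categorical cross-entropy with Adam. Augmentation, when
#' given, is applied to training batches only; validation tiles always
#' pass through unmodified (the returned model's `$audit` log records the
#' per-stream augmentation counts). Validation loss and accuracy are
#' computed after every epoch. All shuffling, augmentation draws and
#' dropout masks run under the training seed.
#'
#' @param model An `"elytra_cnn"` from [build_model()].
#' @param train_tiles,val_tiles Lists with `x` (S x S x 3 x N array) and
#'   `species` (length-N labels), e.g. from [harvest_tiles()].
#' @param aug An [augmentation_config()], or `NULL` for no augmentation.
#' @param tc A [train_config()].
#' @return The trained model, carrying `$history` (one row per epoch:
#'   epoch, train_loss, train_accuracy, val_loss, val_accuracy), `$classes`
#'   and `$audit`. Access the history tibble via `tidy()`.
#' @export
train_model <- function(model, train_tiles, val_tiles, aug = NULL,
                        tc = train_config()) {
  stopifnot(inherits(model, "elytra_cnn"), inherits(tc, "train_config"))
  if (!is.null(aug)) stopifnot(inherits(aug, "augmentation_config"))
  if (length(train_tiles$species) == 0 || length(val_tiles$species) == 0) {
    abort("train and validation tile sets must be non-empty.",
          class = "elytra_invalid_dataset")
  }
  classes <- sort(unique(train_tiles$species))
  if (length(classes) != model$config$n_classes) {
    abort(sprintf("training labels name %d classes but the model has %d output units.",
                  length(classes), model$config$n_classes),
          class = "elytra_invalid_dataset")
  }
  extra <- setdiff(unique(val_tiles$species), classes)
  if (length(extra) > 0) {
    abort(sprintf("validation labels absent from training: %s",
                  paste(extra, collapse = ", ")),
          class = "elytra_invalid_dataset")
  }
  model$classes <- classes
  if (tc$epochs == 0L) return(model)

  xt <- prepare_tiles(train_tiles, model$config)
  xv <- prepare_tiles(val_tiles, model$config)
  S <- model$config$input_size
  n_tr <- dim(xt)[4]
  yt <- outer(train_tiles$species, classes, "==") * 1
  yv <- outer(val_tiles$species, classes, "==") * 1
  rate <- model$config$dropout_rate

  opt <- adam_init(model$params)
  t_step <- 0L
  n_aug_total <- 0L
  history <- vector("list", tc$epochs)

  model2 <- with_seed(tc$seed, {
    for (ep in seq_len(tc$epochs)) {
      ord <- sample.int(n_tr)
      ep_loss <- 0; ep_hits <- 0
      for (start in seq(1, n_tr, by = tc$batch_size)) {
        idx <- ord[start:min(start + tc$batch_size - 1, n_tr)]
        xb <- xt[, , , idx, drop = FALSE]
        yb <- yt[idx, , drop = FALSE]
        if (!is.null(aug)) {
          for (k in seq_along(idx)) {
            xb[, , , k] <- apply_augmentation(xb[, , , k],
                                              sample_augmentation(aug, S))
          }
          n_aug_total <- n_aug_total + length(idx)
        }
        B <- length(idx)
        dm <- if (rate > 0) {
          matrix((runif(B * 128) >= rate) / (1 - rate), B, 128)
        } else NULL
        fw <- cnn_forward(model, xb, keep = TRUE, drop_mask = dm)
        eps <- 1e-12
        ep_loss <- ep_loss - sum(log(pmax(rowSums(fw$probs * yb), eps)))
        ep_hits <- ep_hits + sum(max.col(fw$probs, ties.method = "first") ==
                                   max.col(yb, ties.method = "first"))
        grads <- cnn_backward(model, fw, yb, drop_mask = dm)
        t_step <- t_step + 1L
        upd <- adam_step(model$params, grads, opt, t_step, lr = tc$learning_rate)
        model$params <- upd$params
        opt <- upd$state
      }
      val <- evaluate_loss_acc(model, xv, yv, tc$batch_size)
      history[[ep]] <- tibble(epoch = ep,
                              train_loss = ep_loss / n_tr,
                              train_accuracy = ep_hits / n_tr,
                              val_loss = val$loss, val_accuracy = val$acc)
    }
    model
  })
  model2$history <- dplyr::bind_rows(history)
  model2$trained <- TRUE
  model2$audit <- tibble(
    stream = c("train", "validation"),
    n_tiles_seen = c(n_tr * tc$epochs, dim(xv)[4] * tc$epochs),
    n_augmented = c(n_aug_total, 0L)
  )
  model2
}

evaluate_loss_acc <- function(model, x, y, batch_size = 64) {
  N <- dim(x)[4]
  loss <- 0; hits <- 0
  for (start in seq(1, N, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, N)
    pr <- cnn_forward(model, x[, , , idx, drop = FALSE])$probs
    yb <- y[idx, , drop = FALSE]
    loss <- loss - sum(log(pmax(rowSums(pr * yb), 1e-12)))
    hits <- hits + sum(max.col(pr, ties.method = "first") ==
                         max.col(yb, ties.method = "first"))
  }
  list(loss = loss / N, acc = hits / N)
}

#' Save / load model weights
#'
#' Weights, configuration and history are serialized as plain JSON so the
#' checkpoint survives text-only storage.
#'
#' @param model An `"elytra_cnn"`.
#' @param path Destination file.
#' @return `save_model()` returns `path` invisibly; `load_model()` the
#'   restored model.
#' @export
save_model <- function(model, path) {
  payload <- list(
    config = unclass(model$config),
    classes = model$classes,
    trained = model$trained,
    init_seed = model$init_seed,
    history = model$history,
    params = lapply(model$params, function(p) {
      if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
      else list(dim = NULL, data = as.numeric(p))
    })
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- payload$config
  config <- model_config(input_size = cfg$input_size, n_classes = cfg$n_classes,
                         conv_filters = cfg$conv_filters,
                         dropout_rate = cfg$dropout_rate, rescale = cfg$rescale)
  params <- lapply(payload$params, function(p) {
    if (!is.null(p$dim) && length(p$dim) == 2) matrix(p$data, p$dim[1], p$dim[2])
    else as.numeric(p$data)
  })
  structure(list(config = config, params = params,
                 classes = payload$classes,
                 history = tibble::as_tibble(payload$history),
                 trained = isTRUE(payload$trained),
                 init_seed = payload$init_seed),
            class = "elytra_cnn")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training history of a fitted classifier
#' @param x An `"elytra_cnn"`.
#' @param ... Unused.
#' @return Tibble with one row per epoch.
#' @method tidy elytra_cnn
#' @export
tidy.elytra_cnn <- function(x, ...) x$history

#' One-row summary of a fitted classifier
#' @param x An `"elytra_cnn"`.
#' @param ... Unused.
#' @return Tibble with epochs trained, final losses/accuracies, class and
#'   parameter counts.
#' @method glance elytra_cnn
#' @export
glance.elytra_cnn <- function(x, ...) {
  h <- x$history
  tibble(
    epochs = nrow(h),
    train_loss = if (nrow(h)) h$train_loss[nrow(h)] else NA_real_,
    train_accuracy = if (nrow(h)) h$train_accuracy[nrow(h)] else NA_real_,
    val_loss = if (nrow(h)) h$val_loss[nrow(h)] else NA_real_,
    val_accuracy = if (nrow(h)) h$val_accuracy[nrow(h)] else NA_real_,
    n_classes = x$config$n_classes,
    n_parameters = sum(vapply(x$params, length, integer(1)))
  )
}
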