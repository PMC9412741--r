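test_that("analytic gradients match finite differences on a tiny network", {
  cfg <- model_config(input_size = 16, n_classes = 3,
                      conv_filters = c(2, 3, 2, 2), dropout_rate = 0)
  m <- build_model(cfg, seed = 42)
  set.seed(9)
  x <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  y <- rbind(c(1, 0, 0), c(0, 0, 1))
  loss_fn <- function(mm) {
    fw <- elytra:::cnn_forward(mm, x)
    -sum(log(pmax(rowSums(fw$probs * y), 1e-12))) / 2
  }
  fw <- elytra:::cnn_forward(m, x, keep = TRUE)
  g <- elytra:::cnn_backward(m, fw, y)
  eps <- 1e-5
  for (nm in names(m$params)) {
    set.seed(match(nm, names(m$params)))
    ii <- sample(length(m$params[[nm]]), min(4, length(m$params[[nm]])))
    for (i in ii) {
      mp <- m; mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
      mn <- m; mn$params[[nm]][i] <- mn$params[[nm]][i] - eps
      num <- (loss_fn(mp) - loss_fn(mn)) / (2 * eps)
      ana <- g[[nm]][i]
      expect_lt(abs(num - ana) / max(1e-8, abs(num) + abs(ana)), 1e-5)
    }
  }
})

test_that("architecture contracts hold: widths, softmax rows, feature layer", {
  cfg <- model_config(input_size = 64, n_classes = 27,
                      conv_filters = c(4, 4, 8, 8), dropout_rate = 0.5)
  m <- build_model(cfg, seed = 1)
  expect_equal(ncol(m$params$W2), 27)    # output layer width
  expect_equal(ncol(m$params$W1), 128)   # penultimate width
  set.seed(2)
  x <- array(runif(64 * 64 * 3 * 3), c(64, 64, 3, 3))
  pr <- predict(m, x)
  expect_equal(dim(pr), c(3, 27))
  expect_equal(rowSums(pr), rep(1, 3), tolerance = 1e-6)
  # deterministic inference
  expect_identical(pr, predict(m, x))
  ft <- extract_features(m, x)
  expect_equal(dim(ft), c(3, 128))
  expect_true(all(ft >= 0))
  # identical tiles give identical features
  x2 <- x; x2[, , , 2] <- x2[, , , 1]
  ft2 <- extract_features(m, x2)
  expect_identical(ft2[1, ], ft2[2, ])
})

test_that("invalid model configurations are rejected", {
  expect_error(model_config(input_size = 50, n_classes = 3),
               class = "elytra_invalid_config")
  expect_error(model_config(input_size = 64, n_classes = 3,
                            conv_filters = c(8, 8, 8)),
               class = "elytra_invalid_config")
  expect_error(model_config(input_size = 64, n_classes = 3, dropout_rate = 1),
               class = "elytra_invalid_config")
  m <- build_model(model_config(input_size = 32, n_classes = 2,
                                conv_filters = c(2, 2, 2, 2)))
  expect_error(predict(m, array(0, c(16, 16, 3, 1))),
               class = "elytra_invalid_argument")
})

test_that("training history has one row per epoch and epochs = 0 is a no-op", {
  set <- render_image_set(2, 3, seed = 61, image_size = c(96, 128))
  parts <- split_and_harvest(set, 1 / 3, tiles_per_image = 4, tile_size = 32,
                             split_seed = 1, tile_seed = 2)
  cfg <- model_config(input_size = 32, n_classes = 2,
                      conv_filters = c(2, 2, 4, 4), dropout_rate = 0.5)
  m0 <- build_model(cfg, seed = 3)
  m_none <- train_model(m0, parts$train, parts$test,
                        tc = train_config(epochs = 0, seed = 5))
  expect_equal(nrow(m_none$history), 0)
  expect_identical(m_none$params, m0$params)

  m2 <- train_model(m0, parts$train, parts$test,
                    tc = train_config(epochs = 2, seed = 5))
  expect_equal(nrow(m2$history), 2)
  expect_identical(tidy(m2), m2$history)
  expect_true(all(m2$history$train_loss >= 0))
  expect_true(all(m2$history$val_accuracy >= 0 & m2$history$val_accuracy <= 1))
  expect_equal(glance(m2)$epochs, 2)

  # label present in validation but absent from training
  bad_val <- parts$test
  bad_val$species[1] <- "GHOST"
  expect_error(train_model(m0, parts$train, bad_val,
                           tc = train_config(epochs = 1, seed = 5)),
               class = "elytra_invalid_dataset")
})

test_that("identical seeds and data reproduce identical training histories", {
  set <- render_image_set(2, 3, seed = 71, image_size = c(96, 128))
  parts <- split_and_harvest(set, 1 / 3, tiles_per_image = 4, tile_size = 32,
                             split_seed = 1, tile_seed = 2)
  cfg <- model_config(input_size = 32, n_classes = 2,
                      conv_filters = c(2, 2, 4, 4), dropout_rate = 0.5)
  run <- function() {
    m <- build_model(cfg, seed = 3)
    train_model(m, parts$train, parts$test,
                aug = augmentation_config(),
                tc = train_config(epochs = 2, seed = 5))
  }
  h1 <- run()$history
  h2 <- run()$history
  expect_equal(h1, h2, tolerance = 1e-12)
})

test_that("augmentation touches the training stream only (audit log)", {
  set <- render_image_set(2, 3, seed = 81, image_size = c(96, 128))
  parts <- split_and_harvest(set, 1 / 3, tiles_per_image = 3, tile_size = 32,
                             split_seed = 1, tile_seed = 2)
  cfg <- model_config(input_size = 32, n_classes = 2,
                      conv_filters = c(2, 2, 2, 2), dropout_rate = 0)
  m <- train_model(build_model(cfg, seed = 1), parts$train, parts$test,
                   aug = augmentation_config(),
                   tc = train_config(epochs = 2, seed = 9))
  audit <- m$audit
  expect_equal(audit$n_augmented[audit$stream == "validation"], 0)
  expect_equal(audit$n_augmented[audit$stream == "train"],
               audit$n_tiles_seen[audit$stream == "train"])
})

test_that("dropout reduces the train/validation gap on a deliberately tiny training set", {
  set <- render_image_set(2, 5, seed = 91, image_size = c(96, 128))
  # tiny training set: 1 tile per training image; larger validation pool
  parts <- split_and_harvest(set, 0.4, tiles_per_image = 3, tile_size = 32,
                             split_seed = 2, tile_seed = 3)
  keep <- !duplicated(parts$train$image_id)
  tiny_train <- list(x = parts$train$x[, , , keep, drop = FALSE],
                     species = parts$train$species[keep],
                     image_id = parts$train$image_id[keep])
  gap_for <- function(rate) {
    cfg <- model_config(input_size = 32, n_classes = 2,
                        conv_filters = c(4, 4, 8, 8), dropout_rate = rate)
    m <- train_model(build_model(cfg, seed = 7), tiny_train, parts$test,
                     tc = train_config(epochs = 10, seed = 11))
    h <- m$history
    mean(h$train_accuracy[8:10] - h$val_accuracy[8:10])
  }
  expect_gte(gap_for(0), gap_for(0.5) - 0.05)
})

test_that("model checkpoints round-trip through save/load", {
  cfg <- model_config(input_size = 32, n_classes = 3,
                      conv_filters = c(2, 2, 2, 2), dropout_rate = 0.5)
  m <- build_model(cfg, seed = 13)
  m$classes <- c("A", "B", "C")
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  set.seed(5)
  x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  expect_equal(predict(m, x), predict(m2, x), tolerance = 1e-12)
})
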