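test_that("confusion counts match a hand tally and the perfect case is diagonal", {
  classes <- c("A", "B", "C")
  # 5 tiles with explicit probabilities; argmaxes: A, B, A, C, B (tie -> lowest index)
  probs <- rbind(c(0.7, 0.2, 0.1),
                 c(0.1, 0.8, 0.1),
                 c(0.5, 0.5, 0.0),   # tie A/B -> A
                 c(0.2, 0.2, 0.6),
                 c(0.3, 0.4, 0.3))
  truth <- c("A", "B", "B", "C", "A")
  cm <- confusion_from_predictions(probs, truth, classes)
  hand <- matrix(0L, 3, 3, dimnames = list(true = classes, predicted = classes))
  hand["A", "A"] <- 1; hand["A", "B"] <- 1
  hand["B", "B"] <- 1; hand["B", "A"] <- 1
  hand["C", "C"] <- 1
  expect_equal(unclass(cm$counts), unclass(hand))

  # perfect classifier: diagonal counts, all metrics 1
  perfect <- confusion_from_predictions(truth, truth, classes)
  expect_true(all(perfect$counts[upper.tri(perfect$counts)] == 0))
  expect_true(all(perfect$counts[lower.tri(perfect$counts)] == 0))
  mt <- compute_metrics(perfect)
  expect_true(all(mt$precision == 1 & mt$recall == 1 &
                    mt$specificity == 1 & mt$mcc == 1))
  expect_equal(macro_accuracy(mt), 1)

  # row-normalized rows sum to 100 for non-empty rows
  pct <- confusion_percent(cm)
  expect_equal(unname(rowSums(pct)), c(100, 100, 100))
  expect_error(confusion_from_predictions(truth, c(truth[-5], "Z"), classes),
               class = "elytra_invalid_argument")
})

test_that("a 2-class matrix reproduces metrics verified against raw label lists", {
  # [[8,2],[1,9]]: rebuild the equivalent 20-item lists and tally by brute force
  truth <- c(rep("P", 10), rep("N", 10))
  pred <- c(rep("P", 8), rep("N", 2), "P", rep("N", 9))
  cm <- confusion_from_predictions(pred, truth, c("P", "N"))
  expect_equal(unname(cm$counts["P", ]), c(8, 2))
  expect_equal(unname(cm$counts["N", ]), c(1, 9))
  mt <- compute_metrics(cm)
  p_row <- mt[mt$class == "P", ]
  expect_equal(p_row$TP, 8); expect_equal(p_row$FN, 2)
  expect_equal(p_row$FP, 1); expect_equal(p_row$TN, 9)
  # frozen values from the counting oracle: precision 8/9, recall 8/10,
  # specificity 9/10, MCC 70/sqrt(9900)
  expect_equal(p_row$precision, 8 / 9)
  expect_equal(p_row$recall, 0.8)
  expect_equal(p_row$specificity, 0.9)
  expect_equal(p_row$mcc, 70 / sqrt(9900))
  bf <- brute_force_metrics(truth, pred, c("P", "N"))
  expect_equal(as.data.frame(mt), bf, ignore_attr = TRUE)
})

test_that("metrics equal the brute-force pair-counting oracle on random lists", {
  set.seed(123)
  for (rep in 1:10) {
    k <- sample(2:6, 1)
    n <- sample(20:200, 1)
    classes <- LETTERS[1:k]
    truth <- sample(classes, n, replace = TRUE)
    pred <- sample(classes, n, replace = TRUE)
    mt <- compute_metrics(confusion_from_predictions(pred, truth, classes))
    bf <- brute_force_metrics(truth, pred, classes)
    expect_equal(as.data.frame(mt), bf, ignore_attr = TRUE)
    expect_true(all(mt$mcc >= -1 & mt$mcc <= 1))
  }
})

test_that("a constant predictor gets MCC 0 under the zero-denominator rule", {
  truth <- c("A", "A", "B", "B", "C")
  pred <- rep("A", 5)
  mt <- compute_metrics(confusion_from_predictions(pred, truth, c("A", "B", "C")))
  expect_equal(mt$mcc, rep(0, 3))
})

test_that("the 2-D embedding preserves shape, duplicates and class structure", {
  set.seed(7)
  centers <- matrix(rnorm(3 * 128, sd = 4), 3, 128)
  feats <- centers[rep(1:3, each = 20), ] + matrix(rnorm(60 * 128, sd = 0.3), 60, 128)
  labels <- rep(c("A", "B", "C"), each = 20)
  emb <- embed_2d(feats, labels)
  expect_equal(dim(emb), c(60, 3))
  # duplicated rows map to coincident points
  feats2 <- rbind(feats[1, ], feats[1, ], feats[2, ])
  emb2 <- embed_2d(feats2)
  expect_lt(sqrt(sum((emb2[1, 1:2] - emb2[2, 1:2])^2)), 1e-8)
  # separable classes: inter-centroid distance > intra-class spread
  cents <- sapply(c("A", "B", "C"), function(l) {
    colMeans(as.matrix(emb[emb$label == l, 1:2]))
  })
  inter <- mean(dist(t(cents)))
  intra <- mean(sapply(c("A", "B", "C"), function(l) {
    xy <- as.matrix(emb[emb$label == l, 1:2])
    mean(sqrt(rowSums(sweep(xy, 2, colMeans(xy))^2)))
  }))
  expect_gt(inter, intra)
  expect_error(embed_2d(feats[1:2, ]), class = "elytra_invalid_argument")
})

test_that("majority vote aggregates tile predictions per source image", {
  votes <- majority_vote(c("A", "A", "B", "B", "B", "C"),
                         c("i1", "i1", "i1", "i2", "i2", "i2"))
  expect_equal(votes$predicted[votes$image_id == "i1"], "A")
  expect_equal(votes$predicted[votes$image_id == "i2"], "B")
})
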