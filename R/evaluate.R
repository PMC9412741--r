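#' Confusion matrix from predicted probabilities
#'
#' The predicted class per tile is the argmax of its probability row (ties
#' broken toward the lowest class index); counts are accumulated into a
#' K x K matrix with rows = true class, columns = predicted class.
#'
#' @param probabilities N x K matrix of class probabilities (or already-
#'   predicted labels as a character vector).
#' @param true_labels Length-N true species labels.
#' @param class_order Class labels in matrix order; must cover every label
#'   that occurs.
#' @return An object of class `"elytra_confusion"`: list with `counts`
#'   (K x K integer matrix with dimnames) and `class_order`.
#' @export
confusion_from_predictions <- function(probabilities, true_labels, class_order) {
  if (is.character(probabilities)) {
    pred <- probabilities
  } else {
    stopifnot(is.matrix(probabilities), nrow(probabilities) == length(true_labels))
    if (ncol(probabilities) != length(class_order)) {
      abort("probability columns must align with class_order.",
            class = "elytra_invalid_argument")
    }
    pred <- class_order[max.col(probabilities, ties.method = "first")]
  }
  bad <- setdiff(unique(c(true_labels, pred)), class_order)
  if (length(bad) > 0) {
    abort(sprintf("labels outside class_order: %s", paste(bad, collapse = ", ")),
          class = "elytra_invalid_argument")
  }
  tl <- factor(true_labels, levels = class_order)
  pl <- factor(pred, levels = class_order)
  counts <- unclass(table(tl, pl))
  dimnames(counts) <- list(true = class_order, predicted = class_order)
  structure(list(counts = counts, class_order = class_order),
            class = "elytra_confusion")
}

#' Row-percent view of a confusion matrix
#'
#' Expresses each row (true class) as percentages of that class's total —
#' the diagonal is then the per-species accuracy (recall). Empty rows stay
#' at zero.
#'
#' @param cm An `"elytra_confusion"`.
#' @return K x K numeric matrix of percentages; non-empty rows sum to 100.
#' @export
confusion_percent <- function(cm) {
  stopifnot(inherits(cm, "elytra_confusion"))
  rs <- rowSums(cm$counts)
  out <- cm$counts * 0
  nz <- rs > 0
  out[nz, ] <- 100 * cm$counts[nz, , drop = FALSE] / rs[nz]
  out
}

#' @export
print.elytra_confusion <- function(x, ...) {
  cat(sprintf("<elytra_confusion> %d classes, %d tiles, trace %d\n",
              length(x$class_order), sum(x$counts), sum(diag(x$counts))))
  print(x$counts)
  invisible(x)
}

#' Tidy a confusion matrix into long form
#' @param x An `"elytra_confusion"`.
#' @param ... Unused.
#' @return Tibble `(true, predicted, n, percent)`, one row per cell.
#' @method tidy elytra_confusion
#' @export
tidy.elytra_confusion <- function(x, ...) {
  pct <- confusion_percent(x)
  grid <- expand.grid(true = x$class_order, predicted = x$class_order,
                      stringsAsFactors = FALSE)
  tibble(true = grid$true, predicted = grid$predicted,
         n = as.integer(x$counts[cbind(grid$true, grid$predicted)]),
         percent = as.numeric(pct[cbind(grid$true, grid$predicted)]))
}

#' Per-species one-vs-rest metrics
#'
#' For every class i: TP = counts[i,i], FN = row sum - TP, FP = column sum
#' - TP, TN = total - TP - FP - FN; then precision = TP/(TP+FP), recall
#' (sensitivity, the per-species accuracy) = TP/(TP+FN), specificity =
#' TN/(TN+FP), and the Matthews correlation coefficient
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' Any metric with a zero denominator is defined as 0. The macro average
#' accuracy — the mean of per-class recalls — is attached as attribute
#' `"macro_average_accuracy"` and reported by [macro_accuracy()].
#'
#' @param cm An `"elytra_confusion"`.
#' @return A tibble with one row per class: `class, TP, FP, TN, FN,
#'   precision, recall, specificity, mcc`.
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "elytra_confusion"))
  total <- sum(cm$counts)
  if (total == 0) {
    abort("confusion matrix is empty.", class = "elytra_invalid_argument")
  }
  tp <- diag(cm$counts)
  fn <- rowSums(cm$counts) - tp
  fp <- colSums(cm$counts) - tp
  tn <- total - tp - fp - fn
  safe_div <- function(num, den) ifelse(den == 0, 0, num / den)
  # products can exceed integer range; compute MCC in doubles
  tpd <- as.numeric(tp); fnd <- as.numeric(fn)
  fpd <- as.numeric(fp); tnd <- as.numeric(tn)
  denom <- sqrt((tpd + fpd) * (tpd + fnd) * (tnd + fpd) * (tnd + fnd))
  out <- tibble(
    class = cm$class_order,
    TP = as.integer(tp), FP = as.integer(fp),
    TN = as.integer(tn), FN = as.integer(fn),
    precision = safe_div(tpd, tpd + fpd),
    recall = safe_div(tpd, tpd + fnd),
    specificity = safe_div(tnd, tnd + fpd),
    mcc = ifelse(denom == 0, 0, (tpd * tnd - fpd * fnd) / denom)
  )
  attr(out, "macro_average_accuracy") <- mean(out$recall)
  out
}

#' Macro average prediction accuracy
#'
#' The average of species-wise accuracies (per-class recalls, the diagonal
#' of the row-percent confusion matrix divided by 100).
#'
#' @param x An `"elytra_confusion"` or a [compute_metrics()] tibble.
#' @return A single number in `[0, 1]`.
#' @export
macro_accuracy <- function(x) {
  if (inherits(x, "elytra_confusion")) x <- compute_metrics(x)
  m <- attr(x, "macro_average_accuracy")
  if (is.null(m)) mean(x$recall) else m
}

#' Aggregate tile predictions to image level by majority vote
#'
#' Optional aggregation: each source image is assigned the species most
#' often predicted among its tiles (ties toward the lexicographically
#' first label). Off by default in every pipeline; metrics are reported at
#' tile level unless this is requested explicitly.
#'
#' @param pred_labels Length-N predicted tile labels.
#' @param image_ids Length-N source-image ids.
#' @return Tibble `(image_id, predicted)` with one row per image.
#' @export
majority_vote <- function(pred_labels, image_ids) {
  stopifnot(length(pred_labels) == length(image_ids))
  tibble(image_id = image_ids, predicted = pred_labels) |>
    dplyr::count(.data$image_id, .data$predicted) |>
    dplyr::arrange(.data$image_id, dplyr::desc(.data$n), .data$predicted) |>
    dplyr::distinct(.data$image_id, .keep_all = TRUE) |>
    dplyr::select("image_id", "predicted")
}

#' Two-dimensional embedding of the feature layer
#'
#' Projects the 128-dimensional penultimate-layer activations to two
#' dimensions for visual inspection of class structure. The projection is
#' linear (principal components of the centered feature matrix): it is
#' deterministic, keeps duplicated rows coincident, and places well-
#' separated classes apart.
#'
#' @param features N x P feature matrix (N >= 3).
#' @param labels Optional length-N labels carried into the output.
#' @return Tibble `(x, y, label)`.
#' @export
embed_2d <- function(features, labels = NULL) {
  stopifnot(is.matrix(features))
  if (nrow(features) < 3) {
    abort("need at least 3 rows to embed.", class = "elytra_invalid_argument")
  }
  ctr <- scale(features, center = TRUE, scale = FALSE)
  sv <- svd(ctr, nu = 2, nv = 0)
  coords <- sv$u * rep(sv$d[1:2], each = nrow(features))
  tibble(x = coords[, 1], y = coords[, 2],
         label = if (is.null(labels)) NA_character_ else as.character(labels))
}
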