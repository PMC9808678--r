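#' Rescale an image from the 0-255 scale to [0, 1]
#'
#' Divides elementwise by the image maximum, so any image with a nonzero
#' pixel has maximum exactly 1 after rescaling. A constant-zero image is
#' returned unchanged (the divisor falls back to the format maximum 255 to
#' avoid division by zero).
#'
#' @param image Non-empty numeric array with non-negative entries.
#' @return Array of the same shape on [0, 1].
#' @examples
#' rescale_image(c(0, 51, 255))  # 0 0.2 1
#' @export
rescale_image <- function(image) {
  if (length(image) == 0) stopf("image must be non-empty")
  if (any(image < 0)) stopf("image must be non-negative")
  xmax <- max(image)
  if (xmax == 0) xmax <- 255
  image / xmax
}

#' Pixel-wise confusion counts between two binary masks
#'
#' Tallies true/false positives and negatives between a predicted and a true
#' binary mask. These four counts are the single source from which
#' [dice_coefficient()], [iou()] and [pixel_accuracy()] are computed.
#'
#' @param pred,true Binary arrays (values 0/1) of identical shape.
#' @return A `confusion_counts` object: list with integer `TP`, `TN`, `FP`,
#'   `FN` summing to the number of compared elements.
#' @examples
#' confusion_counts(c(1, 1, 0, 0), c(1, 0, 1, 0))  # TP=FP=FN=TN=1
#' @export
confusion_counts <- function(pred, true) {
  check_same_shape(pred, true, "pred and true masks")
  check_binary_mask(pred, "pred mask")
  check_binary_mask(true, "true mask")
  tp <- sum(pred == 1 & true == 1)
  tn <- sum(pred == 0 & true == 0)
  fp <- sum(pred == 1 & true == 0)
  fn <- sum(pred == 0 & true == 1)
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d TN=%d FP=%d FN=%d (total %d)\n",
              x$TP, x$TN, x$FP, x$FN, x$TP + x$TN + x$FP + x$FN))
  invisible(x)
}

#' Dice coefficient, IoU and pixel accuracy from confusion counts
#'
#' `dice_coefficient()` is 2TP / (2TP + FN + FP); `iou()` (Jaccard index) is
#' TP / (TP + FP + FN); the two are linked by DSC = 2J / (1 + J).
#' `pixel_accuracy()` is (TP + TN) / (TP + TN + FP + FN). When both masks
#' have no positive pixels, Dice and IoU are defined as 1 (perfect agreement
#' on emptiness) and carry an `empty_union` attribute as an audit flag.
#'
#' @param counts A `confusion_counts` object (or list with TP/TN/FP/FN).
#' @return Scalar in [0, 1].
#' @examples
#' cc <- confusion_counts(c(1, 1, 0, 0), c(1, 0, 1, 0))
#' dice_coefficient(cc)  # 0.5
#' iou(cc)               # 1/3
#' @export
dice_coefficient <- function(counts) {
  denom <- 2 * counts$TP + counts$FN + counts$FP
  if (denom == 0) return(structure(1.0, empty_union = TRUE))
  2 * counts$TP / denom
}

#' @rdname dice_coefficient
#' @export
iou <- function(counts) {
  denom <- counts$TP + counts$FP + counts$FN
  if (denom == 0) return(structure(1.0, empty_union = TRUE))
  counts$TP / denom
}

#' @rdname dice_coefficient
#' @export
pixel_accuracy <- function(counts) {
  total <- counts$TP + counts$TN + counts$FP + counts$FN
  if (total == 0) stopf("pixel_accuracy undefined for zero total count")
  (counts$TP + counts$TN) / total
}

#' Dice loss: the complement of the Dice coefficient
#'
#' @param dsc Dice coefficient in [0, 1].
#' @return `1 - dsc`.
#' @examples
#' dice_loss(0.9691)  # 0.0309
#' @export
dice_loss <- function(dsc) {
  if (any(dsc < 0 | dsc > 1)) stopf("dice coefficient must lie in [0, 1]")
  1 - as.numeric(dsc)
}

#' Sparse categorical cross-entropy
#'
#' Mean over samples of the negative log-probability assigned to the true
#' integer class label. Probabilities are clipped to `[eps, 1]` before the
#' logarithm, so a perfect one-hot prediction scores `-log(1 - eps) > 0`
#' rather than exactly zero.
#'
#' @param y Integer true labels in `0:(C-1)`, length n.
#' @param y_hat n x C matrix of predicted class probabilities (rows sum to 1
#'   within 1e-6). A single probability vector is accepted for n = 1.
#' @param eps Clipping floor for probabilities (default 1e-7).
#' @return Non-negative scalar.
#' @examples
#' sparse_categorical_cross_entropy(0:3, matrix(0.25, 4, 4))  # log(4)
#' @export
sparse_categorical_cross_entropy <- function(y, y_hat, eps = 1e-7) {
  if (is.null(dim(y_hat))) y_hat <- matrix(y_hat, nrow = 1)
  n <- nrow(y_hat); C <- ncol(y_hat)
  if (length(y) != n) stopf("length(y) = %d but y_hat has %d rows", length(y), n)
  if (any(y < 0 | y >= C)) stopf("labels must lie in 0..%d", C - 1)
  rs <- rowSums(y_hat)
  if (any(abs(rs - 1) > 1e-6))
    stopf("y_hat rows must sum to 1 (max deviation %.2e)", max(abs(rs - 1)))
  p <- y_hat[cbind(seq_len(n), y + 1)]
  mean(-log(pmin(pmax(p, eps), 1)))
}

# Per-pixel segmentation SCCE for one or more images.
# probs: (H, W, C) or (H, W, C, N); mask: (H, W) or (H, W, N) integer labels.
seg_scce <- function(probs, mask, eps = 1e-7) {
  d <- dim(probs)
  if (length(d) == 3) { dim(probs) <- c(d, 1); d <- dim(probs) }
  if (is.matrix(mask)) dim(mask) <- c(dim(mask), 1)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  tot <- 0
  for (n in seq_len(N)) {
    pn <- probs[, , , n, drop = FALSE]
    dim(pn) <- c(H * W, C)
    lab <- as.vector(mask[, , n]) + 1L
    p <- pn[cbind(seq_len(H * W), lab)]
    tot <- tot + sum(-log(pmin(pmax(p, eps), 1)))
  }
  tot / (H * W * N)
}

#' Evaluation report as JSON
#'
#' Serializes a [evaluate_munet()] report: per-image Dice/IoU/accuracy, their
#' aggregate means and standard deviations, the classification confusion
#' matrix and per-class recall.
#'
#' @param report A `munet_evaluation` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_evaluation_report <- function(report, path) {
  out <- list(
    per_image = report$per_image,
    aggregate = report$aggregate,
    classification = list(
      accuracy = report$cls_accuracy,
      confusion_matrix = report$cls_confusion,
      per_class_recall = report$per_class_recall,
      scce = report$cls_scce))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", matrix = "rowmajor")
  invisible(path)
}
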