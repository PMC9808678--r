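#' Grad-CAM heatmap for a classification decision
#'
#' Computes a gradient-weighted class activation map from the deepest shared
#' convolutional features (the bottleneck block whose output feeds the
#' classification branch). The gradient of the pre-softmax class score with
#' respect to each bottleneck feature map is averaged over space to give one
#' weight per channel; the ReLU of the weighted sum of feature maps is
#' normalized by its maximum (an all-zero map stays all-zero) and bilinearly
#' upsampled to the input resolution.
#'
#' @param model A `munet_model` with a classification head.
#' @param image H x W matrix rescaled to [0, 1] (see [rescale_image()]).
#' @param class_index Class to explain, in `0:(cls_classes - 1)`.
#' @return A `heatmap`: list with `values` (H x W matrix in [0, 1]) and
#'   `class_index`.
#' @export
gradcam <- function(model, image, class_index) {
  C <- model$config$cls_classes
  if (length(class_index) != 1 || class_index < 0 || class_index >= C)
    stopf("class_index must be in 0..%d", C - 1)
  x <- as_input_tensor(image)
  fw <- munet_forward(model, x, training = FALSE)
  g_logits <- matrix(0, C, 1)
  g_logits[class_index + 1, 1] <- 1  # d(score_k)/d(logits)
  hb <- head_bwd(model, fw$cache, g_logits)
  A <- fw$cache$bott$b$out          # (hb, wb, Cb, 1)
  G <- hb$g_z
  cam <- cam_combine(A[, , , 1, drop = TRUE], G[, , , 1, drop = TRUE])
  H <- dim(x)[1]; W <- dim(x)[2]
  up <- bilinear_resize(cam, H, W)
  up <- pmin(pmax(up, 0), 1)
  structure(list(values = up, class_index = as.integer(class_index)),
            class = "heatmap")
}

# Core Grad-CAM combination: per-channel spatial-mean gradient weights, ReLU
# of the weighted feature-map sum, normalization by the maximum (an all-zero
# or all-non-positive raw map stays all-zero).
cam_combine <- function(A, G) {
  if (length(dim(A)) == 2) { dim(A) <- c(dim(A), 1); dim(G) <- dim(A) }
  d <- dim(A)
  cam <- matrix(0, d[1], d[2])
  for (k in seq_len(d[3])) cam <- cam + mean(G[, , k]) * A[, , k]
  cam <- pmax(cam, 0)
  mx <- max(cam)
  if (mx > 0) cam <- cam / mx
  cam
}

#' @export
print.heatmap <- function(x, ...) {
  cat(sprintf("<heatmap> %dx%d for class %d, range [%.3f, %.3f]\n",
              nrow(x$values), ncol(x$values), x$class_index,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Binarize per-pixel segmentation probabilities
#'
#' Per-pixel argmax over the class axis; ties are broken toward the
#' background (class 0), so a pixel with probabilities (0.5, 0.5) maps to 0.
#'
#' @param seg_probs (H, W, C), (H, W, C, 1) or (H, W, C, N) probabilities
#'   summing to 1 over the class axis.
#' @return (H, W) matrix — or (H, W, N) array — of integer class labels; for
#'   the default two-class lung problem this is the 0/1 lung mask.
#' @export
binarize_mask <- function(seg_probs) {
  d <- dim(seg_probs)
  if (is.null(d) || !length(d) %in% c(3, 4))
    stopf("seg_probs must be an (H, W, C[, N]) array")
  if (length(d) == 3) dim(seg_probs) <- c(d, 1)
  d <- dim(seg_probs)
  zp <- aperm(seg_probs, c(1, 2, 4, 3))
  dim(zp) <- c(d[1] * d[2] * d[4], d[3])
  s <- rowSums(zp)
  if (any(abs(s - 1) > 1e-6) || any(zp < -1e-9))
    stopf("seg_probs is not a per-pixel probability tensor (class sums deviate by up to %.2e)",
          max(abs(s - 1)))
  lab <- max.col(zp, ties.method = "first") - 1L
  out <- array(lab, c(d[1], d[2], d[4]))
  if (d[4] == 1) dim(out) <- c(d[1], d[2])
  out
}

# Blue-to-red colormap for heatmap values in [0, 1]; returns an n x 3 matrix.
cam_colormap <- function(v) {
  ramp <- grDevices::colorRamp(c("#0000b0", "#00b0ff", "#80ff80", "#ffb000",
                                 "#ff0000"))
  ramp(pmin(pmax(v, 0), 1)) / 255
}

#' Overlay a mask-cropped heatmap on the original image
#'
#' The heatmap is first cropped by the binary lung mask (elementwise
#' product), then alpha-blended over the grayscale image with a blue-to-red
#' colormap: pixels where the cropped heatmap is zero — in particular every
#' pixel outside the mask — render the original image unchanged.
#'
#' @param image H x W image on the 0-255 scale (or already on [0, 1]).
#' @param heatmap A [gradcam()] result or a bare H x W matrix in [0, 1].
#' @param mask H x W binary lung mask.
#' @param alpha Blend strength in [0, 1] (default 0.4).
#' @return (H, W, 3) RGB array in [0, 1].
#' @export
masked_cam_overlay <- function(image, heatmap, mask, alpha = 0.4) {
  hm <- if (inherits(heatmap, "heatmap")) heatmap$values else heatmap
  check_same_shape(image, hm, "image and heatmap")
  check_same_shape(image, mask, "image and mask")
  check_binary_mask(mask)
  if (alpha < 0 || alpha > 1) stopf("alpha must be in [0, 1]")
  gray <- if (max(image) > 1) image / 255 else image
  cropped <- hm * mask
  cm <- cam_colormap(as.vector(cropped))
  H <- nrow(image); W <- ncol(image)
  out <- array(0, c(H, W, 3))
  w <- alpha * cropped
  for (ch in 1:3) out[, , ch] <- (1 - w) * gray + w * matrix(cm[, ch], H, W)
  out
}

ERROR_CORRECT <- 0L
ERROR_MISSING <- 1L     # lung in truth, background in prediction (FN)
ERROR_ADDITIONAL <- 2L  # background in truth, lung in prediction (FP)

#' Segmentation error map
#'
#' Trinary difference between ground-truth and predicted masks: `missing`
#' where the truth has lung but the prediction does not (rendered black),
#' `additional` where the prediction has lung but the truth does not
#' (white), `correct` elsewhere (gray). Missing equals the FN count and
#' additional the FP count of [confusion_counts()] on the same pair.
#'
#' @param true_mask,pred_mask Binary H x W masks of identical shape.
#' @return An `error_map`: list with `map` (integer matrix; 0 correct,
#'   1 missing, 2 additional) and `counts` (named: missing, additional,
#'   correct; sums to H*W).
#' @export
error_map <- function(true_mask, pred_mask) {
  check_same_shape(true_mask, pred_mask, "masks")
  check_binary_mask(true_mask, "true mask")
  check_binary_mask(pred_mask, "pred mask")
  m <- matrix(ERROR_CORRECT, nrow(true_mask), ncol(true_mask))
  m[true_mask == 1 & pred_mask == 0] <- ERROR_MISSING
  m[true_mask == 0 & pred_mask == 1] <- ERROR_ADDITIONAL
  counts <- c(missing = sum(m == ERROR_MISSING),
              additional = sum(m == ERROR_ADDITIONAL),
              correct = sum(m == ERROR_CORRECT))
  structure(list(map = m, counts = counts), class = "error_map")
}

#' @export
print.error_map <- function(x, ...) {
  cat(sprintf("<error_map> %dx%d: %d missing (FN), %d additional (FP), %d correct\n",
              nrow(x$map), ncol(x$map), x$counts["missing"],
              x$counts["additional"], x$counts["correct"]))
  invisible(x)
}

# Render an error map as a grayscale raster: black missing, white
# additional, gray correct.
error_map_raster <- function(em) {
  r <- matrix(0.5, nrow(em$map), ncol(em$map))
  r[em$map == ERROR_MISSING] <- 0
  r[em$map == ERROR_ADDITIONAL] <- 1
  r
}

#' Write a multi-panel explanation figure
#'
#' Writes a PNG with the original image, the predicted lung mask, the
#' mask-cropped Grad-CAM overlay, and (when a true mask is supplied) the
#' error map.
#'
#' @param image H x W image on the 0-255 scale.
#' @param pred_mask Binary predicted mask.
#' @param overlay RGB overlay from [masked_cam_overlay()].
#' @param err Optional [error_map()] result.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_explanation_panel <- function(image, pred_mask, overlay, err = NULL, path) {
  n_panel <- if (is.null(err)) 3 else 4
  grDevices::png(path, width = 220 * n_panel, height = 240)
  op <- graphics::par(mfrow = c(1, n_panel), mar = c(0.5, 0.5, 2, 0.5))
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  show <- function(r, title) {
    graphics::plot.new()
    graphics::plot.window(c(0, 1), c(0, 1), asp = 1)
    graphics::rasterImage(r, 0, 0, 1, 1)
    graphics::title(title)
  }
  show(image / 255, "input")
  show(pred_mask * 1.0, "predicted mask")  # white = lung
  show(overlay, "masked Grad-CAM")
  if (!is.null(err)) show(error_map_raster(err), "error map")
  invisible(path)
}
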