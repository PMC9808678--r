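#' Training protocol
#'
#' Bundles every knob of the seeded batch-session training procedure. The
#' defaults are the full-scale protocol (sessions of 300 images, 6 sessions,
#' 200 epochs each, batch size 32, 20% test split, 10% of the remainder for
#' validation); [desk_protocol()] returns the small configuration used for
#' phantom experiments and tests.
#'
#' @param test_fraction Fraction of the dataset held out for testing.
#' @param val_fraction Fraction of the post-training-selection remainder used
#'   for validation.
#' @param session_size Images drawn (without replacement) per training session.
#' @param n_sessions Number of training sessions.
#' @param epochs_per_session Epochs per session.
#' @param batch_size Minibatch size.
#' @param seed Master seed for splits, session draws, shuffles and weight init.
#' @param loss_weights `(w_seg, w_cls)` weights of the combined loss; both
#'   non-negative, not both zero.
#' @param learning_rate Adam learning rate.
#' @param train_count Optional fixed training-set size (the classification
#'   split mode); `NULL` means use the whole post-validation remainder.
#' @return A `training_protocol` object.
#' @export
training_protocol <- function(test_fraction = 0.2, val_fraction = 0.1,
                              session_size = 300, n_sessions = 6,
                              epochs_per_session = 200, batch_size = 32,
                              seed = 1, loss_weights = c(1, 1),
                              learning_rate = 1e-3, train_count = NULL) {
  if (test_fraction <= 0 || test_fraction >= 1) stopf("test_fraction must be in (0, 1)")
  if (val_fraction <= 0 || val_fraction >= 1) stopf("val_fraction must be in (0, 1)")
  if (session_size < 1 || n_sessions < 1 || epochs_per_session < 1 || batch_size < 1)
    stopf("session/epoch/batch counts must be positive integers")
  if (length(loss_weights) != 2 || any(loss_weights < 0) || sum(loss_weights) == 0)
    stopf("loss_weights must be two non-negative numbers, not both zero")
  structure(list(test_fraction = test_fraction, val_fraction = val_fraction,
                 session_size = as.integer(session_size),
                 n_sessions = as.integer(n_sessions),
                 epochs_per_session = as.integer(epochs_per_session),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 loss_weights = loss_weights,
                 learning_rate = learning_rate,
                 train_count = if (is.null(train_count)) NULL else as.integer(train_count)),
            class = "training_protocol")
}

#' @rdname training_protocol
#' @param ... Overrides passed on to [training_protocol()].
#' @export
desk_protocol <- function(...) {
  args <- list(test_fraction = 0.16, val_fraction = 0.05, session_size = 300,
               n_sessions = 3, epochs_per_session = 5, batch_size = 32)
  over <- list(...)
  args[names(over)] <- over
  do.call(training_protocol, args)
}

#' Seeded train/validation/test split
#'
#' Draws a seeded permutation of `1:n` and carves it into disjoint test,
#' train and validation index sets. The test set has `floor(n *
#' test_fraction)` elements. In segmentation mode (no `train_count`), the
#' validation set is `floor(remainder * val_fraction)` of the remaining pool
#' and the training set is everything else. In classification mode
#' (`train_count` set), `train_count` images are taken from the remainder
#' first and the validation fraction is applied to what is left after that.
#'
#' @param n Dataset size (>= 10).
#' @param protocol A [training_protocol()].
#' @return A `split_indices` object: list of integer vectors `train`, `val`,
#'   `test` (pairwise disjoint), plus `unused` in classification mode.
#' @examples
#' p <- training_protocol(seed = 1)
#' sp <- split_dataset(21165, p)
#' length(sp$test)  # 4233
#' @export
split_dataset <- function(n, protocol) {
  if (n < 10) stopf("split_dataset needs n >= 10, got %d", n)
  n_test <- floor(n * protocol$test_fraction)
  perm <- with_seed(protocol$seed, sample.int(n))
  test <- sort(perm[seq_len(n_test)])
  remainder <- perm[(n_test + 1):n]
  if (!is.null(protocol$train_count)) {
    if (protocol$train_count >= length(remainder))
      stopf("train_count %d leaves no validation pool (remainder %d)",
            protocol$train_count, length(remainder))
    train <- sort(remainder[seq_len(protocol$train_count)])
    pool <- remainder[(protocol$train_count + 1):length(remainder)]
    n_val <- floor(length(pool) * protocol$val_fraction)
    val <- if (n_val > 0) sort(pool[seq_len(n_val)]) else integer(0)
    unused <- sort(setdiff(pool, val))
  } else {
    n_val <- floor(length(remainder) * protocol$val_fraction)
    val <- if (n_val > 0) sort(remainder[seq_len(n_val)]) else integer(0)
    train <- sort(remainder[setdiff(seq_along(remainder), seq_len(n_val))])
    unused <- integer(0)
  }
  if (length(train) == 0) stopf("split leaves an empty training set")
  if (length(val) == 0)
    warning("validation set is empty at this n and val_fraction", call. = FALSE)
  structure(list(train = train, val = val, test = test, unused = unused,
                 n = n), class = "split_indices")
}

#' Combined segmentation + classification loss
#'
#' `w_seg` times the per-pixel sparse categorical cross-entropy of the
#' segmentation output plus `w_cls` times the sparse categorical
#' cross-entropy of the classification output. With weights `(1, 0)` it
#' reduces to the pure segmentation loss.
#'
#' @param seg_probs (H, W, C) or (H, W, C, N) per-pixel class probabilities.
#' @param true_mask (H, W) or (H, W, N) integer label mask.
#' @param cls_probs Class probabilities: length-C vector or (C, N) columns.
#' @param true_label Integer labels in `0:(C-1)`.
#' @param weights `(w_seg, w_cls)`, non-negative, not both zero.
#' @return List with `total`, `seg` and `cls` loss components
#'   (`total = w_seg * seg + w_cls * cls`).
#' @export
combined_loss <- function(seg_probs, true_mask, cls_probs, true_label,
                          weights = c(1, 1)) {
  if (length(weights) != 2 || any(weights < 0) || sum(weights) == 0)
    stopf("weights must be two non-negative numbers, not both zero")
  seg <- seg_scce(seg_probs, true_mask)
  if (is.null(dim(cls_probs))) cls_probs <- matrix(cls_probs, ncol = 1)
  cls <- sparse_categorical_cross_entropy(true_label, t(cls_probs))
  list(total = weights[1] * seg + weights[2] * cls, seg = seg, cls = cls)
}

adam_init <- function(params) {
  list(m = lapply(params, function(x) { x[] <- 0; x }),
       v = lapply(params, function(x) { x[] <- 0; x }),
       t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Convert a list of phantom samples into model-input tensors.
samples_to_tensors <- function(samples) {
  H <- nrow(samples[[1]]$image); W <- ncol(samples[[1]]$image)
  n <- length(samples)
  x <- array(0, c(H, W, 1, n))
  masks <- array(0L, c(H, W, n))
  labels <- integer(n)
  for (i in seq_len(n)) {
    x[, , 1, i] <- rescale_image(samples[[i]]$image)
    masks[, , i] <- samples[[i]]$mask
    labels[i] <- samples[[i]]$label
  }
  list(x = x, masks = masks, labels = labels, H = H, W = W, n = n)
}

# Gradient of the combined loss at the two logit tensors: softmax minus
# one-hot, averaged and weighted.
loss_logit_grads <- function(seg_probs, masks, cls_probs, labels, weights) {
  d <- dim(seg_probs)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  HW <- H * W
  g_seg <- seg_probs
  for (n in seq_len(N)) {
    lin <- seq_len(HW) + HW * as.vector(masks[, , n]) + HW * C * (n - 1)
    g_seg[lin] <- g_seg[lin] - 1
  }
  g_seg <- g_seg * (weights[1] / (HW * N))
  g_cls <- cls_probs
  g_cls[cbind(labels + 1L, seq_len(N))] <- g_cls[cbind(labels + 1L, seq_len(N))] - 1
  g_cls <- g_cls * (weights[2] / N)
  list(seg = g_seg, cls = g_cls)
}

# Evaluation-mode losses and quick metrics over an index set.
eval_metrics <- function(model, tensors, idx, weights, batch_size = 32) {
  if (length(idx) == 0)
    return(list(total = NA_real_, seg = NA_real_, cls = NA_real_,
                dice = NA_real_, cls_accuracy = NA_real_))
  seg_sum <- 0; cls_sum <- 0
  tp <- 0; fp <- 0; fn <- 0; n_correct <- 0
  for (start in seq(1, length(idx), by = batch_size)) {
    ii <- idx[start:min(start + batch_size - 1, length(idx))]
    fw <- munet_forward(model, tensors$x[, , , ii, drop = FALSE], training = FALSE)
    m <- tensors$masks[, , ii, drop = FALSE]
    seg_sum <- seg_sum + seg_scce(fw$seg_probs, m) * length(ii)
    cls_sum <- cls_sum +
      sparse_categorical_cross_entropy(tensors$labels[ii], t(fw$cls_probs)) * length(ii)
    pred <- binarize_mask(fw$seg_probs)
    dim(pred) <- dim(m)
    tp <- tp + sum(pred == 1 & m == 1)
    fp <- fp + sum(pred == 1 & m == 0)
    fn <- fn + sum(pred == 0 & m == 1)
    n_correct <- n_correct + sum(max.col(t(fw$cls_probs)) - 1L == tensors$labels[ii])
  }
  seg <- seg_sum / length(idx); cls <- cls_sum / length(idx)
  dice <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 1
  list(total = weights[1] * seg + weights[2] * cls, seg = seg, cls = cls,
       dice = dice, cls_accuracy = n_correct / length(idx))
}

#' Train a multi-output U-Net with the batch-session protocol
#'
#' Runs `n_sessions` training sessions. Each session draws `session_size`
#' images from the training split (seeded, without replacement within the
#' session; sessions may re-draw the same images) and trains for
#' `epochs_per_session` epochs of minibatch Adam on the combined loss. After
#' every epoch the validation total loss is evaluated in inference mode and
#' the best weights (minimum validation total loss) are checkpointed; the
#' returned model carries those best weights.
#'
#' @param model A `munet_model` (its config must match the image size).
#' @param dataset A `phantom_dataset`, or a bare list of samples with
#'   `image` / `mask` / `label` fields.
#' @param protocol A [training_protocol()].
#' @param split Optional [split_dataset()] result; computed from the
#'   protocol if omitted.
#' @param verbose Print a line per epoch.
#' @return A `munet_fit`: list with `model` (best checkpoint), `final_model`,
#'   `history` (tibble, one row per epoch), `checkpoint_epoch` (0-based row
#'   index of the best epoch), `split`, `protocol`.
#' @export
train_munet <- function(model, dataset, protocol, split = NULL, verbose = FALSE) {
  samples <- if (inherits(dataset, "phantom_dataset")) dataset$samples else dataset
  tensors <- samples_to_tensors(samples)
  if (tensors$H != model$config$input_size[1] || tensors$W != model$config$input_size[2])
    stopf("dataset images are %dx%d but the model expects %dx%d",
          tensors$H, tensors$W, model$config$input_size[1], model$config$input_size[2])
  if (is.null(split)) split <- split_dataset(tensors$n, protocol)
  w <- protocol$loss_weights
  opt <- adam_init(model$params)
  hist_rows <- list()
  best <- list(loss = Inf, params = model$params, bn = model$bn, epoch = 0L)
  epoch_global <- 0L

  for (s in seq_len(protocol$n_sessions)) {
    ssize <- protocol$session_size
    if (ssize > length(split$train)) {
      warning(sprintf("session_size %d exceeds training pool %d; clamped",
                      ssize, length(split$train)), call. = FALSE)
      ssize <- length(split$train)
    }
    session_idx <- with_seed(derive_seed(protocol$seed, 1000 + s),
                             sample(split$train, ssize))
    for (e in seq_len(protocol$epochs_per_session)) {
      ord <- with_seed(derive_seed(protocol$seed, 1000000 + 1000 * s + e),
                       sample(session_idx))
      seg_sum <- 0; cls_sum <- 0; nseen <- 0
      tp <- 0; fp <- 0; fn <- 0; n_correct <- 0
      for (start in seq(1, length(ord), by = protocol$batch_size)) {
        bi <- ord[start:min(start + protocol$batch_size - 1, length(ord))]
        xb <- tensors$x[, , , bi, drop = FALSE]
        mb <- tensors$masks[, , bi, drop = FALSE]
        lb <- tensors$labels[bi]
        fw <- munet_forward(model, xb, training = TRUE)
        model$bn[names(fw$new_bn)] <- fw$new_bn
        seg_l <- seg_scce(fw$seg_probs, mb)
        cls_l <- sparse_categorical_cross_entropy(lb, t(fw$cls_probs))
        if (!is.finite(seg_l) || !is.finite(cls_l))
          stopf("non-finite loss at session %d epoch %d (seg %.4g, cls %.4g); aborting",
                s, e, seg_l, cls_l)
        seg_sum <- seg_sum + seg_l * length(bi)
        cls_sum <- cls_sum + cls_l * length(bi)
        nseen <- nseen + length(bi)
        pred <- binarize_mask(fw$seg_probs)
        dim(pred) <- dim(mb)
        tp <- tp + sum(pred == 1 & mb == 1)
        fp <- fp + sum(pred == 1 & mb == 0)
        fn <- fn + sum(pred == 0 & mb == 1)
        n_correct <- n_correct + sum(max.col(t(fw$cls_probs)) - 1L == lb)
        lg <- loss_logit_grads(fw$seg_probs, mb, fw$cls_probs, lb, w)
        grads <- munet_backward(model, fw, lg$seg, lg$cls)
        upd <- adam_step(model$params, grads, opt, protocol$learning_rate)
        model$params <- upd$params
        opt <- upd$state
      }
      epoch_global <- epoch_global + 1L
      train_seg <- seg_sum / nseen
      train_cls <- cls_sum / nseen
      vm <- eval_metrics(model, tensors, split$val, w, protocol$batch_size)
      monitored <- if (is.na(vm$total)) w[1] * train_seg + w[2] * train_cls else vm$total
      if (monitored < best$loss) {
        best <- list(loss = monitored, params = model$params, bn = model$bn,
                     epoch = epoch_global - 1L)
      }
      hist_rows[[epoch_global]] <- tibble::tibble(
        epoch = epoch_global, session = s,
        train_total = w[1] * train_seg + w[2] * train_cls,
        train_seg = train_seg, train_cls = train_cls,
        train_dice = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 1,
        train_cls_accuracy = n_correct / nseen,
        val_total = vm$total, val_seg = vm$seg, val_cls = vm$cls,
        val_dice = vm$dice, val_cls_accuracy = vm$cls_accuracy)
      if (verbose)
        message(sprintf("session %d epoch %d: train %.4f val %.4f dice %.4f acc %.3f",
                        s, e, hist_rows[[epoch_global]]$train_total,
                        vm$total, vm$dice, vm$cls_accuracy))
    }
  }
  best_model <- structure(list(config = model$config, params = best$params,
                               bn = best$bn), class = "munet_model")
  structure(list(model = best_model, final_model = model,
                 history = do.call(rbind, hist_rows),
                 checkpoint_epoch = best$epoch,
                 split = split, protocol = protocol),
            class = "munet_fit")
}

#' @export
print.munet_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("<munet_fit> %d epochs; checkpoint at epoch %d (val loss %.4f)\n",
              nrow(h), x$checkpoint_epoch, min(h$val_total, na.rm = TRUE)))
  cat(sprintf("  last epoch: val dice %.4f, val classification accuracy %.4f\n",
              h$val_dice[nrow(h)], h$val_cls_accuracy[nrow(h)]))
  invisible(x)
}

#' Evaluate a trained model on a test set
#'
#' Computes per-image segmentation metrics (Dice coefficient and loss, IoU,
#' pixel accuracy, per-pixel SCCE), their aggregate means and standard
#' deviations, and the classification accuracy, confusion matrix, per-class
#' recall and SCCE.
#'
#' @param model A `munet_model` (typically `fit$model`).
#' @param samples List of samples with `image` (0-255), `mask`, `label`.
#' @param class_names Optional class names for the confusion matrix.
#' @return A `munet_evaluation`: list with `per_image` (tibble), `aggregate`
#'   (named list of means/sds), `cls_accuracy`, `cls_confusion` (true x
#'   predicted), `per_class_recall`, `cls_scce`.
#' @export
evaluate_munet <- function(model, samples, class_names = NULL) {
  if (inherits(samples, "phantom_dataset")) {
    if (is.null(class_names)) class_names <- samples$class_names
    samples <- samples$samples
  }
  if (length(samples) == 0) stopf("test set must be nonempty")
  tensors <- samples_to_tensors(samples)
  pr <- predict(model, tensors$x)
  C <- model$config$cls_classes
  if (is.null(class_names)) class_names <- paste0("class_", seq_len(C) - 1)
  n <- tensors$n
  rows <- vector("list", n)
  conf <- matrix(0L, C, C, dimnames = list(true = class_names, pred = class_names))
  pred_lab <- max.col(t(pr$cls_probs)) - 1L
  for (i in seq_len(n)) {
    pm <- binarize_mask(pr$seg_probs[, , , i, drop = FALSE])
    dim(pm) <- dim(tensors$masks[, , i])
    cc <- confusion_counts(pm, tensors$masks[, , i])
    dsc <- dice_coefficient(cc)
    rows[[i]] <- tibble::tibble(
      sample = i,
      dice = as.numeric(dsc), dice_loss = dice_loss(dsc),
      iou = as.numeric(iou(cc)), pixel_accuracy = pixel_accuracy(cc),
      seg_scce = seg_scce(pr$seg_probs[, , , i, drop = FALSE], tensors$masks[, , i]),
      empty_union = isTRUE(attr(dsc, "empty_union")),
      true_label = tensors$labels[i], pred_label = pred_lab[i])
    conf[tensors$labels[i] + 1L, pred_lab[i] + 1L] <-
      conf[tensors$labels[i] + 1L, pred_lab[i] + 1L] + 1L
  }
  per_image <- do.call(rbind, rows)
  agg <- list()
  for (col in c("dice", "dice_loss", "iou", "pixel_accuracy", "seg_scce")) {
    agg[[paste0("mean_", col)]] <- mean(per_image[[col]])
    agg[[paste0("sd_", col)]] <- sd(per_image[[col]])
  }
  recall <- vapply(seq_len(C), function(k) {
    tot <- sum(conf[k, ])
    if (tot == 0) NA_real_ else conf[k, k] / tot
  }, numeric(1))
  names(recall) <- class_names
  structure(list(per_image = per_image, aggregate = agg,
                 cls_accuracy = mean(pred_lab == tensors$labels),
                 cls_confusion = conf, per_class_recall = recall,
                 cls_scce = sparse_categorical_cross_entropy(tensors$labels,
                                                             t(pr$cls_probs))),
            class = "munet_evaluation")
}

#' @export
print.munet_evaluation <- function(x, ...) {
  cat(sprintf("<munet_evaluation> %d images\n", nrow(x$per_image)))
  cat(sprintf("  mean dice %.4f (dice loss %.4f), mean IoU %.4f, mean pixel accuracy %.4f\n",
              x$aggregate$mean_dice, x$aggregate$mean_dice_loss,
              x$aggregate$mean_iou, x$aggregate$mean_pixel_accuracy))
  cat(sprintf("  classification accuracy %.4f, SCCE %.4f\n",
              x$cls_accuracy, x$cls_scce))
  invisible(x)
}

#' Sweep encoder depth and base filter count
#'
#' Trains and evaluates one model per `(E, F)` combination on identical
#' splits, reporting the test dice loss, segmentation SCCE and pixel
#' accuracy per row. Combinations invalid for the image size are skipped
#' with a message.
#'
#' @param E_list Encoder depths to try.
#' @param F_list Base filter counts to try.
#' @param dataset A `phantom_dataset`.
#' @param protocol A [training_protocol()].
#' @param csv_path Optional path; when given the table is also written as CSV.
#' @return Tibble with columns `E`, `F`, `dice`, `dice_loss`, `scce`,
#'   `accuracy`, `cls_accuracy`.
#' @export
hyperparameter_sweep <- function(E_list, F_list, dataset, protocol,
                                 csv_path = NULL) {
  samples <- dataset$samples
  H <- nrow(samples[[1]]$image); W <- ncol(samples[[1]]$image)
  n_cls <- length(dataset$class_names)
  split <- split_dataset(length(samples), protocol)
  rows <- list()
  for (E in E_list) for (F in F_list) {
    ok <- tryCatch({
      cfg <- architecture_config(depth_E = E, base_filters_F = F,
                                 input_size = c(H, W), cls_classes = n_cls)
      TRUE
    }, error = function(e) {
      message(sprintf("skipping E=%d F=%d: %s", E, F, conditionMessage(e)))
      FALSE
    })
    if (!ok) next
    model <- build_multi_output_unet(cfg, seed = derive_seed(protocol$seed, 7000 + 100 * E + F))
    fit <- train_munet(model, dataset, protocol, split = split)
    ev <- evaluate_munet(fit$model, samples[split$test], dataset$class_names)
    rows[[length(rows) + 1]] <- tibble::tibble(
      E = E, F = F,
      dice = ev$aggregate$mean_dice,
      dice_loss = ev$aggregate$mean_dice_loss,
      scce = ev$aggregate$mean_seg_scce,
      accuracy = ev$aggregate$mean_pixel_accuracy,
      cls_accuracy = ev$cls_accuracy)
  }
  out <- do.call(rbind, rows)
  if (!is.null(csv_path)) write.csv(out, csv_path, row.names = FALSE)
  out
}

#' Compare decoder activation functions
#'
#' Trains one model per activation under identical splits, seeds and weight
#' initialization, and returns the per-epoch training/validation curves.
#'
#' @param activations Subset of `c("relu", "leaky_relu", "elu")`.
#' @param dataset A `phantom_dataset`.
#' @param protocol A [training_protocol()].
#' @param out_dir Optional directory; per-activation curve CSVs
#'   (`curves_<activation>.csv`) are written there.
#' @return Named list of `munet_fit` objects, with a `curves` attribute
#'   holding the combined tibble (columns of the history plus `activation`).
#' @export
compare_activations <- function(activations, dataset, protocol, out_dir = NULL) {
  stopifnot(all(activations %in% c("relu", "leaky_relu", "elu")))
  samples <- dataset$samples
  H <- nrow(samples[[1]]$image); W <- ncol(samples[[1]]$image)
  n_cls <- length(dataset$class_names)
  split <- split_dataset(length(samples), protocol)
  fits <- list()
  curves <- list()
  for (act in activations) {
    cfg <- architecture_config(depth_E = 3, base_filters_F = 8,
                               input_size = c(H, W), cls_classes = n_cls,
                               decoder_activation = act)
    model <- build_multi_output_unet(cfg, seed = derive_seed(protocol$seed, 9001))
    fit <- train_munet(model, dataset, protocol, split = split)
    fits[[act]] <- fit
    cv <- fit$history
    cv$activation <- act
    curves[[act]] <- cv
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write.csv(fit$history, file.path(out_dir, paste0("curves_", act, ".csv")),
                row.names = FALSE)
    }
  }
  attr(fits, "curves") <- do.call(rbind, curves)
  fits
}
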