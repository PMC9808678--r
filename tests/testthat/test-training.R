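test_that("split arithmetic reproduces the documented counts", {
  p <- training_protocol(test_fraction = 0.2, val_fraction = 0.1, seed = 1)
  sp <- split_dataset(21165, p)
  expect_identical(length(sp$test), 4233L)
  expect_identical(length(sp$val) + length(sp$train), 21165L - 4233L)
  # classification mode: fixed 10,000 training images, 10% of the leftover
  pc <- training_protocol(test_fraction = 0.2, val_fraction = 0.1, seed = 1,
                          train_count = 10000)
  spc <- split_dataset(21165, pc)
  expect_identical(length(spc$train), 10000L)
  expect_identical(length(spc$val), 693L)
})

test_that("splits are deterministic, disjoint and warn on empty validation", {
  set.seed(77)
  for (k in 1:30) {
    n <- sample(10:500, 1)
    p <- training_protocol(seed = sample(1e6, 1))
    sp1 <- suppressWarnings(split_dataset(n, p))
    sp2 <- suppressWarnings(split_dataset(n, p))
    expect_identical(sp1, sp2)
    all_idx <- c(sp1$train, sp1$val, sp1$test, sp1$unused)
    expect_identical(sort(all_idx), seq_len(n))
    expect_identical(anyDuplicated(all_idx), 0L)
  }
  expect_warning(split_dataset(10, training_protocol(seed = 1)),
                 "validation set is empty")
  expect_identical(length(suppressWarnings(
    split_dataset(10, training_protocol(seed = 1)))$val), 0L)
})

test_that("the combined loss degenerates correctly and decomposes linearly", {
  set.seed(12)
  H <- 8; W <- 8
  probs <- array(runif(H * W * 2), c(H, W, 2, 1))
  probs[, , 2, ] <- 1 - probs[, , 1, ]
  mask <- matrix(rbinom(H * W, 1, 0.4), H, W)
  cls <- c(0.1, 0.7, 0.2)
  seg_only <- combined_loss(probs, mask, cls, 1L, weights = c(1, 0))
  cls_only <- combined_loss(probs, mask, cls, 1L, weights = c(0, 1))
  both <- combined_loss(probs, mask, cls, 1L, weights = c(2, 3))
  expect_equal(seg_only$total, seg_only$seg)
  expect_equal(cls_only$total, cls_only$cls)
  expect_equal(cls_only$cls, -log(0.7))
  expect_equal(both$total, 2 * both$seg + 3 * both$cls)
  expect_error(combined_loss(probs, mask, cls, 1L, weights = c(0, 0)),
               "not both zero")
  # both heads perfect: bounded by the two clipped logs
  perfect <- array(0, c(H, W, 2, 1))
  perfect[, , 1, ][mask == 0] <- 1
  perfect[, , 2, ][mask == 1] <- 1
  expect_lte(combined_loss(perfect, mask, c(0, 1, 0), 1L)$total, 2.4e-7)
})

test_that("single-epoch training keeps honest books", {
  ts <- tiny_setup(n = 20, seed = 3)
  m <- build_multi_output_unet(ts$cfg, seed = 1)
  fit <- train_munet(m, ts$ds, tiny_protocol())
  expect_identical(nrow(fit$history), 1L)
  expect_identical(fit$checkpoint_epoch, 0L)
  expect_true(all(c("train_total", "val_total", "val_dice") %in% names(fit$history)))
})

test_that("training is deterministic under a fixed seed", {
  ts <- tiny_setup(n = 20, seed = 3)
  proto <- tiny_protocol(n_sessions = 1, epochs_per_session = 2)
  f1 <- train_munet(build_multi_output_unet(ts$cfg, seed = 1), ts$ds, proto)
  f2 <- train_munet(build_multi_output_unet(ts$cfg, seed = 1), ts$ds, proto)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("history total loss decomposes into weighted components", {
  ts <- tiny_setup(n = 20, seed = 4)
  proto <- tiny_protocol(n_sessions = 2, epochs_per_session = 2,
                         loss_weights = c(1.5, 0.5))
  fit <- train_munet(build_multi_output_unet(ts$cfg, seed = 2), ts$ds, proto)
  h <- fit$history
  expect_equal(h$train_total, 1.5 * h$train_seg + 0.5 * h$train_cls,
               tolerance = 1e-6)
  expect_equal(h$val_total, 1.5 * h$val_seg + 0.5 * h$val_cls, tolerance = 1e-6)
})

test_that("the checkpoint reproduces the history's minimum validation loss", {
  ts <- tiny_setup(n = 24, seed = 6)
  proto <- tiny_protocol(n_sessions = 2, epochs_per_session = 3)
  fit <- train_munet(build_multi_output_unet(ts$cfg, seed = 5), ts$ds, proto)
  h <- fit$history
  expect_identical(fit$checkpoint_epoch, which.min(h$val_total) - 1L)
  tensors <- munet:::samples_to_tensors(ts$ds$samples)
  re <- munet:::eval_metrics(fit$model, tensors, fit$split$val,
                             proto$loss_weights)
  expect_equal(re$total, min(h$val_total), tolerance = 1e-6)
})

test_that("session size larger than the training pool is clamped with a warning", {
  ts <- tiny_setup(n = 20, seed = 7)
  proto <- tiny_protocol(session_size = 500)
  expect_warning(train_munet(build_multi_output_unet(ts$cfg, seed = 1),
                             ts$ds, proto),
                 "clamped")
})

test_that("evaluation reports are internally consistent", {
  ts <- tiny_setup(n = 12, seed = 8, n_classes = 3)
  m <- build_multi_output_unet(
    architecture_config(depth_E = 2, base_filters_F = 4, input_size = c(32, 32),
                        cls_classes = 3), seed = 4)
  ev <- evaluate_munet(m, ts$ds$samples, ts$ds$class_names)
  expect_identical(nrow(ev$per_image), 12L)
  expect_equal(ev$per_image$dice_loss, 1 - ev$per_image$dice)
  expect_equal(ev$aggregate$mean_dice, mean(ev$per_image$dice))
  expect_identical(sum(ev$cls_confusion), 12L)
  expect_equal(ev$cls_accuracy, sum(diag(ev$cls_confusion)) / 12)
  # all metrics bounded
  for (col in c("dice", "dice_loss", "iou", "pixel_accuracy"))
    expect_true(all(ev$per_image[[col]] >= 0 & ev$per_image[[col]] <= 1))
  expect_error(evaluate_munet(m, list()), "nonempty")
})

test_that("the hyperparameter sweep shares splits and reports complements", {
  ds <- generate_dataset(24, class_proportions = rep(0.5, 2), size = c(32, 32),
                         seed = 10)
  proto <- tiny_protocol(session_size = 10)
  tab <- hyperparameter_sweep(c(2), c(4, 8), ds, proto)
  expect_identical(nrow(tab), 2L)
  expect_equal(tab$dice_loss, 1 - tab$dice)
  tab2 <- hyperparameter_sweep(c(2), c(4, 8), ds, proto)
  expect_equal(tab, tab2)
  # invalid combination is skipped with a message
  expect_message(
    tab3 <- hyperparameter_sweep(c(2, 6), c(4), ds, proto),
    "skipping E=6")
  expect_identical(nrow(tab3), 1L)
})

test_that("activation comparison yields aligned, reproducible curves", {
  ds <- generate_dataset(24, class_proportions = rep(0.5, 2), size = c(32, 32),
                         seed = 10)
  proto <- tiny_protocol(session_size = 10, n_sessions = 1,
                         epochs_per_session = 2)
  out <- withr::local_tempdir()
  fits <- compare_activations(c("relu", "elu"), ds, proto, out_dir = out)
  curves <- attr(fits, "curves")
  expect_identical(sort(unique(curves$activation)), c("elu", "relu"))
  expect_identical(nrow(curves), 4L)  # 2 activations x 2 epochs
  expect_identical(curves$epoch[curves$activation == "relu"],
                   curves$epoch[curves$activation == "elu"])
  expect_true(all(file.exists(file.path(out, c("curves_relu.csv", "curves_elu.csv")))))
  fits2 <- compare_activations(c("relu", "elu"), ds, proto)
  expect_identical(attr(fits, "curves")$train_total,
                   attr(fits2, "curves")$train_total)
})
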