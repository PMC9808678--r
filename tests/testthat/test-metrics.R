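test_that("rescaling divides by the image maximum with a defined zero case", {
  expect_equal(rescale_image(c(0, 51, 255)), c(0, 0.2, 1.0))
  expect_equal(rescale_image(matrix(0, 4, 4)), matrix(0, 4, 4))
  expect_equal(rescale_image(matrix(200, 3, 3)), matrix(1, 3, 3))
  x <- matrix(c(10, 20, 40, 80), 2, 2)
  expect_equal(max(rescale_image(x)), 1)
  expect_error(rescale_image(c(-1, 2)), "non-negative")
})

test_that("confusion counts enumerate the four pixel outcomes", {
  cc <- confusion_counts(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_identical(unclass(cc)[c("TP", "FP", "FN", "TN")],
                   list(TP = 1L, FP = 1L, FN = 1L, TN = 1L))
  m <- matrix(rbinom(64, 1, 0.4), 8, 8)
  id <- confusion_counts(m, m)
  expect_identical(id$FP + id$FN, 0L)
  comp <- confusion_counts(1 - m, m)
  expect_identical(comp$TP + comp$TN, 0L)
  expect_identical(cc$TP + cc$TN + cc$FP + cc$FN, 4L)
  expect_error(confusion_counts(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
  expect_error(confusion_counts(matrix(2, 2, 2), matrix(0, 2, 2)), "0 and 1")
})

test_that("dice, IoU and accuracy follow their closed forms and identities", {
  cc <- list(TP = 1, TN = 1, FP = 1, FN = 1)
  expect_equal(dice_coefficient(cc), 0.5, ignore_attr = TRUE)
  expect_equal(iou(cc), 1 / 3, ignore_attr = TRUE)
  expect_equal(pixel_accuracy(cc), 0.5)
  # DSC = 2J / (1 + J) exactly, on randomized count tuples
  set.seed(17)
  for (k in 1:50) {
    counts <- list(TP = sample(0:20, 1), TN = sample(0:20, 1),
                   FP = sample(0:20, 1), FN = sample(0:20, 1))
    if (2 * counts$TP + counts$FP + counts$FN == 0) next
    J <- as.numeric(iou(counts))
    expect_equal(as.numeric(dice_coefficient(counts)), 2 * J / (1 + J))
  }
  # disjoint positives
  expect_equal(as.numeric(dice_coefficient(list(TP = 0, TN = 0, FP = 3, FN = 2))), 0)
  # empty union convention: 1 with audit flag
  empty <- dice_coefficient(list(TP = 0, TN = 9, FP = 0, FN = 0))
  expect_equal(as.numeric(empty), 1)
  expect_true(attr(empty, "empty_union"))
  expect_true(attr(iou(list(TP = 0, TN = 9, FP = 0, FN = 0)), "empty_union"))
})

test_that("metrics are symmetric in the two masks", {
  set.seed(31)
  for (k in 1:20) {
    a <- matrix(rbinom(64, 1, 0.4), 8, 8)
    b <- matrix(rbinom(64, 1, 0.4), 8, 8)
    expect_equal(as.numeric(dice_coefficient(confusion_counts(a, b))),
                 as.numeric(dice_coefficient(confusion_counts(b, a))))
    expect_equal(as.numeric(iou(confusion_counts(a, b))),
                 as.numeric(iou(confusion_counts(b, a))))
    expect_equal(pixel_accuracy(confusion_counts(a, b)),
                 pixel_accuracy(confusion_counts(b, a)))
  }
})

test_that("dice loss is the exact complement of the dice coefficient", {
  expect_equal(dice_loss(0.9691), 0.0309)
  expect_equal(dice_loss(1.0), 0.0)
  expect_equal(dice_loss(0.0), 1.0)
  set.seed(5)
  d <- runif(20)
  expect_equal(dice_loss(d) + d, rep(1, 20))
  expect_error(dice_loss(1.2), "\\[0, 1\\]")
})

test_that("sparse categorical cross-entropy matches hand-computed values", {
  # perfect one-hot predictions: bounded by the clipping constant
  onehot <- diag(4)[c(1, 3), ]
  expect_lte(sparse_categorical_cross_entropy(c(0, 2), onehot), 1.2e-7)
  # uniform over 4 classes
  expect_equal(sparse_categorical_cross_entropy(0:3, matrix(0.25, 4, 4)), log(4))
  # n = 2 with true-class probabilities 0.5 and 0.25
  yh <- rbind(c(0.5, 0.5, 0, 0), c(0.25, 0.25, 0.25, 0.25))
  expect_equal(sparse_categorical_cross_entropy(c(0, 1), yh),
               (log(2) + log(4)) / 2)
  expect_error(sparse_categorical_cross_entropy(c(0, 4), matrix(0.25, 2, 4)),
               "labels")
  expect_error(sparse_categorical_cross_entropy(0, c(0.3, 0.3)), "sum to 1")
})

test_that("metrics agree with the double-loop oracle on random mask pairs", {
  set.seed(19)
  for (k in 1:50) {
    pred <- matrix(rbinom(256, 1, runif(1, 0.1, 0.9)), 16, 16)
    true <- matrix(rbinom(256, 1, runif(1, 0.1, 0.9)), 16, 16)
    o <- oracle_seg_metrics(pred, true)
    cc <- confusion_counts(pred, true)
    expect_equal(as.numeric(dice_coefficient(cc)), o$dice, tolerance = 1e-12)
    expect_equal(as.numeric(iou(cc)), o$iou, tolerance = 1e-12)
    expect_equal(pixel_accuracy(cc), o$accuracy, tolerance = 1e-12)
  }
})
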