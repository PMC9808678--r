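test_that("encoder filter schedule doubles from the base filter count", {
  expect_identical(encoder_filter_schedule(
    architecture_config(depth_E = 5, base_filters_F = 16, input_size = c(256, 256))),
    c(16L, 32L, 64L, 128L, 256L))
  expect_identical(encoder_filter_schedule(
    architecture_config(depth_E = 3, base_filters_F = 64, input_size = c(64, 64))),
    c(64L, 128L, 256L))
  expect_identical(encoder_filter_schedule(
    architecture_config(depth_E = 2, base_filters_F = 4, input_size = c(32, 32))),
    c(4L, 8L))
})

test_that("activation functions follow their closed forms", {
  expect_equal(activation("relu", -3), 0)
  expect_equal(activation("relu", 2), 2)
  expect_equal(activation("leaky_relu", -10, alpha = 0.1), -1)
  expect_equal(activation("leaky_relu", 5, alpha = 0.1), 5)
  expect_equal(activation("elu", -1, alpha = 1), exp(-1) - 1)
  expect_equal(activation("elu", 3, alpha = 1), 3)
  expect_error(activation("swish", 1), "unknown activation")
})

test_that("configuration validation happens before any allocation", {
  expect_error(architecture_config(depth_E = 3, base_filters_F = 8,
                                   input_size = c(60, 60)), "divisible")
  expect_error(architecture_config(depth_E = 5, base_filters_F = 8,
                                   input_size = c(32, 32)), "bottleneck")
  expect_error(architecture_config(depth_E = 3, base_filters_F = 8,
                                   input_size = c(64, 64), dense_units = c(64, 32, 5)),
               "cls_classes")
})

test_that("forward pass honours the shape and softmax contracts", {
  set.seed(2)
  for (E in 2:3) {
    cfg <- architecture_config(depth_E = E, base_filters_F = 4,
                               input_size = c(32, 32), cls_classes = 4)
    m <- build_multi_output_unet(cfg, seed = 10 + E)
    x <- array(runif(32 * 32 * 3), c(32, 32, 3))
    out <- predict(m, x)
    expect_identical(dim(out$seg_probs), c(32L, 32L, 2L, 3L))
    expect_identical(dim(out$cls_probs), c(4L, 3L))
    expect_lt(max(abs(colSums(out$cls_probs) - 1)), 1e-6)
    expect_lt(max(abs(apply(out$seg_probs, c(1, 2, 4), sum) - 1)), 1e-6)
  }
})

test_that("layer summary reports the doubling schedule and exact counts", {
  cfg <- architecture_config(depth_E = 5, base_filters_F = 16,
                             input_size = c(256, 256))
  s <- model_summary(build_multi_output_unet(cfg, seed = 1))
  # bottleneck spatial size 256 / 2^5 = 8
  brow <- s[s$layer == "bottleneck.conv_block", ]
  expect_identical(c(brow$height, brow$width), c(8, 8))
  enc_ch <- s$channels[grepl("^enc\\d\\.conv_block$", s$layer)]
  expect_identical(enc_ch, c(16, 32, 64, 128, 256))
  # decoder mirrors the encoder block count
  expect_identical(sum(grepl("^dec\\d\\.upconv", s$layer)), 5L)
  # first conv on a 1-channel input with F = 16: 16*(3*3*1) + 16 weights+biases
  m8 <- build_multi_output_unet(architecture_config(depth_E = 2, base_filters_F = 16,
                                                    input_size = c(32, 32)), seed = 1)
  expect_identical(length(m8$params[["enc1.a.conv.W"]]) + length(m8$params[["enc1.a.conv.b"]]),
                   160L)
})

test_that("parameter count strictly increases with the base filter count", {
  n16 <- attr(model_summary(build_multi_output_unet(
    architecture_config(depth_E = 3, base_filters_F = 16, input_size = c(64, 64)),
    seed = 1)), "total_params")
  n32 <- attr(model_summary(build_multi_output_unet(
    architecture_config(depth_E = 3, base_filters_F = 32, input_size = c(64, 64)),
    seed = 1)), "total_params")
  expect_gt(n32, n16)
  # reported totals match the actual parameter store
  m <- build_multi_output_unet(architecture_config(depth_E = 3, base_filters_F = 16,
                                                   input_size = c(64, 64)), seed = 1)
  expect_identical(attr(model_summary(m), "total_params"),
                   sum(vapply(m$params, length, numeric(1))))
})

test_that("analytic gradients match finite differences on a tiny network", {
  cfg <- architecture_config(depth_E = 2, base_filters_F = 4,
                             input_size = c(16, 16), cls_classes = 3,
                             decoder_activation = "leaky_relu")
  m <- build_multi_output_unet(cfg, seed = 3)
  set.seed(8)
  N <- 2
  x <- array(runif(16 * 16 * N), c(16, 16, 1, N))
  masks <- array(rbinom(16 * 16 * N, 1, 0.3), c(16, 16, N))
  labels <- c(0L, 2L)
  w <- c(1, 1)
  loss_of <- function(model) {
    fw <- munet:::munet_forward(model, x, training = TRUE)
    w[1] * munet:::seg_scce(fw$seg_probs, masks) +
      w[2] * sparse_categorical_cross_entropy(labels, t(fw$cls_probs))
  }
  fw <- munet:::munet_forward(m, x, training = TRUE)
  lg <- munet:::loss_logit_grads(fw$seg_probs, masks, fw$cls_probs, labels, w)
  gr <- munet:::munet_backward(m, fw, lg$seg, lg$cls)
  eps <- 1e-5
  # conv biases are absorbed by batch norm (true gradient 0); check the rest
  check <- c("enc1.a.conv.W", "enc2.b.bn.gamma", "bott.b.conv.W", "head.W1",
             "head.b3", "dec2.up.W", "dec1.a.conv.W", "dec1.b.bn.beta", "out.W")
  for (nm in check) {
    p <- m$params[[nm]]
    for (i in sample(length(p), min(3, length(p)))) {
      m2 <- m; m2$params[[nm]][i] <- p[i] + eps
      m3 <- m; m3$params[[nm]][i] <- p[i] - eps
      num <- (loss_of(m2) - loss_of(m3)) / (2 * eps)
      expect_equal(gr[[nm]][i], num, tolerance = 1e-4,
                   label = sprintf("analytic grad %s[%d]", nm, i))
    }
  }
})
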