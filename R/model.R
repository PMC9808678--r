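#' Architecture configuration for the multi-output U-Net
#'
#' Collects every hyperparameter defining one network instance. The encoder
#' has `depth_E` blocks; block `l` has `base_filters_F * 2^(l-1)` channels
#' (each downsampling doubles the channel count), and the bottleneck has
#' `base_filters_F * 2^depth_E`. The decoder mirrors the encoder with 2x2
#' stride-2 transposed convolutions and skip concatenations; a classification
#' branch (max-pool, flatten, three dense layers ending in softmax) taps the
#' bottleneck features.
#'
#' @param depth_E Number of encoder blocks (>= 2).
#' @param base_filters_F Filters in the first encoder block (>= 4).
#' @param input_size `(H, W)`; both must be divisible by `2^depth_E`, and the
#'   bottleneck must retain at least 2x2 spatial extent for the
#'   classification branch's pooling (`H / 2^depth_E >= 2`).
#' @param seg_classes Segmentation classes (default 2: lung / not-lung).
#' @param cls_classes Classification classes (default 4).
#' @param decoder_activation `"relu"`, `"leaky_relu"` or `"elu"` for the
#'   expansive path (the contracting path always uses ReLU).
#' @param leaky_alpha Slope of leaky ReLU for negative inputs (default 0.1).
#' @param elu_alpha ELU saturation constant (default 1.0).
#' @param dense_units Length-3 widths of the classification head; the last
#'   entry must equal `cls_classes`. Default `c(128, 64, cls_classes)`.
#' @return An `architecture_config` object.
#' @examples
#' cfg <- architecture_config(depth_E = 3, base_filters_F = 8,
#'                            input_size = c(64, 64))
#' encoder_filter_schedule(cfg)  # 8 16 32
#' @export
architecture_config <- function(depth_E = 3, base_filters_F = 8,
                                input_size = c(64, 64), seg_classes = 2,
                                cls_classes = 4,
                                decoder_activation = c("relu", "leaky_relu", "elu"),
                                leaky_alpha = 0.1, elu_alpha = 1.0,
                                dense_units = NULL) {
  decoder_activation <- match.arg(decoder_activation)
  E <- as.integer(depth_E); F <- as.integer(base_filters_F)
  if (E < 2) stopf("depth_E must be >= 2, got %d", E)
  if (F < 4) stopf("base_filters_F must be >= 4, got %d", F)
  H <- as.integer(input_size[1]); W <- as.integer(input_size[2])
  if (H %% 2^E != 0 || W %% 2^E != 0)
    stopf("input_size %dx%d not divisible by 2^depth_E = %d", H, W, 2^E)
  if (H %/% 2^E < 2 || W %/% 2^E < 2)
    stopf("bottleneck spatial size %dx%d too small for the classification head (need >= 2x2)",
          H %/% 2^E, W %/% 2^E)
  if (seg_classes < 2) stopf("seg_classes must be >= 2")
  if (cls_classes < 2) stopf("cls_classes must be >= 2")
  if (is.null(dense_units)) dense_units <- c(128, 64, cls_classes)
  if (length(dense_units) != 3) stopf("dense_units must have length 3")
  if (dense_units[3] != cls_classes)
    stopf("last dense unit (%d) must equal cls_classes (%d)", dense_units[3], cls_classes)
  if (leaky_alpha <= 0 || leaky_alpha >= 1) stopf("leaky_alpha must be in (0, 1)")
  structure(list(depth_E = E, base_filters_F = F, input_size = c(H, W),
                 seg_classes = as.integer(seg_classes),
                 cls_classes = as.integer(cls_classes),
                 decoder_activation = decoder_activation,
                 leaky_alpha = leaky_alpha, elu_alpha = elu_alpha,
                 dense_units = as.integer(dense_units)),
            class = "architecture_config")
}

#' Encoder filter schedule
#'
#' Channel counts per encoder block: `F, 2F, 4F, ..., 2^(E-1) F` — each
#' stride-2 downsampling doubles the number of feature channels.
#'
#' @param config An [architecture_config()].
#' @return Integer vector of length `depth_E`.
#' @export
encoder_filter_schedule <- function(config) {
  as.integer(config$base_filters_F * 2^(seq_len(config$depth_E) - 1))
}

#' Elementwise activation functions
#'
#' ReLU `max(z, 0)`; leaky ReLU `max(alpha z, z)` with `0 < alpha < 1`;
#' ELU `z` for `z >= 0` and `alpha (e^z - 1)` otherwise.
#'
#' @param name One of `"relu"`, `"leaky_relu"`, `"elu"`.
#' @param z Numeric input (vectorized).
#' @param alpha Slope / saturation parameter (used by leaky ReLU and ELU).
#' @return Activated values, same shape as `z`.
#' @examples
#' activation("leaky_relu", -10, alpha = 0.1)  # -1
#' @export
activation <- function(name, z, alpha = if (name == "leaky_relu") 0.1 else 1.0) {
  switch(name,
         relu = pmax(z, 0),
         leaky_relu = {
           if (alpha <= 0 || alpha >= 1) stopf("leaky_relu needs 0 < alpha < 1")
           pmax(alpha * z, z)
         },
         elu = ifelse(z >= 0, z, alpha * (exp(z) - 1)),
         stopf("unknown activation '%s'", name))
}

act_fwd <- function(z, name, alpha) {
  y <- switch(name,
              relu = pmax(z, 0),
              leaky_relu = pmax(alpha * z, z),
              elu = {
                neg <- z < 0
                out <- z
                out[neg] <- alpha * (exp(z[neg]) - 1)
                out
              })
  if (!is.null(dim(z))) dim(y) <- dim(z)
  y
}

act_bwd <- function(z, name, alpha, gy) {
  g <- switch(name,
              relu = gy * (z > 0),
              leaky_relu = gy * ifelse(z > 0, 1, alpha),
              elu = {
                d <- rep(1, length(z)); dim(d) <- dim(z)
                neg <- z < 0
                d[neg] <- alpha * exp(z[neg])
                gy * d
              })
  if (!is.null(dim(gy))) dim(g) <- dim(gy)
  g
}

softmax_cols <- function(z) {
  C <- nrow(z)
  m <- z[1, ]
  if (C > 1) for (k in 2:C) m <- pmax(m, z[k, ])
  e <- exp(z - rep(m, each = C))
  e / rep(colSums(e), each = C)
}

softmax_seg <- function(z) {
  d <- dim(z)
  zp <- aperm(z, c(3, 1, 2, 4))
  dim(zp) <- c(d[3], d[1] * d[2] * d[4])
  p <- softmax_cols(zp)
  dim(p) <- c(d[3], d[1], d[2], d[4])
  aperm(p, c(2, 3, 1, 4))
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

he_conv <- function(kh, kw, ci, co) {
  array(rnorm(kh * kw * ci * co, 0, sqrt(2 / (kh * kw * ci))), c(kh, kw, ci, co))
}

#' Build a multi-output U-Net
#'
#' Constructs and initializes (He-normal weights, seeded) the network:
#' an encoder of `depth_E` blocks of (3x3 SAME conv, batch norm, ReLU) x2
#' followed by 2x2 stride-2 max pooling; a bottleneck conv block; a
#' classification branch tapping the bottleneck (2x2 max pool, flatten,
#' dense-ReLU, dense-ReLU, dense-softmax); and a decoder of `depth_E` blocks
#' of (2x2 stride-2 transposed conv, skip concatenation, (3x3 conv, batch
#' norm, decoder activation) x2), closed by a 1x1 convolution to
#' `seg_classes` channels with per-pixel softmax. The segmentation output has
#' the input's spatial shape; the classification output is a probability
#' vector.
#'
#' @param config An [architecture_config()].
#' @param seed Seed for weight initialization.
#' @return A `munet_model`: list with `config`, `params` (flat named list of
#'   weight arrays) and `bn` (running batch-norm statistics).
#' @examples
#' m <- build_multi_output_unet(architecture_config(depth_E = 2,
#'   base_filters_F = 4, input_size = c(32, 32)))
#' out <- predict(m, matrix(runif(32 * 32), 32, 32))
#' sum(out$cls_probs)  # 1
#' @export
build_multi_output_unet <- function(config, seed = 42) {
  if (!inherits(config, "architecture_config"))
    config <- do.call(architecture_config, config)
  E <- config$depth_E
  sched <- encoder_filter_schedule(config)
  cb <- config$base_filters_F * 2^E  # bottleneck channels
  hb <- config$input_size[1] %/% 2^E
  wb <- config$input_size[2] %/% 2^E
  with_seed(seed, {
    p <- list(); bn <- list()
    add_cba <- function(prefix, ci, co) {
      p[[paste0(prefix, ".conv.W")]] <<- he_conv(3, 3, ci, co)
      p[[paste0(prefix, ".conv.b")]] <<- numeric(co)
      p[[paste0(prefix, ".bn.gamma")]] <<- rep(1, co)
      p[[paste0(prefix, ".bn.beta")]] <<- numeric(co)
      bn[[paste0(prefix, ".bn")]] <<- list(mean = numeric(co), var = rep(1, co))
    }
    ci <- 1L
    for (l in seq_len(E)) {
      add_cba(sprintf("enc%d.a", l), ci, sched[l])
      add_cba(sprintf("enc%d.b", l), sched[l], sched[l])
      ci <- sched[l]
    }
    add_cba("bott.a", ci, cb)
    add_cba("bott.b", cb, cb)
    P <- (hb %/% 2) * (wb %/% 2) * cb
    du <- config$dense_units
    p[["head.W1"]] <- matrix(rnorm(P * du[1], 0, sqrt(2 / P)), P, du[1])
    p[["head.b1"]] <- numeric(du[1])
    p[["head.W2"]] <- matrix(rnorm(du[1] * du[2], 0, sqrt(2 / du[1])), du[1], du[2])
    p[["head.b2"]] <- numeric(du[2])
    p[["head.W3"]] <- matrix(rnorm(du[2] * du[3], 0, sqrt(2 / du[2])), du[2], du[3])
    p[["head.b3"]] <- numeric(du[3])
    ci <- cb
    for (l in rev(seq_len(E))) {
      p[[sprintf("dec%d.up.W", l)]] <- array(rnorm(4 * ci * sched[l], 0, sqrt(2 / (4 * ci))),
                                             c(2, 2, ci, sched[l]))
      p[[sprintf("dec%d.up.b", l)]] <- numeric(sched[l])
      add_cba(sprintf("dec%d.a", l), 2 * sched[l], sched[l])
      add_cba(sprintf("dec%d.b", l), sched[l], sched[l])
      ci <- sched[l]
    }
    p[["out.W"]] <- he_conv(1, 1, sched[1], config$seg_classes)
    p[["out.b"]] <- numeric(config$seg_classes)
    structure(list(config = config, params = p, bn = bn), class = "munet_model")
  })
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

# One (conv -> batch norm -> activation) layer, forward.
cba_fwd <- function(x, params, bn, prefix, act, alpha, training) {
  W <- params[[paste0(prefix, ".conv.W")]]
  b <- params[[paste0(prefix, ".conv.b")]]
  gamma <- params[[paste0(prefix, ".bn.gamma")]]
  beta <- params[[paste0(prefix, ".bn.beta")]]
  cf <- conv2d_fwd(x, W, b)
  if (training) {
    r <- bn_fwd(cf, gamma, beta, BN_EPS)
    y <- r$y; mu <- r$mean; vv <- r$var
    run <- bn[[paste0(prefix, ".bn")]]
    new_run <- list(mean = BN_MOMENTUM * run$mean + (1 - BN_MOMENTUM) * mu,
                    var = BN_MOMENTUM * run$var + (1 - BN_MOMENTUM) * vv)
  } else {
    run <- bn[[paste0(prefix, ".bn")]]
    y <- bn_eval(cf, gamma, beta, run$mean, run$var, BN_EPS)
    mu <- run$mean; vv <- run$var
    new_run <- NULL
  }
  a <- act_fwd(y, act, alpha)
  list(out = a, x_in = x, conv = cf, mean = mu, var = vv, bn_out = y,
       new_run = new_run)
}

# Matching backward; returns grad wrt the layer input plus parameter grads.
cba_bwd <- function(lc, params, prefix, act, alpha, gy) {
  W <- params[[paste0(prefix, ".conv.W")]]
  gamma <- params[[paste0(prefix, ".bn.gamma")]]
  g_bn_out <- act_bwd(lc$bn_out, act, alpha, gy)
  bb <- bn_bwd(lc$conv, gamma, lc$mean, lc$var, BN_EPS, g_bn_out)
  cb <- conv2d_bwd(lc$x_in, W, bb$gx)
  grads <- list()
  grads[[paste0(prefix, ".conv.W")]] <- cb$gw
  grads[[paste0(prefix, ".conv.b")]] <- cb$gb
  grads[[paste0(prefix, ".bn.gamma")]] <- bb$ggamma
  grads[[paste0(prefix, ".bn.beta")]] <- bb$gbeta
  list(gx = cb$gx, grads = grads)
}

# Full forward pass. x is (H, W, 1, N) in [0, 1]. Returns segmentation and
# classification probabilities and logits, plus the cache needed for
# backpropagation and (in training mode) updated batch-norm running stats.
munet_forward <- function(model, x, training = FALSE) {
  cfg <- model$config; p <- model$params
  E <- cfg$depth_E
  alpha_dec <- if (cfg$decoder_activation == "leaky_relu") cfg$leaky_alpha else cfg$elu_alpha
  cache <- list(enc = vector("list", E), dec = vector("list", E))
  new_bn <- list()
  cur <- x
  for (l in seq_len(E)) {
    la <- cba_fwd(cur, p, model$bn, sprintf("enc%d.a", l), "relu", 1, training)
    lb <- cba_fwd(la$out, p, model$bn, sprintf("enc%d.b", l), "relu", 1, training)
    mp <- maxpool2_fwd(lb$out)
    if (training) {
      new_bn[[sprintf("enc%d.a.bn", l)]] <- la$new_run
      new_bn[[sprintf("enc%d.b.bn", l)]] <- lb$new_run
    }
    cache$enc[[l]] <- list(a = la, b = lb, pool_idx = mp$idx,
                           skip_dim = dim(lb$out))
    cur <- mp$y
  }
  ba <- cba_fwd(cur, p, model$bn, "bott.a", "relu", 1, training)
  bb <- cba_fwd(ba$out, p, model$bn, "bott.b", "relu", 1, training)
  if (training) {
    new_bn[["bott.a.bn"]] <- ba$new_run
    new_bn[["bott.b.bn"]] <- bb$new_run
  }
  z <- bb$out  # bottleneck features: the Grad-CAM tap point
  cache$bott <- list(a = ba, b = bb)

  # classification branch
  hp <- maxpool2_fwd(z)
  flat <- hp$y
  N <- dim(x)[4]
  dim(flat) <- c(length(flat) %/% N, N)
  a1 <- crossprod(p[["head.W1"]], flat) + p[["head.b1"]]
  h1 <- pmax(a1, 0)
  a2 <- crossprod(p[["head.W2"]], h1) + p[["head.b2"]]
  h2 <- pmax(a2, 0)
  cls_logits <- crossprod(p[["head.W3"]], h2) + p[["head.b3"]]
  cls_probs <- softmax_cols(cls_logits)
  cache$head <- list(z_dim = dim(z), pool_idx = hp$idx, flat = flat,
                     a1 = a1, h1 = h1, a2 = a2, h2 = h2)

  # decoder
  cur <- z
  for (l in rev(seq_len(E))) {
    u <- convt2_fwd(cur, p[[sprintf("dec%d.up.W", l)]], p[[sprintf("dec%d.up.b", l)]])
    ct <- concat_ch(u, cache$enc[[l]]$b$out)
    da <- cba_fwd(ct, p, model$bn, sprintf("dec%d.a", l), cfg$decoder_activation,
                  alpha_dec, training)
    db <- cba_fwd(da$out, p, model$bn, sprintf("dec%d.b", l), cfg$decoder_activation,
                  alpha_dec, training)
    if (training) {
      new_bn[[sprintf("dec%d.a.bn", l)]] <- da$new_run
      new_bn[[sprintf("dec%d.b.bn", l)]] <- db$new_run
    }
    cache$dec[[l]] <- list(x_in = cur, u_in_dim = dim(cur), u = u, a = da, b = db,
                           n_up = dim(u)[3])
    cur <- db$out
  }
  seg_logits <- conv2d_fwd(cur, p[["out.W"]], p[["out.b"]])
  seg_probs <- softmax_seg(seg_logits)
  list(seg_logits = seg_logits, seg_probs = seg_probs,
       cls_logits = cls_logits, cls_probs = cls_probs,
       cache = cache,
       new_bn = if (training) new_bn else NULL,
       final_act = cur)
}

# Backward through the classification head only, from a gradient on the class
# logits to a gradient on the bottleneck features. Shared by training and
# Grad-CAM.
head_bwd <- function(model, cache, g_logits) {
  p <- model$params; hc <- cache$head
  grads <- list()
  grads[["head.W3"]] <- hc$h2 %*% t(g_logits)
  grads[["head.b3"]] <- rowSums(g_logits)
  g_h2 <- p[["head.W3"]] %*% g_logits
  g_a2 <- g_h2 * (hc$a2 > 0)
  grads[["head.W2"]] <- hc$h1 %*% t(g_a2)
  grads[["head.b2"]] <- rowSums(g_a2)
  g_h1 <- p[["head.W2"]] %*% g_a2
  g_a1 <- g_h1 * (hc$a1 > 0)
  grads[["head.W1"]] <- hc$flat %*% t(g_a1)
  grads[["head.b1"]] <- rowSums(g_a1)
  g_flat <- p[["head.W1"]] %*% g_a1
  zd <- hc$z_dim
  pooled_dim <- c(zd[1] %/% 2, zd[2] %/% 2, zd[3], zd[4])
  g_pool <- g_flat
  dim(g_pool) <- pooled_dim
  g_z <- maxpool2_bwd(hc$pool_idx, g_pool, as.integer(zd))
  list(g_z = g_z, grads = grads)
}

# Full backward pass from gradients on the two output logit tensors.
# Requires a training-mode cache (batch statistics in batch norm).
munet_backward <- function(model, fwd, g_seg_logits, g_cls_logits) {
  cfg <- model$config; p <- model$params; cache <- fwd$cache
  E <- cfg$depth_E
  act <- cfg$decoder_activation
  alpha_dec <- if (act == "leaky_relu") cfg$leaky_alpha else cfg$elu_alpha
  grads <- list()

  ob <- conv2d_bwd(fwd$final_act, p[["out.W"]], g_seg_logits)
  grads[["out.W"]] <- ob$gw
  grads[["out.b"]] <- ob$gb
  g_cur <- ob$gx
  skip_grads <- vector("list", E)
  for (l in seq_len(E)) {
    dc <- cache$dec[[l]]
    rb <- cba_bwd(dc$b, p, sprintf("dec%d.b", l), act, alpha_dec, g_cur)
    grads[names(rb$grads)] <- rb$grads
    ra <- cba_bwd(dc$a, p, sprintf("dec%d.a", l), act, alpha_dec, rb$gx)
    grads[names(ra$grads)] <- ra$grads
    nu <- dc$n_up
    g_u <- ra$gx[, , seq_len(nu), , drop = FALSE]
    skip_grads[[l]] <- ra$gx[, , nu + seq_len(dim(ra$gx)[3] - nu), , drop = FALSE]
    ub <- convt2_bwd(dc$x_in, p[[sprintf("dec%d.up.W", l)]], g_u)
    grads[[sprintf("dec%d.up.W", l)]] <- ub$gw
    grads[[sprintf("dec%d.up.b", l)]] <- ub$gb
    g_cur <- ub$gx
  }

  hb <- head_bwd(model, cache, g_cls_logits)
  grads[names(hb$grads)] <- hb$grads
  g_z <- g_cur + hb$g_z

  rb <- cba_bwd(cache$bott$b, p, "bott.b", "relu", 1, g_z)
  grads[names(rb$grads)] <- rb$grads
  ra <- cba_bwd(cache$bott$a, p, "bott.a", "relu", 1, rb$gx)
  grads[names(ra$grads)] <- ra$grads
  g_cur <- ra$gx
  for (l in rev(seq_len(E))) {
    ec <- cache$enc[[l]]
    g_pooled <- maxpool2_bwd(ec$pool_idx, g_cur, as.integer(ec$skip_dim))
    g_b_out <- g_pooled + skip_grads[[l]]
    rb <- cba_bwd(ec$b, p, sprintf("enc%d.b", l), "relu", 1, g_b_out)
    grads[names(rb$grads)] <- rb$grads
    ra <- cba_bwd(ec$a, p, sprintf("enc%d.a", l), "relu", 1, rb$gx)
    grads[names(ra$grads)] <- ra$grads
    g_cur <- ra$gx
  }
  grads
}

# Stack a list of (H, W) matrices (or an (H, W[, N]) array) into the
# (H, W, 1, N) input tensor.
as_input_tensor <- function(images) {
  if (is.list(images)) {
    H <- nrow(images[[1]]); W <- ncol(images[[1]])
    x <- array(0, c(H, W, 1, length(images)))
    for (i in seq_along(images)) x[, , 1, i] <- images[[i]]
    return(x)
  }
  d <- dim(images)
  if (length(d) == 2) { dim(images) <- c(d, 1, 1); return(images) }
  if (length(d) == 3) { dim(images) <- c(d[1], d[2], 1, d[3]); return(images) }
  if (length(d) == 4) return(images)
  stopf("cannot interpret images with %d dimensions as input", length(d))
}

#' Forward a batch of images through a multi-output U-Net
#'
#' Runs the network in inference mode (batch norm uses running statistics).
#'
#' @param object A `munet_model`.
#' @param images A single H x W matrix, an (H, W, N) array, or a list of
#'   matrices; pixel values should already be rescaled to [0, 1] (see
#'   [rescale_image()]).
#' @param batch_size Images per forward chunk (memory control).
#' @param ... Unused.
#' @return List with `seg_probs` — (H, W, seg_classes, N) per-pixel class
#'   probabilities — and `cls_probs` — (cls_classes, N) class probability
#'   columns.
#' @export
predict.munet_model <- function(object, images, batch_size = 32, ...) {
  x <- as_input_tensor(images)
  d <- dim(x)
  if (d[1] != object$config$input_size[1] || d[2] != object$config$input_size[2])
    stopf("images are %dx%d but the model expects %dx%d", d[1], d[2],
          object$config$input_size[1], object$config$input_size[2])
  N <- d[4]
  seg <- array(0, c(d[1], d[2], object$config$seg_classes, N))
  cls <- matrix(0, object$config$cls_classes, N)
  for (start in seq(1, N, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, N)
    fw <- munet_forward(object, x[, , , idx, drop = FALSE], training = FALSE)
    seg[, , , idx] <- fw$seg_probs
    cls[, idx] <- fw$cls_probs
  }
  list(seg_probs = seg, cls_probs = cls)
}

#' Per-layer summary of a multi-output U-Net
#'
#' Walks the architecture and reports each layer's output spatial shape,
#' channel count and parameter count, plus the grand total.
#'
#' @param model A `munet_model`.
#' @return A `layer_summary`: tibble with columns `layer`, `height`, `width`,
#'   `channels`, `params`, and a `total_params` attribute.
#' @export
model_summary <- function(model) {
  cfg <- model$config
  E <- cfg$depth_E
  sched <- encoder_filter_schedule(cfg)
  H <- cfg$input_size[1]; W <- cfg$input_size[2]
  rows <- list()
  add <- function(layer, h, w, ch, np)
    rows[[length(rows) + 1]] <<- tibble::tibble(layer = layer, height = h,
                                                width = w, channels = ch,
                                                params = np)
  cba_params <- function(ci, co) (9 * ci * co + co) + 2 * co
  ci <- 1L; h <- H; w <- W
  for (l in seq_len(E)) {
    add(sprintf("enc%d.conv_block", l), h, w, sched[l],
        cba_params(ci, sched[l]) + cba_params(sched[l], sched[l]))
    h <- h %/% 2; w <- w %/% 2
    add(sprintf("enc%d.maxpool", l), h, w, sched[l], 0)
    ci <- sched[l]
  }
  cb <- cfg$base_filters_F * 2^E
  add("bottleneck.conv_block", h, w, cb, cba_params(ci, cb) + cba_params(cb, cb))
  P <- (h %/% 2) * (w %/% 2) * cb
  du <- cfg$dense_units
  add("head.maxpool_flatten", 1, 1, P, 0)
  add("head.dense1", 1, 1, du[1], P * du[1] + du[1])
  add("head.dense2", 1, 1, du[2], du[1] * du[2] + du[2])
  add("head.dense3_softmax", 1, 1, du[3], du[2] * du[3] + du[3])
  ci <- cb
  for (l in rev(seq_len(E))) {
    h <- h * 2; w <- w * 2
    add(sprintf("dec%d.upconv_concat", l), h, w, 2 * sched[l],
        4 * ci * sched[l] + sched[l])
    add(sprintf("dec%d.conv_block", l), h, w, sched[l],
        cba_params(2 * sched[l], sched[l]) + cba_params(sched[l], sched[l]))
    ci <- sched[l]
  }
  add("out.conv1x1_softmax", h, w, cfg$seg_classes,
      sched[1] * cfg$seg_classes + cfg$seg_classes)
  out <- do.call(rbind, rows)
  attr(out, "total_params") <- sum(out$params)
  class(out) <- c("layer_summary", class(out))
  out
}

#' @export
summary.munet_model <- function(object, ...) model_summary(object)

#' @export
print.munet_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<munet_model> %dE%dF, input %dx%d, %d seg classes, %d cls classes, decoder %s\n",
              cfg$depth_E, cfg$base_filters_F, cfg$input_size[1], cfg$input_size[2],
              cfg$seg_classes, cfg$cls_classes, cfg$decoder_activation))
  cat(sprintf("  encoder filters: %s; parameters: %s\n",
              paste(encoder_filter_schedule(cfg), collapse = ", "),
              format(attr(model_summary(x), "total_params"), big.mark = ",")))
  invisible(x)
}

# Count of learnable parameters.
n_params <- function(model) sum(vapply(model$params, length, numeric(1)))
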