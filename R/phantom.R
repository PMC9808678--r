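#' Synthetic chest-phantom images with exact lung masks
#'
#' Generates a chest-radiograph-like phantom: two non-overlapping elliptical
#' "lung fields" on a brighter torso background, with class-conditional lung
#' texture and the exact rasterized binary mask of the two ellipses as ground
#' truth. Phantoms make every downstream stage (training, metrics,
#' explainability) testable with no external data.
#'
#' Class-conditional texture (label semantics follow the 4-class chest X-ray
#' convention Normal / COVID-19 / Viral Pneumonia / Lung Opacity):
#' \itemize{
#'   \item \strong{normal} — dark lung fields with low-amplitude Gaussian noise.
#'   \item \strong{diffuse haze} (COVID-19-style) — a smooth low-pass random
#'     field raises lung intensity moderately.
#'   \item \strong{focal} (Viral-Pneumonia-style) — 1–3 bright Gaussian blobs
#'     inside the lungs; the first blob is placed well inside a lung and is
#'     large enough to cover at least 2\% of lung pixels.
#'   \item \strong{dense haze} (Lung-Opacity-style) — a stronger smooth field.
#' }
#' Mean lung intensity is therefore ordered normal < diffuse < dense.
#' Intensities are generated as floats and quantized to the 0–255 scale at
#' creation time. Generation is a pure function of `(seed, label, size)`.
#'
#' @param seed Integer seed; the same seed reproduces the sample bit-for-bit.
#' @param label Integer class id in `0:(n_classes - 1)`.
#' @param size Integer `(H, W)`, both at least 32.
#' @param n_classes Number of classes (2, 3 or 4; default 4).
#' @return A `phantom_sample`: list with `image` (H x W matrix, integer values
#'   on 0–255), `mask` (H x W matrix of 0/1), `label`, and `params` (ellipse
#'   geometry, texture type, lesion descriptors, seed) sufficient to
#'   re-rasterize the mask with [rasterize_lungs()].
#' @examples
#' s <- generate_phantom(seed = 7, label = 0, size = c(64, 64))
#' mean(s$image[s$mask == 1])  # dark normal lungs
#' @export
generate_phantom <- function(seed, label, size = c(64, 64), n_classes = 4) {
  H <- as.integer(size[1]); W <- as.integer(size[2])
  if (H < 32 || W < 32) stopf("size must be at least 32 x 32, got %d x %d", H, W)
  if (!n_classes %in% 1:4) stopf("n_classes must be between 1 and 4")
  if (length(label) != 1 || is.na(label) || label != as.integer(label) ||
      label < 0 || label >= n_classes)
    stopf("label must be an integer in 0..%d, got %s", n_classes - 1, toString(label))
  label <- as.integer(label)
  texture <- texture_for_label(label, n_classes)

  with_seed(seed, {
    ellipses <- list(
      left = list(
        cx = W * (0.28 + runif(1, -0.02, 0.02)),
        cy = H * (0.50 + runif(1, -0.03, 0.03)),
        a  = W * runif(1, 0.12, 0.16),
        b  = H * runif(1, 0.24, 0.30),
        theta = runif(1, -0.15, 0.15)),
      right = list(
        cx = W * (0.72 + runif(1, -0.02, 0.02)),
        cy = H * (0.50 + runif(1, -0.03, 0.03)),
        a  = W * runif(1, 0.12, 0.16),
        b  = H * runif(1, 0.24, 0.30),
        theta = runif(1, -0.15, 0.15))
    )
    params <- list(seed = seed, label = label, n_classes = n_classes,
                   size = c(H, W), texture = texture, ellipses = ellipses,
                   blobs = list())

    masks <- lapply(ellipses, rasterize_ellipse, H = H, W = W)
    if (any(masks$left + masks$right > 1))
      stopf("internal geometry failure: lung ellipses overlap (seed %d)", seed)
    for (e in ellipses) {
      ext_x <- sqrt((e$a * cos(e$theta))^2 + (e$b * sin(e$theta))^2)
      ext_y <- sqrt((e$a * sin(e$theta))^2 + (e$b * cos(e$theta))^2)
      if (e$cx - ext_x < 0 || e$cx + ext_x > W || e$cy - ext_y < 0 || e$cy + ext_y > H)
        stopf("internal geometry failure: lung ellipse out of frame (seed %d)", seed)
    }
    mask <- masks$left + masks$right
    frac <- mean(mask)
    if (frac < 0.10 || frac > 0.50)
      stopf("internal geometry failure: lung fraction %.3f outside [0.10, 0.50]", frac)

    # torso background: bright field with a gentle vertical gradient + noise
    rowgrad <- matrix(seq(-0.5, 0.5, length.out = H), H, W)
    img <- 160 + 8 * rowgrad + matrix(rnorm(H * W, 0, 6), H, W)
    inlung <- mask == 1
    img[inlung] <- 60 + rnorm(sum(inlung), 0, 6)

    if (texture %in% c("diffuse", "dense")) {
      lo <- if (texture == "diffuse") 0.4 else 0.6
      amp <- if (texture == "diffuse") 45 else 85
      field <- smooth_field(H, W, grid = 6, lo = lo, hi = 1.0)
      img[inlung] <- img[inlung] + amp * field[inlung]
      params$field_mean <- mean(field[inlung])
    } else if (texture == "focal") {
      nb <- sample(1:3, 1)
      lung_idx <- which(inlung, arr.ind = TRUE)
      xs <- matrix(rep(seq_len(W) - 0.5, each = H), H, W)
      ys <- matrix(rep(seq_len(H) - 0.5, W), H, W)
      for (k in seq_len(nb)) {
        if (k == 1) {
          # anchor blob: near a lung center, large and bright, so a connected
          # bright region >= 2% of lung pixels is guaranteed
          e <- ellipses[[sample(1:2, 1)]]
          cx <- e$cx + runif(1, -0.25, 0.25) * e$a
          cy <- e$cy + runif(1, -0.25, 0.25) * e$b
          sigma <- runif(1, 0.06, 0.08) * min(H, W)
          amp <- runif(1, 145, 160)
        } else {
          p <- lung_idx[sample(nrow(lung_idx), 1), ]
          cx <- p[["col"]] - 0.5; cy <- p[["row"]] - 0.5
          sigma <- runif(1, 0.03, 0.06) * min(H, W)
          amp <- runif(1, 90, 140)
        }
        img <- img + amp * exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * sigma^2))
        params$blobs[[k]] <- list(cx = cx, cy = cy, sigma = sigma, amp = amp)
      }
    }

    img <- pmin(pmax(round(img), 0), 255)
    structure(list(image = img, mask = mask, label = label, params = params),
              class = "phantom_sample")
  })
}

texture_for_label <- function(label, n_classes) {
  types <- switch(as.character(n_classes),
                  "1" = "normal",
                  "2" = c("normal", "dense"),
                  "3" = c("normal", "diffuse", "dense"),
                  "4" = c("normal", "diffuse", "focal", "dense"))
  types[label + 1]
}

default_class_names <- function(n_classes) {
  switch(as.character(n_classes),
         "1" = "Normal",
         "2" = c("Normal", "Dense Haze"),
         "3" = c("Normal", "Diffuse Haze", "Dense Haze"),
         "4" = c("Normal", "COVID-19", "Viral Pneumonia", "Lung Opacity"))
}

# Rasterize one rotated ellipse at pixel centers (col - 0.5, row - 0.5).
rasterize_ellipse <- function(e, H, W) {
  xs <- matrix(rep(seq_len(W) - 0.5, each = H), H, W) - e$cx
  ys <- matrix(rep(seq_len(H) - 0.5, W), H, W) - e$cy
  u <- xs * cos(e$theta) + ys * sin(e$theta)
  v <- -xs * sin(e$theta) + ys * cos(e$theta)
  ((u / e$a)^2 + (v / e$b)^2 <= 1) + 0L
}

#' Re-rasterize the lung mask from stored phantom parameters
#'
#' The stored mask of a [generate_phantom()] sample is by construction the
#' union of its two lung ellipses; this function recomputes that union from
#' the `params` record, which lets callers verify mask exactness.
#'
#' @param params The `params` element of a `phantom_sample`.
#' @param size Optional `(H, W)`; defaults to the size recorded in `params`.
#' @return H x W matrix of 0/1.
#' @export
rasterize_lungs <- function(params, size = params$size) {
  H <- size[1]; W <- size[2]
  m <- rasterize_ellipse(params$ellipses$left, H, W) +
    rasterize_ellipse(params$ellipses$right, H, W)
  (m > 0) + 0L
}

# Low-pass random field: coarse uniform grid, bilinearly upsampled.
smooth_field <- function(H, W, grid = 6, lo = 0, hi = 1) {
  g <- matrix(runif(grid * grid, lo, hi), grid, grid)
  bilinear_resize(g, H, W)
}

#' Largest-remainder apportionment of n samples over class proportions
#'
#' Each class first receives `floor(n * p)` samples; leftover samples go to
#' the classes with the largest fractional remainders (ties resolved toward
#' the lower class index).
#'
#' @param n Total count.
#' @param proportions Numeric vector summing to 1 (within 1e-9).
#' @return Integer vector of per-class counts summing to `n`.
#' @examples
#' apportion_counts(10, c(0.25, 0.25, 0.25, 0.25))  # 3 3 2 2
#' @export
apportion_counts <- function(n, proportions) {
  if (n < 1) stopf("n must be >= 1")
  if (abs(sum(proportions) - 1) > 1e-9)
    stopf("class proportions must sum to 1 (got %.12f)", sum(proportions))
  if (any(proportions < 0)) stopf("class proportions must be non-negative")
  quota <- n * proportions
  counts <- floor(quota)
  rem <- n - sum(counts)
  if (rem > 0) {
    ord <- order(quota - counts, seq_along(quota), decreasing = c(TRUE, FALSE),
                 method = "radix")
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  as.integer(counts)
}

#' Generate a labelled phantom dataset
#'
#' Draws `n` phantoms with per-class counts given by the largest-remainder
#' apportionment of `n * class_proportions`. Each sample gets its own seed
#' derived deterministically from the master seed and the sample index, so
#' the whole dataset regenerates bit-identically and individual samples can
#' be regenerated in isolation.
#'
#' @param n Number of samples (>= 1).
#' @param class_proportions Simplex vector; its length sets the class count.
#' @param size `(H, W)` image size.
#' @param seed Master seed.
#' @return A `phantom_dataset`: list with `samples` (list of
#'   `phantom_sample`), `manifest` (tibble: image, mask, label, seed),
#'   `class_names`.
#' @examples
#' ds <- generate_dataset(8, class_proportions = rep(0.25, 4), seed = 1)
#' table(ds$manifest$label)
#' @export
generate_dataset <- function(n, class_proportions = rep(0.25, 4),
                             size = c(64, 64), seed = 1) {
  counts <- apportion_counts(n, class_proportions)
  n_classes <- length(class_proportions)
  labels <- rep(seq_along(counts) - 1L, counts)
  seeds <- vapply(seq_len(n), function(i) derive_seed(seed, i), integer(1))
  samples <- lapply(seq_len(n), function(i)
    generate_phantom(seeds[i], labels[i], size = size, n_classes = n_classes))
  manifest <- tibble::tibble(
    image = sprintf("images/sample_%04d.png", seq_len(n)),
    mask = sprintf("masks/sample_%04d.png", seq_len(n)),
    label = labels,
    seed = seeds)
  structure(list(samples = samples, manifest = manifest,
                 class_names = default_class_names(n_classes) %||%
                   paste0("class_", seq_len(n_classes) - 1)),
            class = "phantom_dataset")
}

#' Write / read a phantom dataset as PNGs plus a CSV manifest
#'
#' `write_dataset()` lays out `directory/images/*.png` (8-bit grayscale),
#' `directory/masks/*.png` (0/255 on disk), `manifest.csv` with columns
#' `image,mask,label,seed`, and `classes.txt` (one class name per line in
#' index order). `read_dataset()` reverses it losslessly: 8-bit quantization
#' happened at generation time, so `read_dataset(write_dataset(x))`
#' reproduces images, masks and labels exactly.
#'
#' @param dataset A `phantom_dataset` (or any list with compatible
#'   `samples`/`manifest`/`class_names`).
#' @param directory Target directory (created if needed).
#' @return `write_dataset()` returns `directory` invisibly; `read_dataset()`
#'   returns a `phantom_dataset` whose samples carry `image`, `mask`, `label`
#'   (no generator `params`).
#' @export
write_dataset <- function(dataset, directory) {
  dir.create(file.path(directory, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(directory, "masks"), recursive = TRUE, showWarnings = FALSE)
  man <- dataset$manifest
  for (i in seq_along(dataset$samples)) {
    s <- dataset$samples[[i]]
    png::writePNG(s$image / 255, file.path(directory, man$image[i]))
    png::writePNG(s$mask * 1.0, file.path(directory, man$mask[i]))
  }
  write.csv(man, file.path(directory, "manifest.csv"), row.names = FALSE)
  writeLines(dataset$class_names, file.path(directory, "classes.txt"))
  invisible(directory)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(directory) {
  man_path <- file.path(directory, "manifest.csv")
  if (!file.exists(man_path)) stopf("no manifest.csv in %s", directory)
  man <- tibble::as_tibble(read.csv(man_path, stringsAsFactors = FALSE))
  class_names <- readLines(file.path(directory, "classes.txt"))
  samples <- lapply(seq_len(nrow(man)), function(i) {
    ipath <- file.path(directory, man$image[i])
    mpath <- file.path(directory, man$mask[i])
    if (!file.exists(ipath))
      stopf("manifest row %d: missing image file %s", i, ipath)
    if (!file.exists(mpath))
      stopf("manifest row %d: missing mask file %s", i, mpath)
    if (man$label[i] < 0 || man$label[i] >= length(class_names))
      stopf("manifest row %d: label %d outside classes.txt range 0..%d",
            i, man$label[i], length(class_names) - 1)
    img <- round(read_png_gray(ipath) * 255)
    msk <- (read_png_gray(mpath) * 255 >= 128) + 0L
    structure(list(image = img, mask = msk, label = as.integer(man$label[i]),
                   params = NULL),
              class = "phantom_sample")
  })
  structure(list(samples = samples, manifest = man, class_names = class_names),
            class = "phantom_dataset")
}

# Read a PNG and reduce to a single grayscale channel in [0, 1].
read_png_gray <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  x
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("<phantom_sample> %dx%d, label %d (%s), lung fraction %.3f\n",
              nrow(x$image), ncol(x$image), x$label,
              x$params$texture %||% "?", mean(x$mask)))
  invisible(x)
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat(sprintf("<phantom_dataset> %d samples, %d classes (%s)\n",
              length(x$samples), length(x$class_names),
              paste(x$class_names, collapse = ", ")))
  invisible(x)
}
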