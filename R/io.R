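#' Load a labelled image/mask dataset from a directory
#'
#' Accepts either a manifest layout (`manifest.csv` with columns
#' `image,mask,label` plus `classes.txt`, as written by [write_dataset()]) or
#' a per-class layout (`<dir>/<ClassName>/images/*.png` with parallel
#' `<dir>/<ClassName>/masks/*.png`; class order from `classes.txt` when
#' present, else sorted folder names). Images are rescaled to [0, 1] on load
#' (division by the per-image maximum); masks are binarized at 128 on the
#' 0-255 scale, tolerating mild compression artifacts in nominally {0, 255}
#' mask files.
#'
#' @param path Dataset directory.
#' @return A `phantom_dataset`-shaped list: `samples` (each with `image` in
#'   [0, 1], `mask` in {0, 1}, `label`), `manifest`, `class_names`.
#' @export
load_dataset_dir <- function(path) {
  if (!dir.exists(path)) stopf("dataset directory %s does not exist", path)
  man_path <- file.path(path, "manifest.csv")
  if (file.exists(man_path)) {
    man <- tibble::as_tibble(read.csv(man_path, stringsAsFactors = FALSE))
    cls_path <- file.path(path, "classes.txt")
    class_names <- if (file.exists(cls_path)) readLines(cls_path)
      else paste0("class_", sort(unique(man$label)))
    rows <- seq_len(nrow(man))
    ipaths <- file.path(path, man$image)
    mpaths <- file.path(path, man$mask)
    labels <- as.integer(man$label)
  } else {
    subdirs <- list.dirs(path, recursive = FALSE, full.names = FALSE)
    subdirs <- subdirs[dir.exists(file.path(path, subdirs, "images"))]
    if (length(subdirs) == 0)
      stopf("%s has neither a manifest.csv nor per-class image folders", path)
    cls_path <- file.path(path, "classes.txt")
    class_names <- if (file.exists(cls_path)) readLines(cls_path) else sort(subdirs)
    missing_cls <- setdiff(subdirs, class_names)
    if (length(missing_cls) > 0)
      stopf("folders not listed in classes.txt: %s", toString(missing_cls))
    ipaths <- character(0); mpaths <- character(0); labels <- integer(0)
    for (cls in subdirs) {
      imgs <- sort(list.files(file.path(path, cls, "images"), pattern = "\\.png$"))
      ip <- file.path(path, cls, "images", imgs)
      mp <- file.path(path, cls, "masks", imgs)
      absent <- !file.exists(mp)
      if (any(absent))
        stopf("images without masks under %s: %s", cls,
              toString(imgs[absent]))
      ipaths <- c(ipaths, ip); mpaths <- c(mpaths, mp)
      labels <- c(labels, rep(match(cls, class_names) - 1L, length(ip)))
    }
    man <- tibble::tibble(image = ipaths, mask = mpaths, label = labels)
  }
  samples <- lapply(seq_along(ipaths), function(i) {
    if (!file.exists(ipaths[i])) stopf("row %d: missing image file %s", i, ipaths[i])
    if (!file.exists(mpaths[i])) stopf("row %d: missing mask file %s", i, mpaths[i])
    if (labels[i] < 0 || labels[i] >= length(class_names))
      stopf("row %d: label %d outside classes.txt range 0..%d", i, labels[i],
            length(class_names) - 1)
    img <- rescale_image(read_png_gray(ipaths[i]) * 255)
    msk <- (read_png_gray(mpaths[i]) * 255 >= 128) + 0L
    structure(list(image = img, mask = msk, label = labels[i], params = NULL),
              class = "phantom_sample")
  })
  structure(list(samples = samples, manifest = man, class_names = class_names),
            class = "phantom_dataset")
}

#' Save / load a self-describing model checkpoint
#'
#' `save_checkpoint()` writes the weights plus a `config.json` echoing the
#' full architecture, so a checkpoint directory can be reloaded without any
#' other context. `load_checkpoint()` rebuilds the `munet_model`.
#'
#' @param model A `munet_model`.
#' @param dir Checkpoint directory (created if needed).
#' @return `save_checkpoint()` returns `dir` invisibly; `load_checkpoint()`
#'   returns the model.
#' @export
save_checkpoint <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(model$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(list(params = model$params, bn = model$bn),
          file.path(dir, "weights.rds"))
  invisible(dir)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(dir) {
  cfg_path <- file.path(dir, "config.json")
  w_path <- file.path(dir, "weights.rds")
  if (!file.exists(cfg_path) || !file.exists(w_path))
    stopf("%s is not a checkpoint directory (needs config.json and weights.rds)", dir)
  cj <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
  cfg <- architecture_config(depth_E = cj$depth_E, base_filters_F = cj$base_filters_F,
                             input_size = cj$input_size, seg_classes = cj$seg_classes,
                             cls_classes = cj$cls_classes,
                             decoder_activation = cj$decoder_activation,
                             leaky_alpha = cj$leaky_alpha, elu_alpha = cj$elu_alpha,
                             dense_units = cj$dense_units)
  w <- readRDS(w_path)
  # restore array dims dropped by nothing here (rds keeps them), just rewrap
  structure(list(config = cfg, params = w$params, bn = w$bn),
            class = "munet_model")
}

# Polynomial rolling checksum of a serialized config; fingerprints configs
# in run logs (not cryptographic).
config_hash <- function(obj) {
  s <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = 10)
  h <- 17
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
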