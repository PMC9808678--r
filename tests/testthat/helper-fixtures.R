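# Shared fixtures and independent oracles for the suite.

# Naive double-loop pixel-counting oracle for segmentation metrics: walks
# every pixel with explicit loops, independent of confusion_counts().
oracle_seg_metrics <- function(pred, true) {
  tp <- 0; tn <- 0; fp <- 0; fn <- 0
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      p <- pred[i, j]; t <- true[i, j]
      if (p == 1 && t == 1) tp <- tp + 1
      else if (p == 0 && t == 0) tn <- tn + 1
      else if (p == 1 && t == 0) fp <- fp + 1
      else fn <- fn + 1
    }
  }
  list(
    dice = if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn),
    iou = if (tp + fp + fn == 0) 1 else tp / (tp + fp + fn),
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    tp = tp, tn = tn, fp = fp, fn = fn)
}

# Connected-component size of the largest TRUE region (4-neighbour BFS);
# used to verify the focal-lesion contract.
largest_component <- function(m) {
  visited <- matrix(FALSE, nrow(m), ncol(m))
  best <- 0
  for (si in seq_len(nrow(m))) for (sj in seq_len(ncol(m))) {
    if (!m[si, sj] || visited[si, sj]) next
    queue <- list(c(si, sj)); visited[si, sj] <- TRUE; size <- 0
    while (length(queue) > 0) {
      p <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
      size <- size + 1
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        q <- p + d
        if (q[1] >= 1 && q[1] <= nrow(m) && q[2] >= 1 && q[2] <= ncol(m) &&
            m[q[1], q[2]] && !visited[q[1], q[2]]) {
          visited[q[1], q[2]] <- TRUE
          queue[[length(queue) + 1]] <- q
        }
      }
    }
    best <- max(best, size)
  }
  best
}

# Small model + dataset for fast training-loop tests (32x32, 2 encoder
# blocks, 4-filter base).
tiny_setup <- function(n = 20, seed = 3, n_classes = 2) {
  ds <- generate_dataset(n, class_proportions = rep(1 / n_classes, n_classes),
                         size = c(32, 32), seed = seed)
  cfg <- architecture_config(depth_E = 2, base_filters_F = 4,
                             input_size = c(32, 32), cls_classes = n_classes)
  list(ds = ds, cfg = cfg)
}

tiny_protocol <- function(...) {
  args <- list(test_fraction = 0.2, val_fraction = 0.2, session_size = 12,
               n_sessions = 1, epochs_per_session = 1, batch_size = 6, seed = 9)
  over <- list(...)
  args[names(over)] <- over
  do.call(training_protocol, args)
}
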