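# Internal helpers: seeding, validation, small numerics.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic per-item seed derived from a master seed: a Lehmer-style
# mix evaluated exactly in doubles (all intermediates < 2^53), result in
# [1, 2^31 - 2] so it is always a valid `set.seed()` argument.
derive_seed <- function(master, index) {
  m <- 2147483647
  s <- ((master %% m) * 48271) %% m
  s <- (s + (index %% m) * 16807 + 12345) %% m
  as.integer(s %% (m - 1) + 1)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_binary_mask <- function(x, what = "mask") {
  if (!all(x %in% c(0, 1))) stopf("%s must contain only 0 and 1", what)
  invisible(x)
}

check_same_shape <- function(a, b, what = "arrays") {
  da <- dim(a) %||% length(a)
  db <- dim(b) %||% length(b)
  if (!identical(da, db))
    stopf("%s must have identical shape (%s vs %s)", what,
          paste(da, collapse = "x"), paste(db, collapse = "x"))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Bilinear upsampling of a matrix to (H, W) with corner-aligned sampling.
bilinear_resize <- function(m, H, W) {
  h <- nrow(m); w <- ncol(m)
  if (h == H && w == W) return(m)
  ri <- if (H == 1) rep(1, 1) else seq(1, h, length.out = H)
  ci <- if (W == 1) rep(1, 1) else seq(1, w, length.out = W)
  r0 <- pmin(floor(ri), h - 1L); r0[r0 < 1] <- 1
  c0 <- pmin(floor(ci), w - 1L); c0[c0 < 1] <- 1
  fr <- ri - r0; fc <- ci - c0
  if (h == 1) { r0 <- rep(1, H); fr <- rep(0, H) }
  if (w == 1) { c0 <- rep(1, W); fc <- rep(0, W) }
  a <- m[r0, c0, drop = FALSE]; b <- m[pmin(r0 + 1, h), c0, drop = FALSE]
  cc <- m[r0, pmin(c0 + 1, w), drop = FALSE]; d <- m[pmin(r0 + 1, h), pmin(c0 + 1, w), drop = FALSE]
  FR <- matrix(fr, H, W); FC <- matrix(fc, H, W, byrow = TRUE)
  a * (1 - FR) * (1 - FC) + b * FR * (1 - FC) + cc * (1 - FR) * FC + d * FR * FC
}
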