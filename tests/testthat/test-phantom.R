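test_that("phantom generation is deterministic in the seed and sensitive to it", {
  a <- generate_phantom(seed = 7, label = 0, size = c(64, 64))
  b <- generate_phantom(seed = 7, label = 0, size = c(64, 64))
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  expect_identical(a$params, b$params)
  d <- generate_phantom(seed = 8, label = 0, size = c(64, 64))
  expect_false(identical(a$image, d$image))
})

test_that("phantom samples satisfy the geometric invariants", {
  for (seed in c(1, 23, 99, 4321)) {
    for (label in 0:3) {
      s <- generate_phantom(seed, label, size = c(64, 64))
      expect_identical(dim(s$image), dim(s$mask))
      expect_true(all(s$mask %in% c(0, 1)))
      expect_gte(mean(s$mask), 0.10)
      expect_lte(mean(s$mask), 0.50)
      expect_true(all(s$image >= 0 & s$image <= 255))
      expect_true(all(s$image == round(s$image)))
      # mask is exactly the union of the two recorded ellipses
      expect_identical(s$mask, rasterize_lungs(s$params))
      # the two ellipses are disjoint
      left <- rasterize_lungs(list(ellipses = list(left = s$params$ellipses$left,
                                                   right = s$params$ellipses$left)),
                              size = s$params$size)
      right <- rasterize_lungs(list(ellipses = list(left = s$params$ellipses$right,
                                                    right = s$params$ellipses$right)),
                               size = s$params$size)
      expect_true(all(left + right <= 1))
    }
  }
})

test_that("phantom generation rejects invalid labels and sizes", {
  expect_error(generate_phantom(1, label = 4, size = c(64, 64)), "label")
  expect_error(generate_phantom(1, label = -1, size = c(64, 64)), "label")
  expect_error(generate_phantom(1, label = 0, size = c(16, 64)), "size")
})

test_that("class-conditional texture orders mean lung intensity", {
  wins_diffuse <- 0; wins_dense <- 0
  for (k in 1:100) {
    nrm <- generate_phantom(seed = 3000 + k, label = 0, size = c(64, 64))
    dif <- generate_phantom(seed = 3000 + k, label = 1, size = c(64, 64))
    den <- generate_phantom(seed = 3000 + k, label = 3, size = c(64, 64))
    m_n <- mean(nrm$image[nrm$mask == 1])
    m_dif <- mean(dif$image[dif$mask == 1])
    m_den <- mean(den$image[den$mask == 1])
    if (m_n < m_dif) wins_diffuse <- wins_diffuse + 1
    if (m_dif < m_den) wins_dense <- wins_dense + 1
  }
  expect_gte(wins_diffuse, 95)
  expect_gte(wins_dense, 95)
})

test_that("focal phantoms contain a connected bright region >= 2% of lung pixels", {
  for (k in 1:20) {
    s <- generate_phantom(seed = 7000 + k, label = 2, size = c(64, 64))
    bright <- s$image >= 150 & s$mask == 1
    expect_gte(largest_component(bright), ceiling(0.02 * sum(s$mask)))
  }
})

test_that("a mean-intensity threshold separates normal from dense-haze phantoms", {
  n <- 200
  means <- numeric(n); labs <- integer(n)
  for (i in seq_len(n)) {
    lab <- if (i %% 2 == 0) 0L else 3L
    s <- generate_phantom(seed = 11000 + i, label = lab, size = c(64, 64))
    means[i] <- mean(s$image[s$mask == 1])
    labs[i] <- lab
  }
  thr <- 100  # halfway between the normal (~60) and dense (~130) regimes
  acc <- mean((means > thr) == (labs == 3L))
  expect_gte(acc, 0.95)
})

test_that("largest-remainder apportionment matches hand enumeration", {
  expect_identical(apportion_counts(10, c(0.5, 0.5)), c(5L, 5L))
  expect_identical(apportion_counts(10, rep(0.25, 4)), c(3L, 3L, 2L, 2L))
  expect_identical(apportion_counts(1, 1.0), 1L)
  expect_identical(apportion_counts(7, c(0.6, 0.4)), c(4L, 3L))
  expect_error(apportion_counts(10, c(0.5, 0.4)), "sum to 1")
  set.seed(41)
  for (k in 1:20) {
    x <- runif(4); p <- x / sum(x)
    expect_identical(sum(apportion_counts(97, p)), 97L)
  }
})

test_that("generate_dataset apportions classes and is reproducible", {
  ds <- generate_dataset(10, class_proportions = rep(0.25, 4), seed = 2)
  expect_identical(as.integer(table(factor(ds$manifest$label, levels = 0:3))),
                   c(3L, 3L, 2L, 2L))
  expect_identical(nrow(ds$manifest), 10L)
  ds2 <- generate_dataset(10, class_proportions = rep(0.25, 4), seed = 2)
  expect_identical(lapply(ds$samples, `[[`, "image"),
                   lapply(ds2$samples, `[[`, "image"))
  ds3 <- generate_dataset(1, class_proportions = 1.0, seed = 2)
  expect_identical(ds3$samples[[1]]$label, 0L)
})

test_that("write_dataset / read_dataset round-trips losslessly", {
  ds <- generate_dataset(6, class_proportions = rep(0.25, 4), seed = 5)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_identical(nrow(read.csv(file.path(dir, "manifest.csv"))), 6L)
  back <- read_dataset(dir)
  for (i in 1:6) {
    expect_equal(back$samples[[i]]$image, unname(ds$samples[[i]]$image),
                 ignore_attr = TRUE)
    expect_equal(back$samples[[i]]$mask, ds$samples[[i]]$mask,
                 ignore_attr = TRUE)
    expect_identical(back$samples[[i]]$label, ds$samples[[i]]$label)
  }
  expect_identical(back$class_names, ds$class_names)
})

test_that("read_dataset names the offending row when a file is missing", {
  ds <- generate_dataset(3, class_proportions = rep(0.25, 4), seed = 6)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  file.remove(file.path(dir, ds$manifest$mask[2]))
  expect_error(read_dataset(dir), "row 2.*sample_0002")
})
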