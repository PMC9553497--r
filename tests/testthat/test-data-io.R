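test_that("random tiling stays in bounds, aligns image and mask, and is seeded", {
  H <- 600; W <- 700; size <- 512
  # coordinate-gradient image encodes absolute position in its channels
  img <- array(0, c(H, W, 3))
  img[, , 1] <- row(matrix(0, H, W)) / H
  img[, , 2] <- col(matrix(0, H, W)) / W
  mask <- (matrix(stats::runif(H * W), H, W) > 0.5) * 1
  tiles <- tile_image(img, mask, n_tiles = 5, size = size, seed = 3)
  expect_length(tiles, 5)
  for (tl in tiles) {
    sp <- tl$spec
    expect_gte(sp$top, 0); expect_lte(sp$top, H - size)
    expect_gte(sp$left, 0); expect_lte(sp$left, W - size)
    # gradient channels prove pixel alignment with the stated corner
    expect_equal(tl$image[1, 1, 1], (sp$top + 1) / H)
    expect_equal(tl$image[1, 1, 2], (sp$left + 1) / W)
    expect_equal(tl$mask, mask[sp$top + (1:size), sp$left + (1:size)])
  }
  t2 <- tile_image(img, mask, n_tiles = 5, size = size, seed = 3)
  expect_identical(lapply(tiles, `[[`, "spec"), lapply(t2, `[[`, "spec"))

  # image exactly the tile size: single valid position
  small <- array(runif(64 * 64 * 3), c(64, 64, 3))
  sm <- (matrix(runif(64 * 64), 64, 64) > 0.5) * 1
  for (tl in tile_image(small, sm, n_tiles = 3, size = 64, seed = 1)) {
    expect_identical(tl$image, small)
    expect_equal(tl$spec$top, 0)
  }
  expect_error(tile_image(small, sm, 4, size = 128), "smaller")
})

test_that("grid tiling covers the image deterministically", {
  img <- array(runif(96 * 80 * 3), c(96, 80, 3))
  mask <- matrix(0, 96, 80)
  tiles <- tile_image(img, mask, size = 64, mode = "grid")
  tops <- vapply(tiles, function(t) t$spec$top, numeric(1))
  lefts <- vapply(tiles, function(t) t$spec$left, numeric(1))
  expect_setequal(unique(tops), c(0, 32))
  expect_setequal(unique(lefts), c(0, 16))
  covered <- matrix(FALSE, 96, 80)
  for (tl in tiles) {
    covered[tl$spec$top + (1:64), tl$spec$left + (1:64)] <- TRUE
  }
  expect_true(all(covered))
})

test_that("resize_pair keeps masks binary and interpolates images", {
  img <- array(runif(40 * 30 * 3), c(40, 30, 3))
  mask <- (matrix(runif(40 * 30), 40, 30) > 0.5) * 1
  r <- resize_pair(img, mask, 32)
  expect_equal(dim(r$image), c(32L, 32L, 3L))
  expect_equal(dim(r$mask), c(32L, 32L))
  expect_true(all(r$mask %in% c(0, 1)))

  const <- array(0.4, c(24, 24, 3))
  rc <- resize_pair(const, NULL, 48)
  expect_lt(max(abs(rc$image - 0.4)), 1e-12)
})

test_that("small-component removal equals the flood-fill oracle and is idempotent", {
  m <- matrix(0, 30, 30)
  m[2:11, 2] <- 1                  # area 10
  m[15:24, 11:20] <- 1             # area 100
  out <- remove_small_components(m, 50)
  expect_equal(sum(out), 100)
  expect_equal(out[15:24, 11:20], matrix(1, 10, 10))

  set.seed(37)
  for (i in 1:20) {
    mm <- (matrix(runif(24 * 24), 24, 24) > 0.6) * 1
    ma <- sample(1:20, 1)
    got <- remove_small_components(mm, ma)
    expect_equal(got, bwareaopen_oracle(mm, ma))
    expect_equal(remove_small_components(got, ma), got)   # idempotent
  }
  expect_equal(remove_small_components(m, 1), m)           # identity
  empty <- matrix(0, 5, 5)
  expect_equal(remove_small_components(empty, 3), empty)
  # 8-connectivity: diagonal pixels form one component
  dg <- matrix(0, 5, 5); dg[1, 1] <- 1; dg[2, 2] <- 1
  expect_equal(sum(remove_small_components(dg, 2)), 2)
  expect_error(remove_small_components(matrix(0.3, 3, 3), 2), "binary")
})

test_that("dataset splits follow the documented rounding and are seeded", {
  s <- split_dataset(sprintf("im%02d", 1:10), seed = 2)
  expect_length(s$train_ids, 8)
  expect_length(s$val_ids, 1)
  expect_length(s$test_ids, 1)

  ids <- sprintf("img%03d", 1:398)
  s398 <- split_dataset(ids, seed = 5)
  expect_length(s398$train_ids, 320)
  expect_length(s398$val_ids, 39)
  expect_length(s398$test_ids, 39)
  all_ids <- c(s398$train_ids, s398$val_ids, s398$test_ids)
  expect_setequal(all_ids, ids)
  expect_equal(anyDuplicated(all_ids), 0L)

  expect_identical(split_dataset(ids, seed = 5), s398)
  expect_false(identical(split_dataset(ids, seed = 6), s398))
  expect_error(split_dataset(c("a", "b")), "at least 3")
  expect_error(split_dataset(ids, fractions = c(0.5, 0.2, 0.2)), "summing")
})

test_that("mask files round-trip and grey values are thresholded with a warning", {
  m <- (matrix(runif(20 * 20), 20, 20) > 0.5) * 1
  p <- tempfile(fileext = ".png")
  write_mask(m, p)
  expect_identical(read_mask(p), m)

  grey <- matrix(200 / 255, 4, 4)
  png::writePNG(grey, p)
  expect_warning(got <- read_mask(p), "grey")
  expect_equal(got, matrix(1, 4, 4))
  png::writePNG(matrix(1, 4, 4), p)
  expect_equal(read_mask(p), matrix(1, 4, 4))
  expect_error(write_mask(matrix(0.5, 2, 2), p), "binary")
  expect_error(read_mask(tempfile()), "cannot read")
  unlink(p)
})

test_that("images load from PNG and TIFF with alpha dropped", {
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  pp <- tempfile(fileext = ".png")
  png::writePNG(img, pp)
  expect_equal(read_image(pp), img, tolerance = 1e-2)

  pt <- tempfile(fileext = ".tiff")
  tiff::writeTIFF(img, pt)
  expect_equal(read_image(pt), img, tolerance = 1e-2)

  rgba <- array(runif(8 * 8 * 4), c(8, 8, 4))
  png::writePNG(rgba, pp)
  expect_warning(got <- read_image(pp), "alpha")
  expect_equal(dim(got), c(8L, 8L, 3L))
  unlink(c(pp, pt))
})

test_that("annotation bootstrap writes denoised masks and a complete manifest", {
  dir <- tempfile("boot")
  imgs <- file.path(tempdir(), sprintf("bs%02d.png", 1:3))
  for (p in imgs) {
    png::writePNG(array(runif(32 * 32 * 3), c(32, 32, 3)), p)
  }
  m <- dks_model(tiny_model_config())
  # force an all-background prediction: constant 0.5 fails the strict > 0.5
  m$store$params[["b2.head.W"]][] <- 0
  m$store$params[["b2.head.b"]][] <- 0
  mf <- annotation_bootstrap(m, c(imgs, tempfile("missing")), dir,
                             min_area = 10)
  expect_equal(nrow(mf), 4)
  expect_equal(sum(mf$status == "ok"), 3)
  expect_equal(sum(mf$status == "skipped"), 1)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  for (mp in mf$mask[mf$status == "ok"]) {
    expect_equal(max(read_mask(mp)), 0)   # all-zero model output
  }
  unlink(dir, recursive = TRUE); unlink(imgs)
})
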