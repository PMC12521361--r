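test_that("otsu threshold separates a bimodal image", {
  v <- c(rep(10, 60), rep(200, 40))
  thr <- otsu_threshold(v)
  expect_gt(thr, 10)
  expect_lt(thr, 200)
  expect_identical(v > thr, v == 200)
  expect_error(otsu_threshold(rep(3, 10)), "constant")
})

test_that("otsu threshold matches the exhaustive brute-force oracle", {
  set.seed(101)
  for (i in 1:5) {
    v <- sample(0:255, 4000, replace = TRUE,
                prob = dnorm(0:255, sample(c(60, 180), 1), 30) + 0.2 / 256)
    expect_equal(otsu_threshold(v), oracle_otsu(v))
  }
  # trimodal image with ties broken toward the lower threshold
  v3 <- rep(c(0, 128, 255), times = c(100, 100, 100))
  expect_equal(otsu_threshold(v3), oracle_otsu(v3))
})

test_that("otsu threshold agrees with EBImage on a continuous image", {
  set.seed(7)
  img <- matrix(c(rnorm(6000, 0.3, 0.05), rnorm(4000, 0.7, 0.05)), 100, 100)
  img <- pmin(pmax(img, 0), 1)
  thr <- otsu_threshold(img)
  thr_eb <- EBImage::otsu(EBImage::Image(img), range = range(img))
  # binning details differ between implementations; both must land in the
  # valley between the two modes
  expect_lt(abs(thr - thr_eb), 8 * diff(range(img)) / 256)
  expect_gt(thr, 0.35); expect_lt(thr, 0.65)
})

test_that("largest_component keeps only the biggest blob", {
  m <- array(FALSE, c(20, 20, 20))
  m[2:12, 2:12, 2:12] <- TRUE       # 1331 voxels
  m[16:17, 16:17, 16:18] <- TRUE    # 12 voxels
  out <- largest_component(m)
  expect_equal(sum(out), 11^3)
  expect_false(any(out[16:17, 16:17, 16:18]))
  single <- array(FALSE, c(5, 5, 5)); single[2:3, 2:3, 2:3] <- TRUE
  expect_identical(largest_component(single), single)
  expect_error(largest_component(array(FALSE, c(4, 4, 4))), "empty")
})

test_that("largest_component agrees with a flood-fill oracle", {
  set.seed(33)
  m <- array(runif(16^3) > 0.72, c(16, 16, 16))
  lab <- oracle_components(m)
  sizes <- tabulate(lab[lab > 0])
  expect_identical(unname(largest_component(m)),
                   unname(lab == which.max(sizes)))
})

test_that("prepare_slices crops, normalizes and resizes consistently", {
  set.seed(5)
  arr <- array(runif(40 * 40 * 6, 0.2, 0.8), c(40, 40, 6))
  arr[15:30, 10:25, ] <- runif(16 * 16 * 6, 0.85, 1.0)
  vol <- image_volume(arr, 0.01)
  mask <- array(FALSE, dim(arr)); mask[15:30, 10:25, ] <- TRUE
  sl <- prepare_slices(vol, mask, size = 64L)
  expect_length(sl, 6)
  expect_identical(dim(sl[[1]]$pixels), c(64L, 64L))
  expect_true(all(vapply(sl, function(s) min(s$pixels) >= 0, logical(1))))
  expect_true(all(vapply(sl, function(s) max(s$pixels) <= 1, logical(1))))
  expect_equal(sl[[3]]$z_mm, 2 * 0.01)
  expect_equal(sl[[3]]$source_index, 2L)
})

test_that("bilinear resize matches direct interpolation at mapped points", {
  img <- outer(seq(0, 1, length.out = 8), seq(0, 2, length.out = 8), `+`)
  out <- tibiamorph:::`.cpp_resize_bilinear`(img, 16L, 16L)
  # direct evaluation: output pixel centre (i + 0.5) maps to input
  # coordinate (i + 0.5) * (in/out) - 0.5 (0-based)
  direct <- matrix(0, 16, 16)
  for (i in 1:16) for (j in 1:16) {
    u <- min(max((i - 0.5) * 8 / 16 - 0.5, 0), 7)
    v <- min(max((j - 0.5) * 8 / 16 - 0.5, 0), 7)
    x0 <- floor(u); y0 <- floor(v)
    x1 <- min(x0 + 1, 7); y1 <- min(y0 + 1, 7)
    fx <- u - x0; fy <- v - y0
    direct[i, j] <- img[x0 + 1, y0 + 1] * (1 - fx) * (1 - fy) +
      img[x1 + 1, y0 + 1] * fx * (1 - fy) +
      img[x0 + 1, y1 + 1] * (1 - fx) * fy + img[x1 + 1, y1 + 1] * fx * fy
  }
  expect_equal(out, direct, tolerance = 1e-12)
})

test_that("degenerate (constant) crops yield all-zero slices with a warning", {
  arr <- array(0.5, c(10, 10, 1))
  mask <- array(FALSE, dim(arr)); mask[2:8, 2:8, ] <- TRUE
  vol <- image_volume(arr, 0.01)
  expect_warning(sl <- prepare_slices(vol, mask, size = 16L), "constant")
  expect_true(all(sl[[1]]$pixels == 0))
})

test_that("preprocessing is idempotent up to interpolation identity", {
  set.seed(9)
  arr <- array(runif(30 * 30 * 4), c(30, 30, 4))
  vol <- image_volume(arr, 0.01)
  mask <- array(TRUE, dim(arr))
  s1 <- prepare_slices(vol, mask, size = 30L)
  arr2 <- array(unlist(lapply(s1, `[[`, "pixels")), c(30, 30, 4))
  s2 <- prepare_slices(image_volume(arr2, 0.01), mask, size = 30L)
  expect_equal(s2[[2]]$pixels, s1[[2]]$pixels, tolerance = 1e-10)
})

test_that("volume readers round-trip written files", {
  set.seed(2)
  arr <- array(runif(12 * 10 * 5), c(12, 10, 5))
  vol <- image_volume(arr, 0.007)
  tmp <- withr::local_tempdir()
  mhd <- file.path(tmp, "v.mhd")
  write_mhd(vol, mhd)
  back <- read_volume(mhd)
  expect_equal(back$voxel_size_mm, 0.007)
  expect_equal(back$intensities, arr, tolerance = 1e-6)
  tif <- file.path(tmp, "v.tif")
  write_volume_tiff(vol, tif)
  back2 <- read_volume(tif, voxel_size_mm = 0.007)
  expect_equal(back2$intensities, arr, tolerance = 1 / 65535)
  expect_error(read_volume(file.path(tmp, "missing.mhd")), "exist")
})

test_that("slice stacks load in filename order with index-z arithmetic", {
  tmp <- withr::local_tempdir()
  for (k in 1:4) {
    png::writePNG(matrix(k / 10, 8, 8), file.path(tmp, sprintf("s%03d.png", k)))
  }
  vol <- read_volume(tmp, voxel_size_mm = 0.005)
  expect_identical(dim(vol$intensities), c(8L, 8L, 4L))
  expect_lt(abs(vol$intensities[1, 1, 3] - 0.3), 1 / 254)
  expect_equal(slice_z_mm(vol, 120), 0.6)
  # mixed shapes are rejected with the offending file named
  png::writePNG(matrix(0.5, 7, 8), file.path(tmp, "s999.png"))
  expect_error(read_volume(tmp, voxel_size_mm = 0.005), "s999")
})

test_that("uncompressed 8-bit BMP slices are read correctly", {
  tmp <- withr::local_tempdir()
  path <- file.path(tmp, "s001.bmp")
  w <- 6L; h <- 4L
  px <- matrix(as.integer(row(matrix(0, h, w)) * 10 +
                            col(matrix(0, h, w))), h, w)
  con <- file(path, "wb")
  row_bytes <- ((w + 3) %/% 4) * 4
  img_size <- row_bytes * h
  writeBin(as.raw(c(0x42, 0x4D)), con)
  writeBin(c(14L + 40L + 1024L + img_size, 0L), con, size = 4,
           endian = "little")
  writeBin(14L + 40L + 1024L, con, size = 4, endian = "little")
  writeBin(40L, con, size = 4, endian = "little")       # BITMAPINFOHEADER
  writeBin(c(w, h), con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")        # planes
  writeBin(8L, con, size = 2, endian = "little")        # bpp
  writeBin(c(0L, img_size, 2835L, 2835L, 256L, 0L), con, size = 4,
           endian = "little")
  for (i in 0:255) writeBin(as.raw(c(i, i, i, 0)), con) # grayscale palette
  for (r in h:1) {                                      # bottom-up rows
    writeBin(as.raw(c(px[r, ], rep(0, row_bytes - w))), con)
  }
  close(con)
  img <- tibiamorph:::read_slice_image(path)            # [x, y]
  expect_identical(dim(img), c(w, h))
  # pixel at image row r (from top), column c has value r*10 + c
  expect_equal(img[3, 2], (2 * 10 + 3) / 255)
  expect_equal(img[1, 4], (4 * 10 + 1) / 255)
})
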