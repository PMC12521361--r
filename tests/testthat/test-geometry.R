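test_that("VOI presets encode the standard anchors and heights", {
  ep <- voi_spec("epiphyseal")
  expect_equal(ep$reference, "Z_eg")
  expect_equal(ep$offset_mm, -0.25)
  expect_equal(ep$height_mm, 0.25)
  mx <- voi_spec("mixed_primary_secondary")
  expect_equal(mx$reference, "Z_gp")
  expect_equal(mx$height_mm, 1.0)
  fo <- voi_spec("fixed_offset", offset_mm = 0.125)
  expect_equal(fo$reference, "Z_gp")
  expect_equal(fo$offset_mm, 0.125)
})

test_that("VOI extraction uses half-open intervals with rounded slice counts", {
  arr <- array(runif(4 * 4 * 400), c(4, 4, 400))
  vol <- image_volume(arr, 0.005)
  lms <- landmark_set(Z_eg = 0.5, Z_gp = 0.6, Z_ps = 0.9)
  voi <- extract_voi(vol, lms, voi_spec("secondary"))
  expect_equal(voi$slice_range, c(181L, 380L))  # 0-based [180, 380)
  expect_equal(dim(voi$volume)[3], 200L)
  # fixed offset 0.25 from Z_gp = 0.6 -> [0.85, 1.85)
  voi2 <- extract_voi(vol, lms, voi_spec("fixed_offset", offset_mm = 0.25))
  expect_equal(voi2$z_start_mm, 0.85)
  expect_equal(voi2$z_end_mm, 1.85)
  # adjacent VOIs sharing Z_gp never overlap (half-open)
  mixed <- extract_voi(vol, lms, voi_spec("mixed_primary_secondary"))
  epi <- extract_voi(vol, lms, voi_spec("epiphyseal"))
  expect_equal(epi$slice_range, c(51L, 100L))   # [0.25, 0.5)
  expect_lt(epi$slice_range[2], mixed$slice_range[1])
  # out-of-range and absent-landmark errors
  expect_error(extract_voi(vol, landmark_set(Z_eg = 0.10), voi_spec("epiphyseal")),
               "z-range")
  expect_error(extract_voi(vol, landmark_set(Z_eg = 0.5), voi_spec("secondary")),
               "absent")
})

test_that("alignment of an already-aligned phantom is near identity", {
  spec <- phantom_preset("coarse", lateral_extent_mm = 1.5, seed = 21)
  ph <- generate_phantom(spec)
  seg <- segment_bone(ph$volume)
  al <- align_tibia(ph$volume, seg$mask)
  ang <- acos(min(1, (sum(diag(al$rotation)) - 1) / 2)) * 180 / pi
  expect_lt(ang, 1)
})

test_that("alignment recovers a known rigid misalignment within 2 degrees", {
  spec <- phantom_preset("coarse", lateral_extent_mm = 1.5, seed = 21,
                         rigid_misalignment = list(
                           tilt_deg = 10, inplane_rotation_deg = 30))
  ph <- generate_phantom(spec)
  seg <- segment_bone(ph$volume)
  al <- align_tibia(ph$volume, seg$mask)
  comp <- al$rotation %*% ph$truth$applied_transform
  ang <- acos(min(1, (sum(diag(comp)) - 1) / 2)) * 180 / pi
  expect_lt(ang, 2)
})

test_that("isotropic masks have no principal direction", {
  n <- 30
  idx <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
  ball <- array((idx$x - 15.5)^2 + (idx$y - 15.5)^2 + (idx$z - 15.5)^2 <= 12^2,
                c(n, n, n))
  vol <- image_volume(array(as.numeric(ball), dim(ball)), 0.01)
  expect_error(align_tibia(vol, ball), "principal direction")
})

test_that("substitute segmentation separates cortex from interior specks", {
  nx <- 60
  arr <- array(0.05, c(nx, nx, 6))
  ctr <- (nx + 1) / 2
  r <- sqrt(outer((1:nx - ctr)^2, (1:nx - ctr)^2, `+`))
  ring <- r <= 25 & r >= 20
  specks <- array(FALSE, c(nx, nx))
  specks[cbind(c(25, 35, 30), c(30, 28, 36))] <- TRUE
  for (k in 1:6) arr[, , k][ring | specks] <- 1.0
  masks <- medullary_and_trabecular_masks(arr)
  expect_equal(sum(masks$trabecular), 6 * sum(specks))  # specks retained
  expect_false(any(masks$trabecular & array(ring, dim(arr))))  # cortex removed
  expect_true(all(masks$medullary[array(r <= 19, c(nx, nx, 6))]))
})

test_that("solid cross-sections yield an empty trabecular mask with warning", {
  nx <- 40
  arr <- array(0.05, c(nx, nx, 3))
  r <- sqrt(outer((1:nx - 20.5)^2, (1:nx - 20.5)^2, `+`))
  disk <- r <= 15
  for (k in 1:3) arr[, , k][disk] <- 1.0
  expect_warning(masks <- medullary_and_trabecular_masks(arr), "empty|no bone")
  expect_equal(sum(masks$trabecular), 0)
})

test_that("external masks pass through clipped to the VOI", {
  ph <- generate_phantom(phantom_preset("test", seed = 8))
  tl <- ph$truth$true_landmarks
  voi <- extract_voi(ph$volume, tl, voi_spec("secondary", height_mm = 0.4),
                     masks = list(trab = ph$truth$trabecular_mask,
                                  med = ph$truth$medullary_mask))
  out <- medullary_and_trabecular_masks(voi$volume,
                                        external_trabecular = voi$masks$trab,
                                        external_medullary = voi$masks$med)
  expect_identical(out$trabecular, voi$masks$trab)
  expect_identical(out$medullary, voi$masks$med)
})
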