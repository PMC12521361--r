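# logistic 4-class profile with transitions at k1 < k2 < k3 (slice units)
logistic_profile <- function(n, k1, k2, k3, s, voxel = 0.005) {
  z <- seq_len(n) - 1
  sig <- function(k) 1 / (1 + exp(-(k - z) / s))
  P <- cbind(sig(k1), sig(k2) - sig(k1), sig(k3) - sig(k2), 1 - sig(k3))
  P <- pmax(P, 1e-12)
  probability_profile(P / rowSums(P), voxel)
}

test_that("rolling median smoothing matches the naive oracle", {
  set.seed(4)
  P <- matrix(runif(200 * 4), 200, 4)
  P <- P / rowSums(P)
  prof <- probability_profile(P, 0.005)
  sm <- smooth_profile(prof, landmark_config(smoothing_window_mm = 0.025))
  # window 0.025 mm / 0.005 mm = 5 slices -> half-width 2
  for (cl in 1:4) {
    raw <- oracle_rolling_median(P[, cl], 2L)
    smoothed_raw <- t(apply(cbind(
      oracle_rolling_median(P[, 1], 2L), oracle_rolling_median(P[, 2], 2L),
      oracle_rolling_median(P[, 3], 2L), oracle_rolling_median(P[, 4], 2L)),
      1, function(r) r / sum(r)))
    expect_equal(tibiamorph:::profile_matrix(sm)[, cl], smoothed_raw[, cl],
                 tolerance = 1e-12)
  }
})

test_that("smoothing leaves constants alone and removes singleton spikes", {
  P <- matrix(rep(c(0.7, 0.1, 0.1, 0.1), each = 50), 50, 4)
  prof <- probability_profile(P, 0.005)
  sm <- smooth_profile(prof, landmark_config(smoothing_window_mm = 0.015))
  expect_equal(unname(tibiamorph:::profile_matrix(sm)), P,
               tolerance = 1e-12)
  Pspike <- P
  Pspike[25, ] <- c(0, 1, 0, 0)
  sm2 <- smooth_profile(probability_profile(Pspike, 0.005),
                        landmark_config(smoothing_window_mm = 0.015))
  expect_equal(unname(tibiamorph:::profile_matrix(sm2)[25, ]),
               unname(P[25, ]), tolerance = 1e-12)
})

test_that("a hard step crossing interpolates to the slice midpoint", {
  P <- matrix(0, 200, 4)
  P[1:100, 1] <- 1; P[101:200, 2] <- 1
  # keep rows normalized; give remaining classes presence further distal so
  # detection does not flag them (only the Z_eg crossing is asserted)
  prof <- probability_profile(P + 1e-12, 0.005)
  attr(prof, "smoothed") <- TRUE
  lm <- suppressWarnings(detect_landmarks(prof))
  expect_equal(lm$Z_eg, 0.4975, tolerance = 1e-9)
})

test_that("logistic crossings are recovered within half a voxel", {
  for (s in c(2, 4)) {
    prof <- logistic_profile(400, 80, 160, 260, s)
    sm <- smooth_profile(prof)
    lm <- detect_landmarks(sm)
    expect_lt(abs(lm$Z_eg - 80 * 0.005), 0.5 * 0.005)
    expect_lt(abs(lm$Z_gp - 160 * 0.005), 0.5 * 0.005)
    expect_lt(abs(lm$Z_ps - 260 * 0.005), 0.5 * 0.005)
    expect_true(lm$Z_eg < lm$Z_gp && lm$Z_gp < lm$Z_ps)
  }
})

test_that("landmarks are translation-equivariant", {
  prof_long <- logistic_profile(500, 120, 200, 300, 3)
  P <- tibiamorph:::profile_matrix(prof_long)
  a <- probability_profile(P[1:400, ], 0.005)
  b <- probability_profile(P[21:420, ], 0.005)  # shifted by 20 slices
  la <- detect_landmarks(smooth_profile(a))
  lb <- detect_landmarks(smooth_profile(b))
  for (nm in c("Z_eg", "Z_gp", "Z_ps"))
    expect_equal(lb[[nm]], la[[nm]] - 20 * 0.005, tolerance = 1e-9)
})

test_that("isolated label noise moves landmarks by at most a window width", {
  prof <- logistic_profile(400, 80, 160, 260, 3)
  base <- detect_landmarks(smooth_profile(prof))
  P <- tibiamorph:::profile_matrix(prof)
  set.seed(77)
  noisy_idx <- sample(setdiff(1:400, c(75:85, 155:165, 255:265)), 4)
  P[noisy_idx, ] <- matrix(rep(c(0, 0, 1, 0), each = 4), 4)
  noisy <- detect_landmarks(smooth_profile(probability_profile(P, 0.005)))
  w <- 0.05
  for (nm in c("Z_eg", "Z_gp", "Z_ps"))
    expect_lt(abs(noisy[[nm]] - base[[nm]]), w)
})

test_that("absent primary spongiosa triggers the Z_gs fallback", {
  # three-compartment profile: epiphysis -> growth plate -> secondary
  z <- 0:299
  sig <- function(k) 1 / (1 + exp(-(k - z) / 3))
  P <- cbind(sig(80), sig(180) - sig(80), 0, 1 - sig(180))
  P <- pmax(P, 1e-12); P <- P / rowSums(P)
  prof <- probability_profile(P, 0.005)
  res <- detect_absent_compartments(smooth_profile(prof))
  expect_true(2L %in% res$absent)
  lm <- res$landmarks
  expect_null(lm$Z_gp)
  expect_null(lm$Z_ps)
  expect_lt(abs(lm$Z_gs - 180 * 0.005), 0.01)
  # fully present profile has an empty absent set
  full <- detect_absent_compartments(
    smooth_profile(logistic_profile(400, 80, 160, 260, 3)))
  expect_length(full$absent, 0)
})

test_that("landmark ordering violations raise an error state", {
  expect_error(landmark_set(Z_eg = 0.9, Z_gp = 0.6, Z_ps = 0.5), "ordering")
})

test_that("unsmoothed profiles are flagged", {
  prof <- logistic_profile(100, 20, 50, 80, 2)
  expect_warning(detect_landmarks(prof), "smooth")
})
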