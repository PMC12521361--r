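#' Per-slice class-probability profile
#'
#' A matrix of class probabilities (columns `p0`..`p3` for epiphyseal bone,
#' growth plate, primary spongiosa, secondary spongiosa) over z slices
#' ordered proximal to distal, with the voxel size attached so slice indices
#' convert to mm.
#'
#' @param P numeric matrix (slices x 4); rows must sum to 1 within 1e-6.
#' @param voxel_size_mm voxel size in mm.
#' @return A data frame of class `probability_profile` with columns
#'   `z_index` (0-based), `z_mm`, `p0`..`p3`.
#' @export
probability_profile <- function(P, voxel_size_mm) {
  P <- as.matrix(P)
  if (ncol(P) != 4) stopf("profile must have 4 class columns")
  if (nrow(P) < 1) stopf("profile must contain at least one slice")
  bad <- abs(rowSums(P) - 1) > 1e-6
  if (any(bad)) stopf("%d profile row(s) do not sum to 1", sum(bad))
  out <- data.frame(z_index = seq_len(nrow(P)) - 1L,
                    z_mm = (seq_len(nrow(P)) - 1L) * voxel_size_mm,
                    p0 = P[, 1], p1 = P[, 2], p2 = P[, 3], p3 = P[, 4])
  attr(out, "voxel_size_mm") <- voxel_size_mm
  attr(out, "smoothed") <- FALSE
  class(out) <- c("probability_profile", "data.frame")
  out
}

profile_matrix <- function(profile) {
  as.matrix(profile[, c("p0", "p1", "p2", "p3")])
}

#' Landmark detection configuration
#'
#' @param smoothing_window_mm rolling-median window (default 0.05 mm).
#' @param absence_threshold a compartment whose probability never reaches
#'   this value anywhere along z is declared absent (default 0.5, i.e. the
#'   compartment must be the majority class somewhere).
#' @param crossing_margin a sign change of the probability difference only
#'   counts as a landmark crossing if the difference subsequently reaches
#'   this magnitude on the far side (within `crossing_horizon_mm` in the
#'   scan direction); equality wobbles from residual misclassification
#'   noise, where neither compartment ever clearly dominates, are skipped.
#'   If no crossing qualifies the bare first crossing is used.
#' @param crossing_horizon_mm look-ahead distance for the margin check
#'   (default twice the smoothing window).
#' @return A `landmark_config` list.
#' @export
landmark_config <- function(smoothing_window_mm = 0.05,
                            absence_threshold = 0.5,
                            crossing_margin = 0.2,
                            crossing_horizon_mm = 2 * smoothing_window_mm) {
  if (smoothing_window_mm <= 0) stopf("smoothing window must be > 0")
  if (absence_threshold <= 0 || absence_threshold >= 1)
    stopf("absence_threshold must be in (0,1)")
  if (crossing_margin < 0 || crossing_margin >= 1)
    stopf("crossing_margin must be in [0,1)")
  structure(list(smoothing_window_mm = smoothing_window_mm,
                 absence_threshold = absence_threshold,
                 crossing_margin = crossing_margin,
                 crossing_horizon_mm = crossing_horizon_mm),
            class = "landmark_config")
}

#' Transitional landmark set
#'
#' Axial positions (mm, z = 0 proximal) of the transitional interfaces:
#' `Z_eg` epiphysis/growth plate, `Z_gp` growth plate/primary spongiosa,
#' `Z_ps` primary/secondary spongiosa, and the fallback `Z_gs` growth
#' plate/secondary spongiosa used when the primary spongiosa is absent.
#' Absent landmarks are `NULL`; `absent_compartments` lists class codes
#' declared absent.
#'
#' @param Z_eg,Z_gp,Z_ps,Z_gs positions in mm or `NULL`.
#' @param absent_compartments integer class codes.
#' @return A `landmark_set`.
#' @export
landmark_set <- function(Z_eg = NULL, Z_gp = NULL, Z_ps = NULL, Z_gs = NULL,
                         absent_compartments = integer(0)) {
  if (!is.null(Z_eg) && !is.null(Z_gp) && !is.null(Z_ps)) {
    if (!(Z_eg < Z_gp && Z_gp < Z_ps))
      stopf("landmark ordering violated: Z_eg=%.4f, Z_gp=%.4f, Z_ps=%.4f",
            Z_eg, Z_gp, Z_ps)
  }
  structure(list(Z_eg = Z_eg, Z_gp = Z_gp, Z_ps = Z_ps, Z_gs = Z_gs,
                 absent_compartments = as.integer(absent_compartments)),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  fmt <- function(v) if (is.null(v)) "absent" else sprintf("%.4f mm", v)
  cat("<landmark_set>\n",
      " Z_eg:", fmt(x$Z_eg), "\n Z_gp:", fmt(x$Z_gp),
      "\n Z_ps:", fmt(x$Z_ps), "\n Z_gs:", fmt(x$Z_gs), "\n")
  if (length(x$absent_compartments))
    cat(" absent compartments:",
        paste(x$absent_compartments, collapse = ", "), "\n")
  invisible(x)
}

#' Rolling-median smoothing of a probability profile
#'
#' Applies a centered rolling median (window expressed in mm, converted to an
#' odd number of slices by rounding up) to each class column, shrinking the
#' window symmetrically at the profile edges, then re-normalizes each row to
#' sum 1 (column-wise medians need not preserve row sums; the re-normalization
#' is negligible in magnitude but keeps the profile a distribution).
#'
#' @param profile a [probability_profile].
#' @param config a [landmark_config()].
#' @return The smoothed [probability_profile].
#' @export
smooth_profile <- function(profile, config = landmark_config()) {
  vs <- attr(profile, "voxel_size_mm")
  w <- round(config$smoothing_window_mm / vs)
  if (w < 1) stopf("smoothing window shorter than one slice")
  if (w %% 2 == 0) w <- w + 1L  # force odd (round up)
  half <- (w - 1L) %/% 2L
  P <- profile_matrix(profile)
  n <- nrow(P)
  S <- P
  if (n > 1 && half > 0) {
    for (i in seq_len(n)) {
      h <- min(half, i - 1L, n - i)  # shrink symmetrically at the edges
      rows <- (i - h):(i + h)
      S[i, ] <- apply(P[rows, , drop = FALSE], 2, median)
    }
  }
  S <- S / rowSums(S)
  out <- probability_profile(S, vs)
  attr(out, "smoothed") <- TRUE
  out
}

# First sign change of d (positive to negative in scan order) over the
# indices in `ord`, returned as an interpolated 0-based fractional slice
# index, or NA. A crossing is accepted only if d reaches -margin within the
# next `horizon` scanned indices (the entered compartment must come to
# dominate); if no crossing qualifies, the first bare crossing is used.
first_crossing <- function(d, ord, margin = 0, horizon = 0L) {
  n_ord <- length(ord)
  qualifies <- function(j) {
    if (margin <= 0) return(TRUE)
    ahead <- ord[seq(j + 1L, min(n_ord, j + 1L + horizon))]
    min(d[ahead]) <= -margin
  }
  bare <- NA_real_
  for (j in seq_len(n_ord - 1L)) {
    i0 <- ord[j]; i1 <- ord[j + 1L]
    cand <- NA_real_
    if (d[i0] == 0) {
      cand <- i0 - 1
    } else if (d[i0] > 0 && d[i1] < 0) {
      # linear interpolation of the difference between the two slices
      frac <- d[i0] / (d[i0] - d[i1])
      cand <- (i0 - 1) + frac * (i1 - i0)
    } else if (d[i0] > 0 && d[i1] == 0) {
      cand <- i1 - 1
    }
    if (!is.na(cand)) {
      if (is.na(bare)) bare <- cand
      if (qualifies(j)) return(cand)
    }
  }
  last <- ord[n_ord]
  if (d[last] == 0 && is.na(bare)) bare <- last - 1
  bare
}

#' Detect transitional landmarks from a probability profile
#'
#' Implements the regional probability distribution rule: a landmark lies
#' where the probabilities of the two adjacent compartments are equal.
#' `Z_eg` is the first crossing of p(epiphysis) = p(growth plate) scanning
#' proximal to distal; `Z_ps` the first crossing of p(primary) = p(secondary)
#' scanning distal to proximal; `Z_gp` the first crossing of p(growth plate)
#' = p(primary) scanning proximal to distal inside the interval bounded by
#' `Z_eg` and `Z_ps`. Crossings are located at the first sign change of the
#' probability difference in the scan direction, with sub-slice positions by
#' linear interpolation of the difference (an exact zero at a slice yields
#' that slice's position).
#'
#' @param profile a smoothed [probability_profile] (a warning is emitted for
#'   unsmoothed input).
#' @param config a [landmark_config()].
#' @return A [landmark_set]; landmarks whose crossing is not found are
#'   absent. If [detect_absent_compartments()] declares the primary
#'   spongiosa absent the fallback `Z_gs` is returned instead of
#'   `Z_gp`/`Z_ps`.
#' @export
detect_landmarks <- function(profile, config = landmark_config()) {
  if (!isTRUE(attr(profile, "smoothed")))
    warnf("profile does not appear to be smoothed; landmark positions may be noisy")
  vs <- attr(profile, "voxel_size_mm")
  P <- profile_matrix(profile)
  n <- nrow(P)
  absent <- absent_compartments(P, config$absence_threshold)
  if (length(absent) > 2)
    stopf("more than two compartments absent (%s); profile is unusable",
          paste(absent, collapse = ", "))

  to_mm <- function(idx) if (is.na(idx)) NULL else idx * vs
  mar <- config$crossing_margin
  hor <- max(1L, round(config$crossing_horizon_mm / vs))

  Z_eg <- to_mm(first_crossing(P[, 1] - P[, 2], seq_len(n), mar, hor))
  if (2L %in% absent) {
    # no primary spongiosa: growth plate hands over to secondary directly
    Z_gs <- to_mm(first_crossing(P[, 2] - P[, 4], seq_len(n), mar, hor))
    return(landmark_set(Z_eg = Z_eg, Z_gs = Z_gs,
                        absent_compartments = absent))
  }
  # scanning distal to proximal the leading compartment is the secondary one
  idx_ps <- first_crossing(P[, 4] - P[, 3], rev(seq_len(n)), mar, hor)
  Z_ps <- to_mm(idx_ps)
  lo <- if (!is.null(Z_eg)) max(1L, ceiling(Z_eg / vs) + 1L) else 1L
  hi <- if (!is.na(idx_ps)) min(n, floor(idx_ps) + 1L) else n
  Z_gp <- if (lo < hi)
    to_mm(first_crossing(P[, 2] - P[, 3], lo:hi, mar, hor)) else NULL
  landmark_set(Z_eg = Z_eg, Z_gp = Z_gp, Z_ps = Z_ps,
               absent_compartments = absent)
}

absent_compartments <- function(P, threshold) {
  which(apply(P, 2, max) < threshold) - 1L
}

#' Detect absent compartments and fallback landmarks
#'
#' A compartment is declared absent when its probability never reaches the
#' absence threshold anywhere along z. If the primary spongiosa is absent,
#' `Z_gp` and `Z_ps` do not exist and the growth plate/secondary spongiosa
#' interface `Z_gs` (crossing of p(growth plate) = p(secondary)) is returned.
#'
#' @param profile a smoothed [probability_profile].
#' @param config a [landmark_config()].
#' @return List with `absent` (integer codes) and `landmarks` (a
#'   [landmark_set] including any fallback).
#' @export
detect_absent_compartments <- function(profile, config = landmark_config()) {
  P <- profile_matrix(profile)
  absent <- absent_compartments(P, config$absence_threshold)
  if (length(absent) > 2)
    stopf("more than two compartments absent (%s); profile is unusable",
          paste(absent, collapse = ", "))
  lm <- detect_landmarks(profile, config)
  list(absent = absent, landmarks = lm)
}
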