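#' Otsu threshold
#'
#' Computes the global threshold maximizing the between-class variance on a
#' 256-bin histogram of the input. Ties are broken toward the lower
#' threshold; the foreground is defined as values strictly above the
#' returned threshold.
#'
#' @param image numeric vector, matrix or array with at least two distinct
#'   values.
#' @param nbins number of histogram bins (default 256).
#' @return The threshold, on the intensity scale of the input.
#' @export
otsu_threshold <- function(image, nbins = 256L) {
  v <- as.numeric(image)
  v <- v[is.finite(v)]
  mn <- min(v); mx <- max(v)
  if (mn == mx) stopf("constant image: no threshold exists")
  edges <- seq(mn, mx, length.out = nbins + 1L)
  counts <- tabulate(pmin(findInterval(v, edges, rightmost.closed = TRUE),
                          nbins), nbins)
  centers <- (edges[-1] + edges[-(nbins + 1L)]) / 2
  p <- counts / sum(counts)
  w0 <- cumsum(p)
  mu <- cumsum(p * centers)
  mu_t <- mu[nbins]
  # candidate k: classes are bins [1..k] vs (k..nbins]
  k <- seq_len(nbins - 1L)
  w1 <- 1 - w0[k]
  valid <- w0[k] > 0 & w1 > 0
  sigma_b <- rep(-Inf, nbins - 1L)
  sigma_b[valid] <- (mu_t * w0[k][valid] - mu[k][valid])^2 /
    (w0[k][valid] * w1[valid])
  best <- which.max(sigma_b)  # which.max takes the first (lowest) maximizer
  edges[best + 1L]
}

#' Keep only the largest connected component
#'
#' @param mask binary matrix or 3D array.
#' @param connectivity 26 (default) or 6 in 3D; in 2D these degenerate to
#'   8 and 4.
#' @return A logical mask of the same shape containing only the largest
#'   component.
#' @export
largest_component <- function(mask, connectivity = 26L) {
  if (is.null(dim(mask))) stopf("mask must be a matrix or 3D array")
  orig_dim <- dim(mask)
  m <- mask > 0
  dim(m) <- orig_dim
  if (!any(m)) stopf("empty mask: no components")
  lab <- label_components(m, connectivity)
  keep <- which.max(component_sizes(lab))
  out <- lab == keep
  dim(out) <- orig_dim
  out
}

#' Segment the bone from a volume
#'
#' The standard preprocessing chain: Otsu threshold on the whole volume, then
#' retain only the largest 26-connected component.
#'
#' @param volume an [image_volume] or 3D array.
#' @return A list with `mask` (logical volume) and `threshold`.
#' @export
segment_bone <- function(volume) {
  arr <- if (inherits(volume, "image_volume")) volume$intensities else volume
  thr <- otsu_threshold(arr)
  mask <- arr > thr
  dim(mask) <- dim(arr)
  list(mask = largest_component(mask, 26L), threshold = thr)
}

#' Prepare classifier-ready slices
#'
#' Crops every slice to the volume-level 3D bounding box of the bone mask,
#' min-max normalizes intensities to \[0,1\] per volume (so the relative
#' cartilage/bone contrast is preserved along z), and resizes each slice to
#' `size` x `size` pixels with bilinear interpolation.
#'
#' @param volume an [image_volume].
#' @param mask bone mask from [segment_bone()] (logical volume of the same
#'   shape).
#' @param size output slice edge length in pixels (default 384).
#' @return A list of `prepared_slice` objects, each with `pixels` (size x
#'   size matrix in \[0,1\]), `source_index` (0-based z index) and `z_mm`.
#' @export
prepare_slices <- function(volume, mask, size = 384L) {
  arr <- volume$intensities
  if (!identical(dim(arr), dim(mask))) stopf("mask/volume shape mismatch")
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stopf("empty mask: zero-extent bounding box")
  rx <- range(idx[, 1]); ry <- range(idx[, 2])
  sub <- arr[rx[1]:rx[2], ry[1]:ry[2], , drop = FALSE]
  mn <- min(sub); mx <- max(sub)
  vs <- volume$voxel_size_mm
  lapply(seq_len(dim(arr)[3]), function(k) {
    sl <- sub[, , k]
    if (mx > mn) {
      px <- (sl - mn) / (mx - mn)
    } else {
      warnf("slice %d: constant intensities after crop; emitting zeros", k - 1L)
      px <- matrix(0, nrow(sl), ncol(sl))
    }
    structure(list(pixels = .cpp_resize_bilinear(px, size, size),
                   source_index = k - 1L,
                   z_mm = (k - 1L) * vs),
              class = "prepared_slice")
  })
}
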