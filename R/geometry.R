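#' Rigidly align a tibia volume to the global axes
#'
#' Computes the principal axis of the segmented bone mask by PCA of its voxel
#' coordinates and maps it to the +z axis with the proximal end (identified
#' as the end with the larger cross-sectional area, i.e. the epiphysis) at
#' z = 0. The in-plane rotation is then fixed by the tibial ridge: within the
#' proximal 65-75% segment of the bone length, the furthest mask point from
#' each slice centroid defines the per-slice ridge direction, and the mean
#' ridge orientation is rotated onto the +x axis. The volume is resampled
#' once with trilinear interpolation (masks use nearest-neighbour).
#'
#' @param volume an [image_volume].
#' @param mask segmented bone mask (Otsu + largest component), same shape.
#' @param masks optional named list of additional masks to resample
#'   (nearest-neighbour).
#' @param flip_proximal set `TRUE` to override the automatic proximal-end
#'   choice.
#' @return A list of class `alignment_result`: `rotation` (3x3, maps input
#'   to output voxel coordinates about the volume centre), `ridge_angle_deg`,
#'   `aligned_volume`, `aligned_mask`, `aligned_masks`.
#' @export
align_tibia <- function(volume, mask, masks = NULL, flip_proximal = FALSE) {
  arr <- volume$intensities
  if (!identical(dim(arr), dim(mask))) stopf("mask/volume shape mismatch")
  coords <- which(mask > 0, arr.ind = TRUE)
  if (nrow(coords) < 10) stopf("degenerate mask: too few voxels")
  if (nrow(coords) > 200000) {
    keep <- seq(1, nrow(coords), length.out = 200000)
    coords_pca <- coords[round(keep), , drop = FALSE]
  } else coords_pca <- coords
  pc <- prcomp(coords_pca, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  if (ev[1] < 1.44 * ev[2])
    stopf("no principal direction: mask is nearly isotropic (axis undefined)")
  axis1 <- pc$rotation[, 1]

  # proximal end = larger cross-sectional area along the principal axis:
  # compare voxel counts in equal-length windows at either end
  proj <- as.matrix(coords) %*% axis1
  L <- diff(range(proj))
  area_lo <- sum(proj <= min(proj) + 0.1 * L)
  area_hi <- sum(proj >= max(proj) - 0.1 * L)
  if (xor(area_lo < area_hi, flip_proximal)) axis1 <- -axis1

  # rotation mapping axis1 -> +z (minimal rotation about axis1 x z)
  R1 <- rotation_between(axis1, c(0, 0, 1))

  d <- dim(arr)
  ctr <- (d - 1) / 2

  # axis-align the mask first so the ridge search runs on raster slices
  mask1 <- .cpp_resample_rigid(mask + 0, d, d, R1, ctr, ctr, TRUE, 0) > 0.5
  dim(mask1) <- d
  zs <- which(apply(mask1, 3, any))
  zr <- range(zs)
  lo <- zr[1] + 0.65 * diff(zr)
  hi <- zr[1] + 0.75 * diff(zr)
  seg_slices <- zs[zs >= lo & zs <= hi]
  if (length(seg_slices) < 2) stopf("empty ridge segment (65-75%% of length)")
  angles <- vapply(seg_slices, function(k) {
    sl <- mask1[, , k]
    # centre of the filled silhouette: unlike the bone-mask centroid it is
    # barely dragged toward the extra bone mass of the ridge itself
    filled <- fill_holes_2d(sl)
    idx <- which(filled, arr.ind = TRUE)
    cc <- colMeans(idx)
    bidx <- which(sl, arr.ind = TRUE)
    dx <- bidx[, 1] - cc[1]; dy <- bidx[, 2] - cc[2]
    rr <- sqrt(dx^2 + dy^2)
    # angular centroid of the furthest-point cap (within 2 voxels of the
    # maximal radius): robust to single-voxel jitter of the ridge tip
    cap <- rr >= max(rr) - 2
    th <- atan2(dy[cap], dx[cap])
    atan2(mean(sin(th)), mean(cos(th)))
  }, numeric(1))
  mean_angle <- atan2(mean(sin(angles)), mean(cos(angles)))
  R <- rotation_z(-mean_angle) %*% R1

  res_lin <- function(v) .cpp_resample_rigid(v, dim(v), dim(v), R, ctr, ctr,
                                             FALSE, 0)
  res_nn <- function(v) {
    out <- .cpp_resample_rigid(v + 0, dim(v), dim(v), R, ctr, ctr, TRUE, 0)
    out > 0.5
  }
  aligned_masks <- if (!is.null(masks)) lapply(masks, res_nn) else NULL
  structure(list(rotation = R,
                 ridge_angle_deg = mean_angle * 180 / pi,
                 aligned_volume = image_volume(res_lin(arr),
                                               volume$voxel_size_mm),
                 aligned_mask = res_nn(mask + 0),
                 aligned_masks = aligned_masks),
            class = "alignment_result")
}

# minimal rotation taking unit vector a onto unit vector b
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (abs(c_ + 1) < 1e-12) {
    # antiparallel: rotate pi about any axis orthogonal to a
    axis <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- axis - sum(axis * a) * a
    v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

#' Standardized VOI specifications
#'
#' Named presets anchor each volume of interest on a transitional landmark:
#' \describe{
#'   \item{epiphyseal}{from `Z_eg` extending 0.25 mm proximally.}
#'   \item{mixed_primary_secondary}{from `Z_gp` extending 1 mm distally.}
#'   \item{secondary}{from `Z_ps` extending 1 mm distally.}
#'   \item{fixed_offset}{from `Z_gp` plus a fixed offset (0.125 or 0.25 mm)
#'     extending 1 mm distally — the conventional growth-plate-offset VOI,
#'     provided for comparison with the anatomically anchored presets.}
#' }
#'
#' @param name preset name, or `"custom"` with explicit fields.
#' @param reference landmark id (`"Z_eg"`, `"Z_gp"`, `"Z_ps"`, `"Z_gs"`).
#' @param offset_mm signed offset from the reference (distal positive).
#' @param height_mm VOI height (> 0).
#' @return A `voi_spec`.
#' @export
voi_spec <- function(name = c("epiphyseal", "mixed_primary_secondary",
                              "secondary", "fixed_offset", "custom"),
                     reference = NULL, offset_mm = NULL, height_mm = NULL) {
  name <- match.arg(name)
  preset <- switch(name,
    epiphyseal = list(reference = "Z_eg", offset_mm = -0.25,
                      height_mm = 0.25),
    mixed_primary_secondary = list(reference = "Z_gp", offset_mm = 0,
                                   height_mm = 1.0),
    secondary = list(reference = "Z_ps", offset_mm = 0, height_mm = 1.0),
    fixed_offset = list(reference = "Z_gp", offset_mm = offset_mm %||% 0.25,
                        height_mm = 1.0),
    custom = list(reference = reference, offset_mm = offset_mm %||% 0,
                  height_mm = height_mm))
  if (!is.null(reference)) preset$reference <- reference
  if (!is.null(offset_mm)) preset$offset_mm <- offset_mm
  if (!is.null(height_mm)) preset$height_mm <- height_mm
  if (is.null(preset$reference)) stopf("voi_spec requires a reference landmark")
  if (is.null(preset$height_mm) || preset$height_mm <= 0)
    stopf("height_mm must be > 0")
  structure(c(list(name = name), preset), class = "voi_spec")
}

#' Extract a standardized VOI
#'
#' The VOI covers the half-open axial interval `[ref + offset, ref + offset
#' + height)` so that adjacent VOIs sharing a reference never overlap; the
#' slice count is `round(height / voxel)` (1 mm at 5 um is exactly 200
#' slices).
#'
#' @param volume an aligned [image_volume] (or 3D array).
#' @param landmarks a [landmark_set].
#' @param spec a [voi_spec].
#' @param masks optional named list of masks to crop along with the volume.
#' @return List with `volume` (sub-array), `masks`, `z_start_mm`,
#'   `z_end_mm`, `slice_range` (1-based inclusive indices into the source).
#' @export
extract_voi <- function(volume, landmarks, spec, masks = NULL) {
  arr <- if (inherits(volume, "image_volume")) volume$intensities else volume
  vs <- if (inherits(volume, "image_volume")) volume$voxel_size_mm
        else attr(volume, "voxel_size_mm")
  if (is.null(vs)) stopf("voxel size unavailable; pass an image_volume")
  ref <- landmarks[[spec$reference]]
  if (is.null(ref))
    stopf("landmark %s is absent; cannot anchor VOI '%s'",
          spec$reference, spec$name)
  z0 <- ref + spec$offset_mm
  n_slices <- round(spec$height_mm / vs)
  k0 <- round(z0 / vs)          # 0-based first slice
  k1 <- k0 + n_slices - 1L      # 0-based last slice (half-open interval)
  nz <- dim(arr)[3]
  if (k0 < 0 || k1 > nz - 1L)
    stopf("VOI [%.3f, %.3f) mm exceeds the volume z-range [0, %.3f) mm",
          z0, z0 + spec$height_mm, nz * vs)
  sel <- (k0 + 1L):(k1 + 1L)
  out_masks <- if (!is.null(masks))
    lapply(masks, function(m) m[, , sel, drop = FALSE]) else NULL
  list(volume = arr[, , sel, drop = FALSE], masks = out_masks,
       z_start_mm = z0, z_end_mm = z0 + spec$height_mm,
       slice_range = c(k0 + 1L, k1 + 1L), voxel_size_mm = vs, spec = spec)
}

#' Medullary and trabecular masks for a VOI
#'
#' When a precomputed trabecular mask is supplied (e.g. from a dedicated
#' segmentation model or phantom ground truth) it is passed through clipped
#' to the VOI. Otherwise a threshold-based substitute segmentation is used:
#' the VOI is binarized by Otsu; per slice, the cortical shell is the bone
#' component(s) touching the outer boundary of the filled bone silhouette;
#' the medullary mask is the filled silhouette minus the cortex, and the
#' trabecular mask is bone restricted to the medulla. This substitute is a
#' simple geometric rule and is not equivalent to a learned trabecular
#' segmentation; supply an external mask when one is available.
#'
#' @param voi result of [extract_voi()] (or a 3D intensity array).
#' @param external_trabecular optional binary volume of trabecular bone.
#' @param external_medullary optional binary medullary volume accompanying
#'   `external_trabecular`.
#' @return List with logical volumes `medullary` and `trabecular`.
#' @export
medullary_and_trabecular_masks <- function(voi, external_trabecular = NULL,
                                           external_medullary = NULL) {
  arr <- if (is.list(voi)) voi$volume else voi
  if (!is.null(external_trabecular)) {
    if (!identical(dim(external_trabecular), dim(arr)))
      stopf("external mask shape does not match the VOI")
    med <- external_medullary %||% external_trabecular
    return(list(medullary = as_logical_volume(med),
                trabecular = as_logical_volume(external_trabecular)))
  }
  thr <- otsu_threshold(arr)
  bone <- arr > thr
  dim(bone) <- dim(arr)
  med <- array(FALSE, dim(arr))
  trab <- array(FALSE, dim(arr))
  empty_slices <- 0L
  for (k in seq_len(dim(arr)[3])) {
    b <- bone[, , k]
    if (!any(b)) { empty_slices <- empty_slices + 1L; next }
    filled <- fill_holes_2d(b)
    lab <- label_components(b, 26L)
    outer_bg <- !filled
    adj <- outer_bg
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)))
      adj <- adj | shift_mat(outer_bg, d[1], d[2])
    cortex_labels <- setdiff(unique(lab[adj & b]), 0L)
    cortex <- matrix(lab %in% cortex_labels, nrow(b), ncol(b)) & b
    med_k <- filled & !cortex
    med[, , k] <- med_k
    trab[, , k] <- b & med_k
  }
  if (empty_slices > 0)
    warnf("%d slice(s) contained no bone", empty_slices)
  if (!any(trab))
    warnf("trabecular mask is empty (solid or hollow cross-sections only)")
  list(medullary = med, trabecular = trab)
}
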