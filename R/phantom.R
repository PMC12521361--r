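#' Specification of a synthetic tibia phantom
#'
#' Describes a synthetic micro-CT volume of the murine proximal tibia: a
#' tapered cortical tube whose medulla is divided, proximal to distal, into
#' epiphyseal trabecular bone, a non-calcified growth-plate cartilage band,
#' fine primary spongiosa and coarser secondary spongiosa, optionally followed
#' by empty shaft marrow. Trabecular texture inside each compartment is an
#' excursion set of a smoothed Gaussian random field calibrated to a target
#' bone volume fraction and trabecular thickness.
#'
#' Default microarchitecture follows typical values for untreated adult
#' C57BL/6 proximal tibiae: dense thick epiphyseal trabeculae (BV/TV ~ 0.33,
#' Tb.Th ~ 70 um), fine dense primary spongiosa (BV/TV ~ 0.40, Tb.Th ~ 35 um)
#' and sparse secondary spongiosa (BV/TV ~ 0.12, Tb.Th ~ 50 um).
#'
#' @param voxel_size_mm isotropic voxel size (default 0.005 mm = 5 um; the
#'   `"coarse"` preset uses 0.010 mm).
#' @param lateral_extent_mm lateral (x and y) field of view in mm.
#' @param compartment_heights_mm named vector of axial heights (mm) for
#'   `epiphysis`, `growth_plate`, `primary`, `secondary`, `shaft`.
#' @param compartment_texture named list (`epiphysis`, `primary`,
#'   `secondary`), each a list with `target_bvtv` in (0,1) and
#'   `target_tbth_mm`.
#' @param cortical_thickness_mm thickness of the cortical shell (mm).
#' @param boundary_undulation named list (`eg`, `gp`, `ps`), each a list with
#'   `amplitude_mm` and `period_mm`, describing sinusoidal tortuosity of the
#'   compartment interfaces.
#' @param intensity_model list with `bone_mu`, `marrow_mu`, `cartilage_mu`
#'   (normalized attenuation in \[0,1\]; cartilage sits between marrow and
#'   bone so that global thresholding assigns it to background, as for
#'   non-calcified tissue), `noise_sd`, and `psf_sd_mm` (Gaussian point-spread
#'   blur).
#' @param rigid_misalignment list with `tilt_deg` (about the x axis) and
#'   `inplane_rotation_deg` (about z), emulating imperfect specimen mounting.
#' @param ridge_height_mm height of the longitudinal cortical ridge bump that
#'   breaks rotational symmetry (used by in-plane alignment).
#' @param bone_radius_mm outer radius of the cortical tube at the proximal
#'   end; defaults to 36% of the lateral extent so small mounting tilts keep
#'   the bone inside the field of view.
#' @param seed integer seed; identical specs and seeds give bit-identical
#'   phantoms.
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()], [phantom_preset()]
#' @export
phantom_spec <- function(voxel_size_mm = 0.005,
                         lateral_extent_mm = 1.5,
                         compartment_heights_mm = c(epiphysis = 0.5,
                                                    growth_plate = 0.1,
                                                    primary = 0.3,
                                                    secondary = 1.2,
                                                    shaft = 0),
                         compartment_texture = list(
                           epiphysis = list(target_bvtv = 0.33,
                                            target_tbth_mm = 0.070),
                           primary = list(target_bvtv = 0.40,
                                          target_tbth_mm = 0.035),
                           secondary = list(target_bvtv = 0.12,
                                            target_tbth_mm = 0.050)),
                         cortical_thickness_mm = 0.15,
                         boundary_undulation = list(
                           eg = list(amplitude_mm = 0.02, period_mm = 0.5),
                           gp = list(amplitude_mm = 0.02, period_mm = 0.5),
                           ps = list(amplitude_mm = 0.02, period_mm = 0.5)),
                         intensity_model = list(bone_mu = 0.85,
                                                marrow_mu = 0.12,
                                                cartilage_mu = 0.35,
                                                noise_sd = 0.03,
                                                psf_sd_mm = 0.004),
                         rigid_misalignment = list(tilt_deg = 0,
                                                   inplane_rotation_deg = 0),
                         ridge_height_mm = 0.12,
                         bone_radius_mm = NULL,
                         seed = 1L) {
  h <- compartment_heights_mm
  need <- c("epiphysis", "growth_plate", "primary", "secondary", "shaft")
  if (!all(need %in% names(h)))
    stopf("compartment_heights_mm must name %s", paste(need, collapse = ", "))
  h <- h[need]
  if (voxel_size_mm <= 0) stopf("voxel_size_mm must be > 0")
  if (any(h < 0)) stopf("compartment heights must be >= 0")
  if (h[["epiphysis"]] <= 0 || h[["growth_plate"]] <= 0 ||
      h[["secondary"]] <= 0)
    stopf("epiphysis, growth_plate and secondary heights must be > 0")
  if (cortical_thickness_mm <= 0) stopf("cortical_thickness_mm must be > 0")
  for (nm in names(compartment_texture)) {
    tx <- compartment_texture[[nm]]
    if (tx$target_bvtv <= 0 || tx$target_bvtv >= 1)
      stopf("target_bvtv for %s must be in (0,1)", nm)
    if (tx$target_tbth_mm < 2 * voxel_size_mm)
      stopf("target_tbth_mm for %s is below 2 voxels (degenerate texture)", nm)
  }
  if (lateral_extent_mm <= 2 * (cortical_thickness_mm + 4 * voxel_size_mm))
    stopf("lateral_extent_mm too small for the cortical shell")
  bone_radius_mm <- bone_radius_mm %||% (0.36 * lateral_extent_mm)
  if (bone_radius_mm + ridge_height_mm > lateral_extent_mm / 2)
    stopf("bone radius plus ridge exceeds the lateral field of view")
  if (bone_radius_mm <= cortical_thickness_mm + 4 * voxel_size_mm)
    stopf("bone_radius_mm leaves no medulla inside the cortex")
  structure(list(voxel_size_mm = voxel_size_mm,
                 lateral_extent_mm = lateral_extent_mm,
                 compartment_heights_mm = h,
                 compartment_texture = compartment_texture,
                 cortical_thickness_mm = cortical_thickness_mm,
                 boundary_undulation = boundary_undulation,
                 intensity_model = intensity_model,
                 rigid_misalignment = rigid_misalignment,
                 ridge_height_mm = ridge_height_mm,
                 bone_radius_mm = bone_radius_mm,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Phantom presets
#'
#' `"default"` is the full-resolution phantom (5 um voxels); `"coarse"`
#' halves the grid (10 um) for fast validation runs; `"test"` uses 20 um
#' voxels and a smaller field of view for unit-scale checks.
#'
#' @param name preset name.
#' @param ... overrides forwarded to [phantom_spec()].
#' @return A `phantom_spec`.
#' @export
phantom_preset <- function(name = c("default", "coarse", "test"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    default = list(),
    coarse = list(voxel_size_mm = 0.010),
    test = list(voxel_size_mm = 0.020, lateral_extent_mm = 1.2,
                compartment_heights_mm = c(epiphysis = 0.4,
                                           growth_plate = 0.1,
                                           primary = 0.25,
                                           secondary = 0.85, shaft = 0),
                compartment_texture = list(
                  epiphysis = list(target_bvtv = 0.33,
                                   target_tbth_mm = 0.080),
                  primary = list(target_bvtv = 0.40,
                                 target_tbth_mm = 0.048),
                  secondary = list(target_bvtv = 0.12,
                                   target_tbth_mm = 0.055))))
  do.call(phantom_spec, utils::modifyList(base, list(...)))
}

# sd of texture field at/above which a voxel is bone, given target volume
# fraction p: threshold at the (1 - p) standard-normal quantile
texture_threshold <- function(bvtv) qnorm(1 - bvtv)

# Gaussian-kernel width (voxels) so the mean local thickness of the excursion
# set approximates the target thickness. From the Rice crossing rate of a
# standardized field smoothed with kernel sd `sigma`, the mean foreground
# chord along a line is 2*sqrt(2)*pi*sigma*p*exp(t^2/2); the inscribed-sphere
# thickness is shorter than the line chord by a factor that shrinks with
# volume fraction, calibrated once on reference random fields
# (~0.97 at p = 0.12, ~0.84 at p = 0.33, ~0.79 at p = 0.40).
chord_to_thickness <- function(bvtv) pmin(1, pmax(0.6, 1.05 - 0.64 * bvtv))

texture_sigma <- function(tbth_vox, bvtv) {
  t <- texture_threshold(bvtv)
  chord <- tbth_vox / chord_to_thickness(bvtv)
  chord / (2 * sqrt(2) * pi * bvtv * exp(t^2 / 2))
}

# smoothed Gaussian random field, standardized to zero mean and unit sd
# empirically (reflective padding inflates the theoretical variance near the
# volume border)
gaussian_random_field <- function(dim3, sigma_vox) {
  noise <- array(rnorm(prod(dim3)), dim = dim3)
  sm <- .cpp_gaussian_blur(noise, as.integer(dim3), rep(sigma_vox, 3))
  (sm - mean(sm)) / sd(sm)
}

#' Generate a synthetic tibia phantom
#'
#' Produces a grayscale micro-CT-like volume together with voxel-level ground
#' truth: anatomical region labels, trabecular and medullary masks, and the
#' true transitional landmarks derived from the labels by the slice rules of
#' [derive_truth_landmarks()].
#'
#' Region labels code 0 = epiphyseal bone, 1 = growth plate, 2 = primary
#' spongiosa, 3 = secondary spongiosa, 4 = cortex, 5 = background/marrow.
#' Labels are *region occupancy* labels: every medullary voxel in, e.g., the
#' secondary compartment carries label 3 whether it is bone or marrow; the
#' bone microarchitecture is carried by `trabecular_mask`.
#'
#' When a rigid misalignment is requested, the emitted intensity volume is
#' rotated, while the truth labels, masks and landmarks stay in the canonical
#' (aligned) frame; `applied_transform` maps canonical voxel coordinates into
#' the emitted volume.
#'
#' @param spec a [phantom_spec].
#' @return A list with elements `volume` (an [image_volume]) and `truth`
#'   (class `phantom_truth`: `label_volume`, `trabecular_mask`,
#'   `medullary_mask`, `true_landmarks`, `applied_transform`,
#'   `voxel_size_mm`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  vs <- spec$voxel_size_mm
  h <- spec$compartment_heights_mm
  nx <- ny <- round(spec$lateral_extent_mm / vs)
  nz <- round(sum(h) / vs)
  if (nz < 4) stopf("compartment heights give a volume of < 4 slices")
  cum <- cumsum(h)  # eg | gp | ps | ss-end | shaft-end

  with_seed(spec$seed, {
    cx <- (nx - 1) / 2
    cy <- (ny - 1) / 2
    xg <- (seq_len(nx) - 1) - cx
    yg <- (seq_len(ny) - 1) - cy
    r_mat <- sqrt(outer(xg^2, yg^2, `+`))
    th_mat <- atan2(rep(yg, each = nx), rep(xg, ny))
    dim(th_mat) <- c(nx, ny)

    # bone outer radius leaves lateral margin so small mounting tilts keep
    # the bone inside the field of view
    R0 <- spec$bone_radius_mm / vs
    taper <- 0.15
    cort_vox <- spec$cortical_thickness_mm / vs
    ridge_vox <- spec$ridge_height_mm / vs
    # smooth angular bump centred on +x
    ridge_prof <- ridge_vox * pmax(0, cos(th_mat))^12

    # undulating interface fields (mm)
    und_field <- function(u) {
      if (is.null(u) || u$amplitude_mm == 0) return(matrix(0, nx, ny))
      fx <- 2 * pi / (u$period_mm / vs)
      phx <- runif(1, 0, 2 * pi)
      phy <- runif(1, 0, 2 * pi)
      u$amplitude_mm *
        outer(sin(fx * (seq_len(nx) - 1) + phx),
              sin(fx * (seq_len(ny) - 1) + phy))
    }
    I_eg <- cum[["epiphysis"]] + und_field(spec$boundary_undulation$eg)
    I_gp <- cum[["growth_plate"]] + und_field(spec$boundary_undulation$gp)
    I_ps <- cum[["primary"]] + und_field(spec$boundary_undulation$ps)
    I_ss <- cum[["secondary"]]
    has_primary <- h[["primary"]] > 0

    # trabecular texture fields per compartment, generated on z-slabs
    tex_mask <- function(comp, z0_mm, z1_mm) {
      tx <- spec$compartment_texture[[comp]]
      if (is.null(tx) || z1_mm <= z0_mm) return(NULL)
      sig <- texture_sigma(tx$target_tbth_mm / vs, tx$target_bvtv)
      pad <- ceiling(3 * sig)
      k0 <- max(0L, floor(z0_mm / vs) - pad)
      k1 <- min(nz - 1L, ceiling(z1_mm / vs) + pad)
      field <- gaussian_random_field(c(nx, ny, k1 - k0 + 1L), sig)
      list(mask = field > texture_threshold(tx$target_bvtv), k0 = k0, k1 = k1)
    }
    amp_max <- max(vapply(spec$boundary_undulation,
                          function(u) u$amplitude_mm %||% 0, 0))
    tex_ep <- tex_mask("epiphysis", 0, cum[["epiphysis"]] + amp_max)
    tex_pr <- if (has_primary)
      tex_mask("primary", cum[["growth_plate"]] - amp_max,
               cum[["primary"]] + amp_max) else NULL
    tex_se <- tex_mask("secondary", cum[["primary"]] - amp_max,
                       cum[["secondary"]])

    im <- spec$intensity_model
    label <- array(5L, dim = c(nx, ny, nz))
    trab <- array(FALSE, dim = c(nx, ny, nz))
    medul <- array(FALSE, dim = c(nx, ny, nz))
    vol <- array(im$marrow_mu, dim = c(nx, ny, nz))

    for (k in seq_len(nz) - 1L) {
      zc <- k * vs
      Rout_base <- R0 * (1 - taper * k / max(1, nz - 1))
      Rout <- Rout_base + ridge_prof
      Rin <- Rout_base - cort_vox
      inside <- r_mat <= Rout
      med_k <- r_mat <= Rin
      cort_k <- inside & !med_k
      lab_k <- matrix(5L, nx, ny)
      lab_k[cort_k] <- 4L
      reg_k <- matrix(5L, nx, ny)
      reg_k[med_k & (zc < I_eg)] <- 0L
      reg_k[med_k & (zc >= I_eg) & (zc < I_gp)] <- 1L
      if (has_primary)
        reg_k[med_k & (zc >= I_gp) & (zc < I_ps)] <- 2L
      reg_k[med_k & (zc >= (if (has_primary) I_ps else I_gp)) &
              (zc < I_ss)] <- 3L
      lab_k[med_k] <- reg_k[med_k]

      trab_k <- matrix(FALSE, nx, ny)
      for (tx in list(list(t = tex_ep, code = 0L),
                      list(t = tex_pr, code = 2L),
                      list(t = tex_se, code = 3L))) {
        tt <- tx$t
        if (is.null(tt) || k < tt$k0 || k > tt$k1) next
        sel <- reg_k == tx$code & med_k
        trab_k[sel] <- tt$mask[, , k - tt$k0 + 1L][sel]
      }

      v_k <- matrix(0, nx, ny)          # exterior background
      v_k[med_k] <- im$marrow_mu
      v_k[reg_k == 1L] <- im$cartilage_mu
      v_k[trab_k | cort_k] <- im$bone_mu

      label[, , k + 1L] <- lab_k
      trab[, , k + 1L] <- trab_k
      medul[, , k + 1L] <- med_k
      vol[, , k + 1L] <- v_k
    }

    psf_vox <- im$psf_sd_mm / vs
    if (psf_vox > 0)
      vol <- .cpp_gaussian_blur(vol, dim(vol), rep(psf_vox, 3))
    if (im$noise_sd > 0)
      vol <- vol + array(rnorm(length(vol), sd = im$noise_sd), dim = dim(vol))
    vol[vol < 0] <- 0
    vol[vol > 1] <- 1

    truth <- structure(list(label_volume = label, trabecular_mask = trab,
                            medullary_mask = medul,
                            true_landmarks = NULL,
                            applied_transform = diag(3),
                            voxel_size_mm = vs),
                       class = "phantom_truth")
    truth$true_landmarks <- derive_truth_landmarks(truth, vs)

    mis <- spec$rigid_misalignment
    if (abs(mis$tilt_deg %||% 0) > 0 ||
        abs(mis$inplane_rotation_deg %||% 0) > 0) {
      R <- rotation_z(mis$inplane_rotation_deg * pi / 180) %*%
        rotation_x(mis$tilt_deg * pi / 180)
      ctr <- (dim(vol) - 1) / 2
      vol <- .cpp_resample_rigid(vol, dim(vol), dim(vol), R, ctr, ctr,
                                 FALSE, 0)
      truth$applied_transform <- R
    }
    list(volume = image_volume(vol, vs), truth = truth)
  })
}

rotation_x <- function(a) matrix(c(1, 0, 0,
                                   0, cos(a), sin(a),
                                   0, -sin(a), cos(a)), 3, 3)
rotation_z <- function(a) matrix(c(cos(a), sin(a), 0,
                                   -sin(a), cos(a), 0,
                                   0, 0, 1), 3, 3)

# does `phase` contain one 8-connected component that touches both the
# anterior-most and posterior-most rows of the medulla in this slice?
stripe_spans_medulla <- function(phase, medulla) {
  if (!any(phase)) return(FALSE)
  ys <- which(apply(medulla, 2, any))
  if (length(ys) == 0) return(FALSE)
  lab <- label_components(phase, 26L)
  a <- unique(lab[, ys[1]])
  p <- unique(lab[, ys[length(ys)]])
  any(a > 0 & a %in% p[p > 0])
}

#' Derive true landmarks from phantom labels
#'
#' Applies the annotator slice rules to a label volume: `Z_ps` is the distal
#' face of the distal-most slice in which primary spongiosa traverses the
#' medulla in an uninterrupted anterior-posterior stripe; `Z_gp` likewise for
#' non-calcified growth-plate cartilage; `Z_eg` is the proximal face of the
#' proximal-most slice in which any growth-plate cartilage is visible. When
#' the primary spongiosa is absent, `Z_gp` and `Z_ps` are reported absent and
#' `Z_gs` (growth plate to secondary spongiosa interface) is returned instead.
#'
#' @param truth a `phantom_truth` (canonical, unrotated frame).
#' @param voxel_size_mm voxel size in mm (defaults to the truth's own).
#' @return A [landmark_set] in mm.
#' @export
derive_truth_landmarks <- function(truth, voxel_size_mm = NULL) {
  vs <- voxel_size_mm %||% truth$voxel_size_mm
  lab <- truth$label_volume
  med <- truth$medullary_mask
  nz <- dim(lab)[3]

  distal_most_stripe <- function(code) {
    for (k in rev(seq_len(nz))) {
      if (!any(lab[, , k] == code)) next
      if (stripe_spans_medulla(lab[, , k] == code, med[, , k]))
        return(k)  # 1-based slice; interface at its distal face
    }
    NA_integer_
  }

  has_primary <- any(lab == 2L)
  k_eg <- which(apply(lab == 1L, 3, any))[1]
  Z_eg <- if (is.na(k_eg) || length(k_eg) == 0) NULL else (k_eg - 1L) * vs

  k_cart <- distal_most_stripe(1L)
  if (has_primary) {
    Z_gp <- if (is.na(k_cart)) NULL else k_cart * vs
    k_ps <- distal_most_stripe(2L)
    Z_ps <- if (is.na(k_ps)) NULL else k_ps * vs
    Z_gs <- NULL
    absent <- integer(0)
  } else {
    Z_gp <- NULL
    Z_ps <- NULL
    Z_gs <- if (is.na(k_cart)) NULL else k_cart * vs
    absent <- 2L
  }
  if (is.null(Z_eg)) absent <- union(absent, 1L)
  landmark_set(Z_eg = Z_eg, Z_gp = Z_gp, Z_ps = Z_ps, Z_gs = Z_gs,
               absent_compartments = absent)
}

#' Write a phantom to disk
#'
#' Writes the intensity volume (MetaImage or multipage TIFF), the label
#' volume (TIFF) and a JSON sidecar with landmarks (mm), seed and the spec.
#'
#' @param phantom result of [generate_phantom()].
#' @param dir output directory (created if needed).
#' @param spec the generating [phantom_spec()] (echoed into the sidecar).
#' @param format `"mhd"` or `"tiff"` for the intensity volume.
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir, spec = NULL,
                          format = c("mhd", "tiff")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (format == "mhd") write_mhd(phantom$volume, file.path(dir, "volume.mhd"))
  else write_volume_tiff(phantom$volume, file.path(dir, "volume.tif"))
  write_volume_tiff(phantom$truth$label_volume / 5,
                    file.path(dir, "labels.tif"))
  write_landmarks_json(phantom$truth$true_landmarks,
                       file.path(dir, "truth_landmarks.json"),
                       extra = list(seed = spec$seed,
                                    voxel_size_mm = phantom$volume$voxel_size_mm,
                                    spec = unclass(spec)))
  invisible(dir)
}
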