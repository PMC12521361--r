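#' Image volume container
#'
#' Wraps a 3D intensity array with its isotropic voxel size. Slices are
#' ordered proximal to distal along the third index; the axial position of
#' 0-based slice index `i` is `i * voxel_size_mm` (z = 0 mm is the proximal
#' end).
#'
#' @param intensities 3D numeric array `[x, y, z]`.
#' @param voxel_size_mm isotropic voxel edge length in mm (> 0).
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(intensities, voxel_size_mm) {
  if (!is.array(intensities) || length(dim(intensities)) != 3)
    stopf("intensities must be a 3D array")
  if (!is.numeric(voxel_size_mm) || length(voxel_size_mm) != 1 ||
      voxel_size_mm <= 0)
    stopf("voxel_size_mm must be a single positive number")
  structure(list(intensities = intensities,
                 voxel_size_mm = as.numeric(voxel_size_mm)),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<image_volume> %d x %d x %d voxels @ %.4g mm (%.3g x %.3g x %.3g mm)\n",
              d[1], d[2], d[3], x$voxel_size_mm,
              d[1] * x$voxel_size_mm, d[2] * x$voxel_size_mm,
              d[3] * x$voxel_size_mm))
  invisible(x)
}

#' Axial position (mm) of a 0-based slice index
#' @param volume an `image_volume`.
#' @param index 0-based slice index (vectorized).
#' @return z position(s) in mm.
#' @export
slice_z_mm <- function(volume, index) index * volume$voxel_size_mm

# ---- readers ----------------------------------------------------------------

read_slice_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    bmp = read_bmp(path),
    stopf("unsupported slice format '%s' (%s)", ext, path))
  if (length(dim(img)) == 3) img <- img[, , 1]  # first channel of RGB(A)
  # image rows are y (top first); transpose to [x, y]
  t(img)
}

# minimal reader for uncompressed 8-bit palette / 24-bit BMP (the native
# export format of bench-top micro-CT consoles); returns values in [0, 1]
read_bmp <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2)
  if (!identical(as.integer(magic), c(0x42L, 0x4DL)))
    stopf("not a BMP file: %s", path)
  readBin(con, "integer", 2, size = 4)            # file size, reserved
  offset <- readBin(con, "integer", 1, size = 4)
  hdr_size <- readBin(con, "integer", 1, size = 4)
  if (hdr_size < 40) stopf("unsupported BMP header in %s", path)
  w <- readBin(con, "integer", 1, size = 4)
  h <- readBin(con, "integer", 1, size = 4)
  readBin(con, "integer", 1, size = 2)            # planes
  bpp <- readBin(con, "integer", 1, size = 2)
  compression <- readBin(con, "integer", 1, size = 4)
  if (compression != 0)
    stopf("compressed BMP is not supported (%s)", path)
  if (!bpp %in% c(8L, 24L))
    stopf("only 8-bit and 24-bit BMP are supported (%s has %d bpp)", path, bpp)
  seek(con, offset)
  row_bytes <- ((w * bpp / 8 + 3) %/% 4) * 4
  data <- readBin(con, "raw", row_bytes * abs(h))
  px <- as.integer(data)
  dim(px) <- c(row_bytes, abs(h))
  if (bpp == 8L) {
    img <- px[seq_len(w), , drop = FALSE] / 255
  } else {
    rgb <- px[seq_len(w * 3), , drop = FALSE]
    b <- rgb[seq(1, w * 3, by = 3), , drop = FALSE]
    g <- rgb[seq(2, w * 3, by = 3), , drop = FALSE]
    r <- rgb[seq(3, w * 3, by = 3), , drop = FALSE]
    img <- (0.299 * r + 0.587 * g + 0.114 * b) / 255
  }
  # BMP rows are stored bottom-up when h > 0; flip so row 1 is the image top
  if (h > 0) img <- img[, rev(seq_len(ncol(img))), drop = FALSE]
  t(img)  # -> [row = y, col = x]; transposed again by the caller convention
}

read_mhd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) >= 2)
      kv[[trimws(parts[1])]] <- trimws(paste(parts[-1], collapse = "="))
  }
  dims <- as.integer(strsplit(kv[["DimSize"]], "\\s+")[[1]])
  spacing <- as.numeric(strsplit(kv[["ElementSpacing"]] %||% "0 0 0",
                                 "\\s+")[[1]])
  type <- kv[["ElementType"]] %||% "MET_FLOAT"
  raw_file <- file.path(dirname(path), kv[["ElementDataFile"]])
  size <- switch(type, MET_UCHAR = 1L, MET_SHORT = 2L, MET_USHORT = 2L,
                 MET_FLOAT = 4L, MET_DOUBLE = 8L,
                 stopf("unsupported MetaImage ElementType '%s'", type))
  what <- if (type %in% c("MET_FLOAT", "MET_DOUBLE")) "numeric" else "integer"
  signed <- !type %in% c("MET_UCHAR", "MET_USHORT")
  con <- file(raw_file, "rb")
  on.exit(close(con))
  v <- readBin(con, what, n = prod(dims), size = size, signed = signed,
               endian = "little")
  if (type == "MET_UCHAR") v <- v / 255
  arr <- array(as.numeric(v), dim = dims)
  list(intensities = arr, spacing = spacing)
}

#' Read a micro-CT volume
#'
#' Loads a slice stack (directory of BMP/PNG/TIFF files, ordered by
#' lexicographic filename), a multipage TIFF, a MetaImage (.mhd/.raw) pair, or
#' a NIfTI file. Intensities are returned as read without rescaling; slices
#' are ordered proximal to distal.
#'
#' @param path directory (slice stack) or file.
#' @param voxel_size_mm voxel size in mm. Required for formats without
#'   spacing metadata; for MetaImage/NIfTI the embedded spacing is used when
#'   this is `NULL`.
#' @param pattern optional filename regex for slice stacks.
#' @return An [image_volume].
#' @export
read_volume <- function(path, voxel_size_mm = NULL, pattern = NULL) {
  if (!file.exists(path)) stopf("path does not exist: %s", path)
  if (dir.exists(path)) {
    files <- list.files(path, pattern = pattern %||%
                          "\\.(bmp|png|tif|tiff)$",
                        ignore.case = TRUE, full.names = TRUE)
    if (length(files) == 0) stopf("no image slices found in %s", path)
    files <- sort(files)
    slices <- lapply(files, read_slice_image)
    d1 <- dim(slices[[1]])
    for (i in seq_along(slices)) {
      if (!identical(dim(slices[[i]]), d1))
        stopf("slice %s has shape %s, expected %s", basename(files[i]),
              paste(dim(slices[[i]]), collapse = "x"),
              paste(d1, collapse = "x"))
    }
    vol <- array(unlist(slices, use.names = FALSE),
                 dim = c(d1, length(slices)))
    if (is.null(voxel_size_mm))
      stopf("voxel_size_mm is required for slice stacks")
    return(image_volume(vol, voxel_size_mm))
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, function(p) {
      if (length(dim(p)) == 3) p <- p[, , 1]
      t(p)
    })
    vol <- array(unlist(pages, use.names = FALSE),
                 dim = c(dim(pages[[1]]), length(pages)))
    if (is.null(voxel_size_mm))
      stopf("voxel_size_mm is required for TIFF volumes")
    return(image_volume(vol, voxel_size_mm))
  }
  if (ext == "mhd") {
    m <- read_mhd(path)
    vs <- voxel_size_mm %||% m$spacing[1]
    if (vs <= 0) stopf("MetaImage %s has no usable spacing; pass voxel_size_mm",
                       path)
    return(image_volume(m$intensities, vs))
  }
  if (ext %in% c("nii", "gz")) {
    img <- RNifti::readNifti(path)
    vs <- voxel_size_mm %||% RNifti::pixdim(img)[1]
    return(image_volume(array(as.numeric(img), dim = dim(img)), vs))
  }
  stopf("unknown volume format: %s", path)
}

# ---- writers ----------------------------------------------------------------

#' Write a volume as MetaImage (.mhd + .raw)
#' @param volume an [image_volume] or 3D array.
#' @param path output path ending in .mhd.
#' @param voxel_size_mm voxel size (taken from the volume when omitted).
#' @return `path`, invisibly.
#' @export
write_mhd <- function(volume, path, voxel_size_mm = NULL) {
  if (inherits(volume, "image_volume")) {
    voxel_size_mm <- voxel_size_mm %||% volume$voxel_size_mm
    volume <- volume$intensities
  }
  stopifnot(grepl("\\.mhd$", path))
  raw_name <- sub("\\.mhd$", ".raw", basename(path))
  d <- dim(volume)
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           paste("DimSize =", paste(d, collapse = " ")),
           paste("ElementSpacing =",
                 paste(rep(voxel_size_mm %||% 1, 3), collapse = " ")),
           "ElementType = MET_FLOAT",
           paste("ElementDataFile =", raw_name))
  writeLines(hdr, path)
  con <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(con))
  writeBin(as.numeric(volume), con, size = 4, endian = "little")
  invisible(path)
}

#' Write a volume as multipage TIFF
#' @param volume an [image_volume] or 3D array with values in \[0, 1\].
#' @param path output .tif path.
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(volume, path) {
  if (inherits(volume, "image_volume")) volume <- volume$intensities
  pages <- lapply(seq_len(dim(volume)[3]), function(k) t(volume[, , k]))
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' Write a landmark set as JSON
#'
#' Landmarks are written in mm; absent landmarks are `null` and also listed
#' under `absent`.
#' @param landmarks a [landmark_set].
#' @param path output .json path.
#' @param extra optional named list merged into the JSON object (e.g. seed,
#'   provenance).
#' @return `path`, invisibly.
#' @export
write_landmarks_json <- function(landmarks, path, extra = NULL) {
  obj <- c(list(Z_eg = landmarks$Z_eg, Z_gp = landmarks$Z_gp,
                Z_ps = landmarks$Z_ps, Z_gs = landmarks$Z_gs,
                absent = as.character(landmarks$absent_compartments)),
           extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
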