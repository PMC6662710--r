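#' Voxel containers
#'
#' `voxel_mask()` wraps a binary 3D grid, `hu_volume()` a scalar grid in
#' Hounsfield units. Both carry an isotropic voxel spacing in mm and a world
#' origin: the world coordinate, in mm, of the center of the first voxel
#' (array index `[1, 1, 1]`). Array axes map to world axes as i -> x,
#' j -> y, k -> z. Anisotropic spacing is rejected: the supported scans are
#' isotropic (0.39 mm in the source CBCT protocol) and every downstream
#' formula (volume = count x spacing^3, surface = faces x spacing^2) assumes
#' cubic voxels.
#'
#' @param data A 3D array: logical/0-1 for masks, numeric HU for volumes.
#' @param spacing Voxel edge length in mm (scalar, or length 3 with all
#'   entries equal).
#' @param origin World coordinate (mm) of the center of voxel `[1, 1, 1]`.
#' @return A `voxel_mask` or `hu_volume` object.
#' @export
voxel_mask <- function(data, spacing = 1, origin = c(0, 0, 0)) {
  geom <- check_grid_geometry(data, spacing, origin)
  if (is.numeric(data)) {
    if (!all(data %in% c(0, 1))) {
      stop("mask values must be 0/1 or logical", call. = FALSE)
    }
    data <- array(data != 0, dim = dim(data))
  }
  stopifnot(is.logical(data))
  structure(list(data = data, spacing = geom$spacing, origin = geom$origin),
            class = "voxel_mask")
}

#' @rdname voxel_mask
#' @export
hu_volume <- function(data, spacing = 1, origin = c(0, 0, 0)) {
  geom <- check_grid_geometry(data, spacing, origin)
  if (!all(is.finite(data))) {
    stop("HU values must be finite", call. = FALSE)
  }
  structure(list(data = data, spacing = geom$spacing, origin = geom$origin),
            class = "hu_volume")
}

check_grid_geometry <- function(data, spacing, origin) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("data must be a 3D array", call. = FALSE)
  }
  if (any(dim(data) < 1L) || length(data) == 0L) {
    stop("grid must be non-empty", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) == 3L) {
    if (diff(range(spacing)) > 1e-9) {
      stop("anisotropic voxel spacing is not supported (isotropic scans only)",
           call. = FALSE)
    }
    spacing <- spacing[1]
  }
  stopifnot(length(spacing) == 1L, is.finite(spacing), spacing > 0)
  origin <- as.numeric(origin)
  stopifnot(length(origin) == 3L, all(is.finite(origin)))
  list(spacing = spacing, origin = origin)
}

#' @export
print.voxel_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<voxel_mask> %d x %d x %d, spacing %.4g mm, %d foreground voxels\n",
    d[1], d[2], d[3], x$spacing, sum(x$data)))
  invisible(x)
}

#' @export
print.hu_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hu_volume> %d x %d x %d, spacing %.4g mm, HU range [%g, %g]\n",
              d[1], d[2], d[3], x$spacing, min(x$data), max(x$data)))
  invisible(x)
}

is_voxel_mask <- function(x) inherits(x, "voxel_mask")

# world coordinates of voxel centers along each grid axis
axis_coords <- function(vol) {
  d <- dim(vol$data)
  list(x = vol$origin[1] + (seq_len(d[1]) - 1) * vol$spacing,
       y = vol$origin[2] + (seq_len(d[2]) - 1) * vol$spacing,
       z = vol$origin[3] + (seq_len(d[3]) - 1) * vol$spacing)
}

# 3D array of signed distances from every voxel center to `plane`
signed_distance_grid <- function(vol, plane) {
  cc <- axis_coords(vol)
  n <- plane$normal
  outer(outer(n[1] * cc$x, n[2] * cc$y, "+"), n[3] * cc$z, "+") - plane$offset
}

same_grid <- function(a, b, tol = 1e-9) {
  identical(dim(a$data), dim(b$data)) &&
    abs(a$spacing - b$spacing) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

#' Read and write volumes as NIfTI
#'
#' `read_hu_volume()` loads a NIfTI scalar volume (spacing taken from the
#' header, which must be isotropic); `write_volume_nifti()` writes an
#' [hu_volume] or [voxel_mask] (masks as unsigned 8-bit). NRRD and DICOM
#' series are not supported; convert to NIfTI first.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return `read_hu_volume()`: an [hu_volume].
#' @export
read_hu_volume <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)
  hu_volume(array(as.numeric(img), dim = dim(img)), spacing = sp,
            origin = nifti_origin(img))
}

#' @rdname read_hu_volume
#' @param vol An [hu_volume] or [voxel_mask].
#' @export
write_volume_nifti <- function(vol, path) {
  dat <- if (is_voxel_mask(vol)) {
    array(as.integer(vol$data), dim = dim(vol$data))
  } else {
    vol$data
  }
  img <- RNifti::asNifti(dat)
  img <- RNifti::`pixdim<-`(img, rep(vol$spacing, 3))
  # qform stores the origin so round trips preserve world coordinates
  RNifti::qform(img) <- structure(
    rbind(cbind(diag(3) * vol$spacing, vol$origin), c(0, 0, 0, 1)),
    code = 2L)
  datatype <- if (is_voxel_mask(vol)) "uint8" else "float"
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' @rdname read_hu_volume
#' @export
read_voxel_mask <- function(path) {
  v <- read_hu_volume(path)
  voxel_mask(array(v$data != 0, dim = dim(v$data)), v$spacing, v$origin)
}

nifti_origin <- function(img) {
  q <- RNifti::xform(img)
  # xform columns follow NIfTI RAS; voxel (0,0,0) center maps to the 4th column
  as.numeric(q[1:3, 4])
}
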