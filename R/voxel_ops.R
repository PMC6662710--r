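#' Hounsfield-unit band
#'
#' Closed intensity interval used for binarization. Both ends are inclusive,
#' matching the printed threshold ranges: bone 320-520 HU, soft tissue
#' -480 to -360 HU.
#'
#' @param lower,upper Band limits in HU, `lower < upper`.
#' @return An object of class `hu_band`.
#' @export
hu_band <- function(lower, upper) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  stopifnot(length(lower) == 1L, length(upper) == 1L,
            is.finite(lower), is.finite(upper))
  if (lower >= upper) {
    stop("invalid HU band: lower must be below upper", call. = FALSE)
  }
  structure(list(lower = lower, upper = upper), class = "hu_band")
}

#' @rdname hu_band
#' @export
hu_band_bone <- function() hu_band(320, 520)

#' @rdname hu_band
#' @export
hu_band_soft_tissue <- function() hu_band(-480, -360)

#' Binarize an HU volume
#'
#' A voxel is foreground iff `lower <= HU <= upper` (inclusive on both
#' ends). Grid geometry is carried over.
#'
#' @param volume An [hu_volume].
#' @param band An [hu_band] (or length-2 numeric `c(lower, upper)`).
#' @return A [voxel_mask]. Warns if the result is empty.
#' @export
binarize <- function(volume, band) {
  stopifnot(inherits(volume, "hu_volume"))
  if (is.numeric(band) && length(band) == 2L) band <- hu_band(band[1], band[2])
  stopifnot(inherits(band, "hu_band"))
  m <- volume$data >= band$lower & volume$data <= band$upper
  if (!any(m)) {
    warning("binarization produced an empty mask", call. = FALSE)
  }
  voxel_mask(array(m, dim = dim(volume$data)), volume$spacing, volume$origin)
}

#' Fill interior holes of a binary mask
#'
#' Sets to foreground every background component that is not 6-connected to
#' the grid boundary. Extensive (output contains input) and idempotent.
#'
#' @param mask A [voxel_mask].
#' @return The hole-filled [voxel_mask].
#' @export
fill_holes <- function(mask) {
  stopifnot(is_voxel_mask(mask))
  bg <- !mask$data
  reach <- array(cpp_boundary_connected(as.logical(bg), dim(bg)),
                 dim = dim(bg))
  out <- mask$data | (bg & !reach)
  voxel_mask(out, mask$spacing, mask$origin)
}

# discrete ball dilation/erosion via the exact squared Euclidean distance
# transform: dilate(X) = {p : d(p, X)^2 <= r^2}, erode(X) = {p : d(p, X^c)^2 > r^2}
edt_sq <- function(arr) {
  array(cpp_sq_edt(as.logical(arr), dim(arr)), dim = dim(arr))
}

dilate_ball <- function(arr, radius) {
  edt_sq(arr) <= radius^2 + 1e-9
}

erode_ball <- function(arr, radius) {
  !(edt_sq(!arr) <= radius^2 + 1e-9)
}

#' Morphological closing with a spherical structuring element
#'
#' Dilation followed by erosion with the discrete Euclidean ball
#' `{v : |v| <= radius}` in voxel units (default radius 10, the value used
#' to close thin-walled condylar heads after bone binarization). The grid is
#' padded with background before the operation and cropped afterwards, so
#' the result matches closing over an unbounded background and structures
#' near the grid edge are not artificially eroded.
#'
#' @param mask A [voxel_mask].
#' @param radius_vox Ball radius in voxels (integer >= 1).
#' @return The closed [voxel_mask]; always contains the input.
#' @export
morph_close <- function(mask, radius_vox = 10) {
  stopifnot(is_voxel_mask(mask))
  radius_vox <- as.integer(radius_vox)
  if (length(radius_vox) != 1L || is.na(radius_vox) || radius_vox < 1L) {
    stop("radius_vox must be an integer >= 1", call. = FALSE)
  }
  r <- radius_vox
  d <- dim(mask$data)
  # pad by 2r: the dilation reaches at most r beyond the structure, and the
  # erosion then never probes beyond the padded grid, so the result equals
  # closing on an unbounded background
  p <- 2L * r
  padded <- array(FALSE, d + 2L * p)
  padded[p + seq_len(d[1]), p + seq_len(d[2]), p + seq_len(d[3])] <- mask$data
  closed <- erode_ball(dilate_ball(padded, r), r)
  out <- closed[p + seq_len(d[1]), p + seq_len(d[2]), p + seq_len(d[3])]
  out <- out | mask$data  # guard: closing is extensive by construction
  voxel_mask(array(out, dim = d), mask$spacing, mask$origin)
}

#' Mask volume in cubic millimetres
#'
#' Foreground voxel count times the cube of the voxel spacing.
#'
#' @param mask A [voxel_mask].
#' @return Volume in mm^3.
#' @export
volume_mm3 <- function(mask) {
  stopifnot(is_voxel_mask(mask))
  sum(mask$data) * mask$spacing^3
}

#' Surface area of a binary mask
#'
#' Two estimators are provided:
#' \describe{
#'   \item{`face_count`}{number of foreground voxel faces adjacent to
#'     background, times `spacing^2` (the default; a well-defined discrete
#'     surface).}
#'   \item{`slice_perimeter`}{per-axial-slice boundary length in voxel
#'     edges, times `spacing^2`, summed over slices (the literal
#'     boundary-distance formula; counts only in-slice x/y faces).}
#' }
#' When `exclude` is one or more planes, boundary faces whose centers lie
#' within half a voxel of a plane and whose face normal aligns with that
#' plane's normal (|dot| above `normal_alignment`) are omitted — used to
#' drop the artificial flat face left by cutting a structure with a
#' reference plane.
#'
#' @param mask A [voxel_mask].
#' @param mode `"face_count"` or `"slice_perimeter"`.
#' @param exclude Optional [plane] or list of planes whose cut faces are
#'   excluded from the total.
#' @param normal_alignment Minimum |cosine| between face normal and plane
#'   normal for a face to count as lying on the cut.
#' @return Surface area in mm^2.
#' @export
surface_area_mm2 <- function(mask, mode = c("face_count", "slice_perimeter"),
                             exclude = NULL, normal_alignment = 0.5) {
  stopifnot(is_voxel_mask(mask))
  mode <- match.arg(mode)
  axes <- if (mode == "face_count") 1:3 else 1:2
  if (!is.null(exclude) && is_plane(exclude)) exclude <- list(exclude)
  total <- 0
  for (ax in axes) {
    total <- total + count_exposed_faces(mask, ax, exclude, normal_alignment)
  }
  total * mask$spacing^2
}

# exposed faces orthogonal to axis `ax`, minus faces lying on excluded planes
count_exposed_faces <- function(mask, ax, exclude, normal_alignment) {
  d <- dim(mask$data)
  dpad <- d
  dpad[ax] <- d[ax] + 2L
  padded <- array(FALSE, dpad)
  idx <- lapply(seq_len(3), function(a) seq_len(d[a]) + if (a == ax) 1L else 0L)
  padded[idx[[1]], idx[[2]], idx[[3]]] <- mask$data
  df <- apply_diff(padded, ax)  # dim d[ax]+1 along ax; nonzero = exposed face
  faces <- df != 0
  n_faces <- sum(faces)
  if (n_faces == 0L || is.null(exclude)) {
    return(n_faces)
  }
  pos <- which(faces, arr.ind = TRUE)
  # face t along axis ax sits between original voxels t-1 and t: its center
  # is half a voxel below the center of voxel t
  centers <- matrix(0, nrow(pos), 3)
  for (a in 1:3) {
    shift <- if (a == ax) 1.5 else 1
    centers[, a] <- mask$origin[a] + (pos[, a] - shift) * mask$spacing
  }
  keep <- rep(TRUE, n_faces)
  for (pl in exclude) {
    if (abs(pl$normal[ax]) < normal_alignment) next
    sd <- abs(as.numeric(centers %*% pl$normal) - pl$offset)
    keep <- keep & sd > mask$spacing / 2 + 1e-9
  }
  sum(keep)
}

# forward difference of a logical 3D array along one axis
apply_diff <- function(arr, ax) {
  d <- dim(arr)
  i1 <- lapply(seq_len(3), function(a) {
    if (a == ax) seq_len(d[a] - 1L) + 1L else seq_len(d[a])
  })
  i0 <- lapply(seq_len(3), function(a) {
    if (a == ax) seq_len(d[a] - 1L) else seq_len(d[a])
  })
  arr[i1[[1]], i1[[2]], i1[[3]], drop = FALSE] -
    arr[i0[[1]], i0[[2]], i0[[3]], drop = FALSE]
}

#' Split a mask into the two sides of a plane
#'
#' Each foreground voxel is assigned by the sign of the signed distance from
#' its world-coordinate center to the plane; voxels exactly on the plane go
#' to the positive side. The two outputs partition the input.
#'
#' @param mask A [voxel_mask].
#' @param plane A [plane].
#' @return A list with `positive` and `negative` [voxel_mask]s on the
#'   input grid.
#' @export
split_by_plane <- function(mask, plane) {
  stopifnot(is_voxel_mask(mask), is_plane(plane))
  sd <- signed_distance_grid(mask, plane)
  pos <- mask$data & sd >= 0
  neg <- mask$data & sd < 0
  list(positive = voxel_mask(pos, mask$spacing, mask$origin),
       negative = voxel_mask(neg, mask$spacing, mask$origin))
}

#' Remove the part of a mask above a plane
#'
#' Clears voxels with positive signed distance. With the Frankfort plane
#' (normal superior) this keeps the lower face, the region retained for the
#' soft-tissue analysis.
#'
#' @param mask A [voxel_mask].
#' @param plane A [plane] with superiorly oriented normal.
#' @return The cropped [voxel_mask].
#' @export
crop_below_plane <- function(mask, plane) {
  stopifnot(is_voxel_mask(mask), is_plane(plane))
  sd <- signed_distance_grid(mask, plane)
  voxel_mask(mask$data & sd <= 0, mask$spacing, mask$origin)
}
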