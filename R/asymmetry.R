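#' Mirror a binary mask through a plane
#'
#' Every output voxel center is reflected through the plane and the input is
#' sampled there. The output lives on the input's grid. With
#' `interpolation = "nearest"` (default) binary values are preserved without
#' a threshold choice; `"linear"` does trilinear interpolation of the 0/1
#' field followed by a 0.5 threshold. When the mirror plane is a grid
#' mid-plane orthogonal to an axis, nearest-neighbor sampling reduces to an
#' exact index flip, so mirroring twice recovers the input exactly.
#'
#' @param mask A [voxel_mask].
#' @param plane The mirror [plane].
#' @param interpolation `"nearest"` or `"linear"`.
#' @return The mirrored [voxel_mask] on the same grid.
#' @export
mirror_mask <- function(mask, plane, interpolation = c("nearest", "linear")) {
  stopifnot(is_voxel_mask(mask), is_plane(plane))
  interpolation <- match.arg(interpolation)
  d <- dim(mask$data)
  n <- plane$normal
  cc <- axis_coords(mask)
  sd <- signed_distance_grid(mask, plane)
  # reflected center, expressed in fractional 0-based grid indices
  fx <- (array(cc$x, d) - 2 * sd * n[1] - mask$origin[1]) / mask$spacing
  fy <- (array(rep(cc$y, each = d[1]), d) - 2 * sd * n[2] -
           mask$origin[2]) / mask$spacing
  fz <- (array(rep(cc$z, each = d[1] * d[2]), d) - 2 * sd * n[3] -
           mask$origin[3]) / mask$spacing
  out <- if (interpolation == "nearest") {
    sample_nearest(mask$data, fx, fy, fz)
  } else {
    sample_trilinear(mask$data, fx, fy, fz) >= 0.5
  }
  voxel_mask(array(out, d), mask$spacing, mask$origin)
}

sample_nearest <- function(arr, fx, fy, fz) {
  d <- dim(arr)
  i <- as.integer(round(fx)) + 1L
  j <- as.integer(round(fy)) + 1L
  k <- as.integer(round(fz)) + 1L
  ok <- i >= 1L & i <= d[1] & j >= 1L & j <= d[2] & k >= 1L & k <= d[3]
  out <- logical(length(arr))
  lin <- i[ok] + (j[ok] - 1L) * d[1] + (k[ok] - 1L) * (d[1] * d[2])
  out[ok] <- arr[lin]
  out
}

sample_trilinear <- function(arr, fx, fy, fz) {
  d <- dim(arr)
  i0 <- floor(fx); j0 <- floor(fy); k0 <- floor(fz)
  wx <- fx - i0; wy <- fy - j0; wz <- fz - k0
  out <- numeric(length(arr))
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    i <- as.integer(i0) + di + 1L
    j <- as.integer(j0) + dj + 1L
    k <- as.integer(k0) + dk + 1L
    w <- (if (di) wx else 1 - wx) * (if (dj) wy else 1 - wy) *
      (if (dk) wz else 1 - wz)
    ok <- i >= 1L & i <= d[1] & j >= 1L & j <= d[2] & k >= 1L & k <= d[3]
    lin <- i[ok] + (j[ok] - 1L) * d[1] + (k[ok] - 1L) * (d[1] * d[2])
    out[ok] <- out[ok] + w[ok] * arr[lin]
  }
  out
}

#' Overlap statistics and similarity index of two masks
#'
#' Computes the voxel counts of two masks and their intersection, the
#' non-overlapping volume (the symmetric difference
#' `|A| + |B| - 2 |A n B|`), and the Sorensen-Dice similarity index
#' `2 |A n B| / (|A| + |B|)`. The index runs from 0 (disjoint) to 1
#' (identical); the identity `dice = 1 - NOV / (|A| + |B|)` holds exactly
#' in integer arithmetic.
#'
#' @param A,B [voxel_mask]s on the same grid.
#' @return An object of class `overlap_result` with fields `count_A`,
#'   `count_B`, `count_intersection`, `count_nonoverlap`, `dice`,
#'   `nonoverlap_mm3`, `spacing`.
#' @export
overlap_stats <- function(A, B) {
  stopifnot(is_voxel_mask(A), is_voxel_mask(B))
  if (!same_grid(A, B)) {
    stop("masks are not on the same grid (dimensions, spacing, origin)",
         call. = FALSE)
  }
  ca <- sum(A$data)
  cb <- sum(B$data)
  ci <- sum(A$data & B$data)
  if (ca + cb == 0L) {
    stop("similarity index undefined: both masks are empty", call. = FALSE)
  }
  nov <- ca + cb - 2L * ci
  structure(list(count_A = ca, count_B = cb, count_intersection = ci,
                 count_nonoverlap = nov,
                 dice = 2 * ci / (ca + cb),
                 nonoverlap_mm3 = nov * A$spacing^3,
                 spacing = A$spacing),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "<overlap_result> |A| = %d, |B| = %d, |A n B| = %d\n  dice = %.4f, non-overlapping volume = %.2f mm^3\n",
    x$count_A, x$count_B, x$count_intersection, x$dice, x$nonoverlap_mm3))
  invisible(x)
}

#' Mirrored similarity of a bilateral structure
#'
#' The mirroring pipeline: split the structure by the reference plane into
#' its left (positive-side) and right (negative-side) halves, reflect the
#' left half through the plane, superimpose it on the right half, and
#' compute [overlap_stats]. No re-registration is performed after mirroring:
#' superimposition is purely by the reference plane, so the result measures
#' asymmetry about that plane.
#'
#' @param structure A [voxel_mask] of the whole structure.
#' @param plane The reference [plane] (mandibular median or midsagittal).
#' @param interpolation Passed to [mirror_mask()].
#' @return An `overlap_result`; additionally carries the mirrored half and
#'   the non-overlap mask in attributes `"mirrored"` and `"nonoverlap_mask"`
#'   for segment analysis.
#' @export
mirrored_similarity <- function(structure, plane,
                                interpolation = c("nearest", "linear")) {
  stopifnot(is_voxel_mask(structure), is_plane(plane))
  halves <- split_by_plane(structure, plane)
  if (sum(halves$positive$data) == 0L || sum(halves$negative$data) == 0L) {
    warning("one half is empty: similarity index is 0", call. = FALSE)
  }
  mirrored <- mirror_mask(halves$positive, plane, interpolation)
  res <- overlap_stats(mirrored, halves$negative)
  nov_mask <- voxel_mask(xor(mirrored$data, halves$negative$data),
                         structure$spacing, structure$origin)
  attr(res, "mirrored") <- mirrored
  attr(res, "nonoverlap_mask") <- nov_mask
  res
}

#' Distribution of non-overlapping volume across ramus and body
#'
#' Splits the non-overlap mask by the ramus-body sectioning plane (through
#' gonion midpoint and the lateral/medial junction points, normal oriented
#' toward the condyle so the ramus is the positive side) and reports the
#' percentage and absolute volume falling in each segment.
#'
#' @param nonoverlap_mask Binary [voxel_mask] of non-overlapping voxels
#'   (e.g. `attr(res, "nonoverlap_mask")` from [mirrored_similarity()]).
#' @param sectioning_plane The ramus-body [plane] in superimposed space.
#' @return A one-row tibble: `ramus_fraction`, `body_fraction` (percent),
#'   `ramus_mm3`, `body_mm3`.
#' @export
segment_distribution <- function(nonoverlap_mask, sectioning_plane) {
  stopifnot(is_voxel_mask(nonoverlap_mask), is_plane(sectioning_plane))
  halves <- split_by_plane(nonoverlap_mask, sectioning_plane)
  nr <- sum(halves$positive$data)
  nb <- sum(halves$negative$data)
  tot <- nr + nb
  if (tot == 0L) {
    warning("empty non-overlap mask: segment fractions reported as 0",
            call. = FALSE)
    return(tibble::tibble(ramus_fraction = 0, body_fraction = 0,
                          ramus_mm3 = 0, body_mm3 = 0))
  }
  s3 <- nonoverlap_mask$spacing^3
  tibble::tibble(ramus_fraction = 100 * nr / tot,
                 body_fraction = 100 * nb / tot,
                 ramus_mm3 = nr * s3,
                 body_mm3 = nb * s3)
}

#' Menton deviation and side assignment
#'
#' The lateral deviation of the menton from the midsagittal plane defines
#' the deviated (Dev) side: positive signed distance means the menton
#' deviates toward the patient's left under the package's orientation
#' convention. Subjects qualify for the asymmetry analysis when the
#' deviation strictly exceeds the threshold (default 4 mm).
#'
#' @param landmarks A [landmark_set] containing `Me`.
#' @param msp The midsagittal [plane], normal toward the patient's left.
#' @param threshold_mm Inclusion threshold in mm (strict `>`).
#' @return A one-row tibble: `deviation_mm`, `dev_side` (`"left"`,
#'   `"right"`, or `"midline"`), `included`.
#' @export
assess_deviation <- function(landmarks, msp, threshold_mm = 4) {
  require_landmarks(landmarks, "Me")
  stopifnot(is_plane(msp))
  sd <- signed_distance(landmark_point(landmarks, "Me"), msp)
  dev_mm <- abs(sd)
  side <- if (dev_mm < 1e-6) "midline" else if (sd > 0) "left" else "right"
  tibble::tibble(deviation_mm = dev_mm, dev_side = side,
                 included = dev_mm > threshold_mm)
}
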