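#' Phantom specification
#'
#' Parameters of the synthetic mandible phantom: a horseshoe-shaped body
#' (half-annulus slab) carrying two vertical rami with spherical condylar
#' knobs, wrapped in a soft-tissue shell, embedded in an HU volume. All
#' lengths are mm. Asymmetry is applied to the right side only (per-axis
#' scale and yaw about the vertical axis) plus a whole-mandible lateral
#' shift, so the deviated side is known a priori from the parameters.
#'
#' Default HU values sit strictly inside the standard binarization bands
#' (bone 320-520, soft tissue -480 to -360), so thresholding a noiseless
#' phantom recovers the generated masks exactly.
#'
#' @param shape Grid dimensions (voxels). The default grid is centered on
#'   the midsagittal plane `x = 0`, which falls on a grid mid-plane.
#' @param spacing Voxel edge length, mm.
#' @param origin World coordinate of the first voxel center.
#' @param arc_radius Radius of the body arc (mm).
#' @param body_width,body_height Cross-section of the body slab (mm).
#' @param ramus_width,ramus_depth Cross-section of each ramus (mm).
#' @param ramus_height Height of the rami above the body plane (mm).
#' @param condyle_radius Radius of the condylar knobs (mm).
#' @param shell_mm Soft-tissue shell thickness (mm); 0 disables it.
#' @param hu_bone,hu_soft,hu_background HU values assigned to bone, soft
#'   tissue, and background.
#' @param right_scale Length-3 per-axis scale factor applied to the right
#'   hemi-mandible (about the midline/body planes).
#' @param lateral_shift_mm Whole-mandible shift along x (+ toward the
#'   patient's left); displaces the menton off the midsagittal plane.
#' @param right_yaw_deg Yaw of the right hemi-mandible about the vertical
#'   axis, degrees.
#' @param noise_sd Gaussian HU noise standard deviation (default 0).
#' @param seed Seed for the noise generator.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(108, 66, 68),
                         spacing = 1,
                         origin = c(-53.5, -18, -13),
                         arc_radius = 34,
                         body_width = 9,
                         body_height = 11,
                         ramus_width = 9,
                         ramus_depth = 13,
                         ramus_height = 42,
                         condyle_radius = 5.5,
                         shell_mm = 3,
                         hu_bone = 420,
                         hu_soft = -420,
                         hu_background = -1000,
                         right_scale = c(1, 1, 1),
                         lateral_shift_mm = 0,
                         right_yaw_deg = 0,
                         noise_sd = 0,
                         seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= 4),
            length(right_scale) == 3L, all(right_scale > 0),
            spacing > 0, shell_mm >= 0, noise_sd >= 0)
  if (hu_bone <= 320 || hu_bone >= 520) {
    stop("hu_bone must lie strictly inside the bone band (320, 520)",
         call. = FALSE)
  }
  if (shell_mm > 0 && (hu_soft <= -480 || hu_soft >= -360)) {
    stop("hu_soft must lie strictly inside the soft-tissue band (-480, -360)",
         call. = FALSE)
  }
  spec <- list(shape = as.integer(shape), spacing = spacing,
               origin = as.numeric(origin),
               arc_radius = arc_radius, body_width = body_width,
               body_height = body_height, ramus_width = ramus_width,
               ramus_depth = ramus_depth, ramus_height = ramus_height,
               condyle_radius = condyle_radius, shell_mm = shell_mm,
               hu_bone = hu_bone, hu_soft = hu_soft,
               hu_background = hu_background,
               right_scale = as.numeric(right_scale),
               lateral_shift_mm = lateral_shift_mm,
               right_yaw_deg = right_yaw_deg,
               noise_sd = noise_sd, seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  spec
}

# symmetric implicit mandible: TRUE where (x, y, z) is inside bone.
# Coordinates are vectors of equal length.
mandible_indicator <- function(spec, x, y, z) {
  R <- spec$arc_radius
  w2 <- spec$body_width / 2
  h2 <- spec$body_height / 2
  rad <- sqrt(x^2 + y^2)
  body <- y >= 0 & abs(rad - R) <= w2 & abs(z) <= h2
  ax <- abs(x)
  ramus <- abs(ax - R) <= spec$ramus_width / 2 &
    abs(y) <= spec$ramus_depth / 2 &
    z >= -h2 & z <= spec$ramus_height
  condyle <- (ax - R)^2 + y^2 + (z - spec$ramus_height)^2 <=
    spec$condyle_radius^2
  body | ramus | condyle
}

# analytic landmark positions of the symmetric left hemi-mandible plus the
# cranial reference landmarks (before asymmetry is applied)
phantom_base_landmarks <- function(spec) {
  R <- spec$arc_radius
  w2 <- spec$body_width / 2
  h2 <- spec$body_height / 2
  H <- spec$ramus_height
  dr2 <- spec$ramus_depth / 2
  wr2 <- spec$ramus_width / 2
  z_fhp <- H + 25
  go_post <- c(R, -dr2, 0)
  go_inf <- c(R, 0, -h2)
  list(
    midline = list(
      Me = c(0, R, -h2),
      Pog = c(0, R + w2, 0),
      B_point = c(0, R + w2, h2),
      G = c(0, R - w2, 0)),
    left = list(
      Con_left = c(R, 0, H + spec$condyle_radius),
      Go_post_left = go_post,
      Go_inf_left = go_inf,
      Go_mid_left = (go_post + go_inf) / 2,
      J_lat_left = c(R + wr2, dr2, h2),
      J_med_left = c(R - wr2, dr2, h2)),
    cranial = list(
      N = c(0, R, z_fhp + 8),
      S = c(0, 0, z_fhp + 10),
      Or_left = c(40, R, z_fhp),
      Po_left = c(52, -8, z_fhp),
      Po_right = c(-52, -8, z_fhp)),
    z_fhp = z_fhp)
}

# affine applied to the right hemi-mandible: scale about the midline/body
# planes, then yaw about the vertical axis
right_affine <- function(spec) {
  th <- spec$right_yaw_deg * pi / 180
  rot <- rbind(c(cos(th), -sin(th), 0),
               c(sin(th), cos(th), 0),
               c(0, 0, 1))
  rot %*% diag(spec$right_scale)
}

#' Generate a synthetic mandible phantom
#'
#' Builds the HU volume, the matching landmark set, and the ground truth
#' (applied asymmetry parameters and the analytic reference planes). The
#' left hemi-mandible is the symmetric template; the right hemi-mandible is
#' its mirror image deformed by `right_scale` and `right_yaw_deg`, and the
#' whole mandible is shifted laterally by `lateral_shift_mm`. Landmarks are
#' placed analytically from the parametric construction and transformed
#' consistently with the voxel model. The cranial landmarks (N, S, Po, Or)
#' are unaffected by the mandibular asymmetry, so the Frankfort and
#' midsagittal planes stay fixed.
#'
#' @param spec A [phantom_spec()].
#' @return A list: `volume` ([hu_volume]), `bone` (the generated bone
#'   [voxel_mask]), `soft` (soft-tissue mask or NULL), `landmarks`
#'   ([landmark_set]), `truth` (asymmetry parameters, expected deviation
#'   side, analytic `msp`/`fhp` planes).
#' @export
make_mandible_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  geom <- list(data = array(FALSE, d), spacing = spec$spacing,
               origin = spec$origin)
  cc <- axis_coords(geom)
  X <- array(cc$x, d)
  Y <- array(rep(cc$y, each = d[1]), d)
  Z <- array(rep(cc$z, each = d[1] * d[2]), d)

  # remove the global shift, then pull right-side voxels back through the
  # inverse of the right-side affine; the symmetric template does the rest
  xs <- as.numeric(X) - spec$lateral_shift_mm
  ys <- as.numeric(Y)
  zs <- as.numeric(Z)
  right <- xs < 0
  A_inv <- solve(right_affine(spec))
  if (any(right)) {
    q <- A_inv %*% rbind(xs[right], ys[right], zs[right])
    xs[right] <- q[1, ]
    ys[right] <- q[2, ]
    zs[right] <- q[3, ]
  }
  bone_arr <- array(mandible_indicator(spec, xs, ys, zs), d)
  if (!any(bone_arr)) {
    stop("phantom produced an empty bone mask", call. = FALSE)
  }
  if (touches_boundary(bone_arr)) {
    stop("phantom structure exceeds the grid; enlarge shape or shrink sizes",
         call. = FALSE)
  }
  bone <- voxel_mask(bone_arr, spec$spacing, spec$origin)

  soft <- NULL
  hu <- array(spec$hu_background, d)
  if (spec$shell_mm > 0) {
    shell_vox <- spec$shell_mm / spec$spacing
    soft_arr <- edt_sq(bone_arr) <= shell_vox^2 + 1e-9
    soft_arr <- soft_arr & !bone_arr
    if (touches_boundary(soft_arr)) {
      stop("soft-tissue shell exceeds the grid", call. = FALSE)
    }
    soft <- voxel_mask(array(soft_arr, d), spec$spacing, spec$origin)
    hu[soft_arr] <- spec$hu_soft
  }
  hu[bone_arr] <- spec$hu_bone
  if (spec$noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(spec$seed)
    hu <- hu + array(stats::rnorm(length(hu), 0, spec$noise_sd), d)
  }
  volume <- hu_volume(hu, spec$spacing, spec$origin)

  landmarks <- phantom_landmarks(spec)
  truth <- list(
    right_scale = spec$right_scale,
    lateral_shift_mm = spec$lateral_shift_mm,
    right_yaw_deg = spec$right_yaw_deg,
    dev_side = if (spec$lateral_shift_mm > 0) "left"
               else if (spec$lateral_shift_mm < 0) "right" else "midline",
    deviation_mm = abs(spec$lateral_shift_mm),
    msp = plane(c(1, 0, 0), 0),
    fhp = plane(c(0, 0, 1), phantom_base_landmarks(spec)$z_fhp))
  list(volume = volume, bone = bone, soft = soft,
       landmarks = landmarks, truth = truth)
}

phantom_landmarks <- function(spec) {
  base <- phantom_base_landmarks(spec)
  A <- right_affine(spec)
  shift <- c(spec$lateral_shift_mm, 0, 0)
  mirror_x <- function(p) c(-p[1], p[2], p[3])
  pts <- list()
  for (nm in names(base$midline)) {
    pts[[nm]] <- base$midline[[nm]] + shift
  }
  for (nm in names(base$left)) {
    pts[[nm]] <- base$left[[nm]] + shift
    rnm <- sub("_left$", "_right", nm)
    pts[[rnm]] <- as.numeric(A %*% mirror_x(base$left[[nm]])) + shift
  }
  for (nm in names(base$cranial)) {
    pts[[nm]] <- base$cranial[[nm]]
  }
  landmark_set(pts)
}

touches_boundary <- function(arr) {
  d <- dim(arr)
  any(arr[c(1, d[1]), , ]) || any(arr[, c(1, d[2]), ]) ||
    any(arr[, , c(1, d[3])])
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Mirror-symmetric box-pair phantom
#'
#' Two axis-aligned boxes placed on either side of the grid mid-plane
#' `x = 0`, corner-aligned after mirroring, as a closed-form oracle for the
#' similarity index: for corner-aligned boxes
#' `dice = 2 prod(min(l, r)) / (prod(l) + prod(r))`. A `right_offset_vox`
#' shifts the right box (in voxels) to create partially overlapping or
#' fully disjoint configurations; the expected dice follows from integer
#' interval overlaps and is returned alongside the masks.
#'
#' @param left_dims,right_dims Box dimensions in voxels (length 3,
#'   positive integers).
#' @param spacing Voxel edge length, mm.
#' @param right_offset_vox Integer shift of the right box; the x component
#'   moves it away from the mirror plane.
#' @return A list: `left`, `right`, `whole` (union) [voxel_mask]s on a
#'   shared grid, the mirror `plane`, and `dice_expected`.
#' @export
make_box_pair <- function(left_dims, right_dims, spacing = 1,
                          right_offset_vox = c(0, 0, 0)) {
  left_dims <- as.integer(left_dims)
  right_dims <- as.integer(right_dims)
  off <- as.integer(right_offset_vox)
  stopifnot(length(left_dims) == 3L, length(right_dims) == 3L,
            all(left_dims > 0), all(right_dims > 0), length(off) == 3L,
            all(off >= 0L))
  margin <- 2L
  half <- max(left_dims[1], right_dims[1] + abs(off[1])) + margin
  nx <- 2L * half
  ny <- max(left_dims[2], right_dims[2] + abs(off[2])) + 2L * margin
  nz <- max(left_dims[3], right_dims[3] + abs(off[3])) + 2L * margin
  d <- c(nx, ny, nz)
  origin <- c(-(nx - 1) / 2 * spacing, 0, 0)

  left_arr <- array(FALSE, d)
  right_arr <- array(FALSE, d)
  c0 <- nx %/% 2L  # last column with x < 0; mirror plane between c0 and c0+1
  left_arr[c0 + seq_len(left_dims[1]),
           margin + seq_len(left_dims[2]),
           margin + seq_len(left_dims[3])] <- TRUE
  right_arr[c0 - right_dims[1] - off[1] + seq_len(right_dims[1]),
            margin + off[2] + seq_len(right_dims[2]),
            margin + off[3] + seq_len(right_dims[3])] <- TRUE

  # mirrored-left occupies columns [c0 - lx + 1, c0]; expected overlap by
  # integer interval intersection per axis
  ov_axis <- function(a_start, a_len, b_start, b_len) {
    max(0L, min(a_start + a_len - 1L, b_start + b_len - 1L) -
          max(a_start, b_start) + 1L)
  }
  ox <- ov_axis(c0 - left_dims[1] + 1L, left_dims[1],
                c0 - right_dims[1] + 1L - off[1], right_dims[1])
  oy <- ov_axis(margin + 1L, left_dims[2], margin + 1L + off[2],
                right_dims[2])
  oz <- ov_axis(margin + 1L, left_dims[3], margin + 1L + off[3],
                right_dims[3])
  inter <- as.numeric(ox) * oy * oz
  dice_expected <- 2 * inter / (prod(left_dims) + prod(right_dims))

  list(left = voxel_mask(left_arr, spacing, origin),
       right = voxel_mask(right_arr, spacing, origin),
       whole = voxel_mask(left_arr | right_arr, spacing, origin),
       plane = plane(c(1, 0, 0), 0),
       dice_expected = dice_expected)
}

#' Generate a synthetic surgical cohort
#'
#' Draws per-subject pre-treatment (T1) asymmetry parameters and shrinks
#' them by `reduction` for the post-treatment (T2) state, emulating a
#' cohort whose asymmetry decreases after surgery: T2 parameter =
#' identity + (T1 parameter - identity) x reduction. The deviated side is
#' randomized per subject via the sign of the lateral shift. Deterministic
#' under a fixed seed.
#'
#' @param n Number of subjects (>= 2).
#' @param reduction Asymmetry reduction factor at T2 in `[0, 1]`; 0 makes
#'   every T2 phantom perfectly symmetric, 1 leaves asymmetry unchanged.
#' @param shift_range Range (mm) of the absolute T1 lateral shift; the
#'   default keeps every T1 menton deviation above the 4 mm inclusion
#'   threshold.
#' @param scale_z_range Range of the T1 right-side vertical scale.
#' @param yaw_sd Standard deviation (degrees) of the T1 right-side yaw.
#' @param seed Integer seed.
#' @param base_spec Template [phantom_spec()] supplying grid and anatomy.
#' @return A tibble with one row per subject x timepoint and the asymmetry
#'   parameter columns; pass rows to [realize_subject()] or the whole table
#'   to [run_cohort()].
#' @export
make_cohort <- function(n = 20, reduction = 0.5,
                        shift_range = c(4.5, 8),
                        scale_z_range = c(0.78, 0.95),
                        yaw_sd = 2,
                        seed = 1L,
                        base_spec = phantom_spec()) {
  stopifnot(n >= 2, reduction >= 0, reduction <= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  shift <- stats::runif(n, shift_range[1], shift_range[2]) *
    sample(c(-1, 1), n, replace = TRUE)
  scale_z <- stats::runif(n, scale_z_range[1], scale_z_range[2])
  yaw <- stats::rnorm(n, 0, yaw_sd)
  t1 <- tibble::tibble(subject = seq_len(n), timepoint = "T1",
                       lateral_shift_mm = shift,
                       right_scale_z = scale_z,
                       right_yaw_deg = yaw)
  t2 <- tibble::tibble(subject = seq_len(n), timepoint = "T2",
                       lateral_shift_mm = shift * reduction,
                       right_scale_z = 1 + (scale_z - 1) * reduction,
                       right_yaw_deg = yaw * reduction)
  out <- dplyr::arrange(dplyr::bind_rows(t1, t2), .data$subject,
                        .data$timepoint)
  attr(out, "base_spec") <- base_spec
  attr(out, "reduction") <- reduction
  attr(out, "seed") <- seed
  class(out) <- c("asym_cohort", class(out))
  out
}

#' Realize one cohort row as a phantom
#'
#' @param row One row of a [make_cohort()] table.
#' @param base_spec Template [phantom_spec()].
#' @return The [make_mandible_phantom()] output for that subject/timepoint.
#' @export
realize_subject <- function(row, base_spec = phantom_spec()) {
  spec <- base_spec
  spec$lateral_shift_mm <- row$lateral_shift_mm
  spec$right_scale <- c(1, 1, row$right_scale_z)
  spec$right_yaw_deg <- row$right_yaw_deg
  make_mandible_phantom(spec)
}
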