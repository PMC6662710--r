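#' Oriented infinite plane
#'
#' A plane is stored in Hessian normal form as \eqn{\{p : n \cdot p = d\}}
#' with a unit normal `n` (dimensionless) and a signed offset `d` in mm.
#' Points with `signed_distance() > 0` lie on the side the normal points to.
#'
#' @param normal Numeric length-3 normal vector (normalized internally).
#' @param offset Signed offset in mm along the unit normal.
#' @return An object of class `plane`.
#' @examples
#' msp <- plane(c(1, 0, 0), 0)   # the x = 0 plane
#' signed_distance(c(3, 2, 1), msp)
#' @export
plane <- function(normal, offset) {
  normal <- as.numeric(normal)
  offset <- as.numeric(offset)
  stopifnot(length(normal) == 3L, length(offset) == 1L)
  if (!all(is.finite(normal)) || !is.finite(offset)) {
    stop("plane parameters must be finite", call. = FALSE)
  }
  nn <- sqrt(sum(normal^2))
  if (nn < 1e-12) {
    stop("degenerate geometry: zero-length plane normal", call. = FALSE)
  }
  structure(list(normal = normal / nn, offset = offset / nn),
            class = "plane")
}

#' @export
print.plane <- function(x, ...) {
  cat(sprintf("<plane> n = (%.6f, %.6f, %.6f), d = %.6f mm\n",
              x$normal[1], x$normal[2], x$normal[3], x$offset))
  invisible(x)
}

is_plane <- function(x) inherits(x, "plane")

#' Plane through three points
#'
#' Constructs the plane containing three non-collinear points. The normal
#' direction follows the cross product `(p2 - p1) x (p3 - p1)`, so the
#' orientation is fixed by the point order. Used for the mandibular median
#' plane (through menton, supramentale, and the genial tubercle) and for the
#' ramus-body sectioning plane (through gonion midpoint and the lateral and
#' medial junction points).
#'
#' @param p1,p2,p3 Numeric length-3 points in mm.
#' @return A [plane].
#' @examples
#' plane_from_points(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))  # z = 0
#' @export
plane_from_points <- function(p1, p2, p3) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2); p3 <- as.numeric(p3)
  n <- cross3(p2 - p1, p3 - p1)
  if (sqrt(sum(n^2)) < 1e-12) {
    stop("degenerate geometry: points are collinear or coincident",
         call. = FALSE)
  }
  plane(n, sum(n * p1))
}

#' Plane through two points, perpendicular to a reference plane
#'
#' Constructs the plane that contains both anchor points and is perpendicular
#' to `ref`. This realizes the midsagittal plane: through nasion and sella,
#' perpendicular to the Frankfort horizontal plane. The normal is
#' `normalize((p2 - p1) x n_ref)`.
#'
#' @param p1,p2 Numeric length-3 anchor points in mm.
#' @param ref Reference [plane] the result must be perpendicular to.
#' @return A [plane] containing `p1` and `p2` with normal orthogonal to
#'   `ref`'s normal.
#' @export
plane_through_two_points_perpendicular_to <- function(p1, p2, ref) {
  stopifnot(is_plane(ref))
  p1 <- as.numeric(p1); p2 <- as.numeric(p2)
  n <- cross3(p2 - p1, ref$normal)
  if (sqrt(sum(n^2)) < 1e-12) {
    stop(paste("degenerate geometry: anchor direction is parallel to the",
               "reference normal (or points coincide)"), call. = FALSE)
  }
  n <- n / sqrt(sum(n^2))
  plane(n, sum(n * p1))
}

#' Signed distance from point(s) to a plane
#'
#' Returns `n . p - d` in mm: positive on the side the normal points to,
#' zero on the plane. With the package's orientation convention (midsagittal
#' normal toward the patient's left) a positive distance means "left side",
#' which is how the deviation side of the menton is determined.
#'
#' @param p Numeric length-3 point, or an N x 3 matrix of points (mm).
#' @param plane A [plane].
#' @return Signed distance(s) in mm.
#' @export
signed_distance <- function(p, plane) {
  stopifnot(is_plane(plane))
  if (is.matrix(p)) {
    stopifnot(ncol(p) == 3L)
    return(as.numeric(p %*% plane$normal) - plane$offset)
  }
  sum(as.numeric(p) * plane$normal) - plane$offset
}

#' Reflect point(s) through a plane
#'
#' Mirror image of `p` across `plane`: `p' = p - 2 (n.p - d) n`. Reflection
#' is an involution and an isometry; the signed distance changes sign.
#'
#' @inheritParams signed_distance
#' @return Reflected point(s), same shape as the input.
#' @export
reflect_point <- function(p, plane) {
  stopifnot(is_plane(plane))
  if (is.matrix(p)) {
    sd <- as.numeric(p %*% plane$normal) - plane$offset
    return(p - 2 * outer(sd, plane$normal))
  }
  p <- as.numeric(p)
  p - 2 * (sum(p * plane$normal) - plane$offset) * plane$normal
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rigid transform (rotation + translation)
#'
#' @param rotation 3 x 3 rotation matrix (orthonormal, determinant +1).
#' @param translation Numeric length-3 translation in mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9) {
    stop("rotation matrix is not orthonormal", call. = FALSE)
  }
  if (abs(det(rotation) - 1) > 1e-9) {
    stop("rotation matrix must be proper (det +1)", call. = FALSE)
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  print(round(x$rotation, 6))
  cat(sprintf("translation: (%.4f, %.4f, %.4f) mm\n",
              x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Apply or invert a rigid transform
#'
#' `apply_transform()` maps points `p` to `R p + t`; `invert_transform()`
#' returns the inverse transform.
#'
#' @param tf A [rigid_transform].
#' @param p Numeric length-3 point or N x 3 matrix.
#' @return Transformed point(s) / the inverse `rigid_transform`.
#' @export
apply_transform <- function(tf, p) {
  stopifnot(inherits(tf, "rigid_transform"))
  if (is.matrix(p)) {
    return(p %*% t(tf$rotation) +
             matrix(tf$translation, nrow(p), 3, byrow = TRUE))
  }
  as.numeric(tf$rotation %*% as.numeric(p)) + tf$translation
}

#' @rdname apply_transform
#' @export
invert_transform <- function(tf) {
  stopifnot(inherits(tf, "rigid_transform"))
  rigid_transform(t(tf$rotation),
                  -as.numeric(t(tf$rotation) %*% tf$translation))
}

#' Transform a plane by a rigid transform
#'
#' @param tf A [rigid_transform].
#' @param plane A [plane].
#' @return The transformed [plane]: normal rotated, offset updated so the
#'   transformed plane contains the images of the original plane's points.
#' @export
transform_plane <- function(tf, plane) {
  stopifnot(inherits(tf, "rigid_transform"), is_plane(plane))
  n2 <- as.numeric(tf$rotation %*% plane$normal)
  p0 <- apply_transform(tf, plane$normal * plane$offset)
  plane(n2, sum(n2 * p0))
}

#' Reorientation transform from the two reference planes
#'
#' Builds the rigid transform that standardizes patient orientation from the
#' Frankfort horizontal plane (FHP) and the midsagittal plane (MSP): after
#' the transform the MSP is the `x = 0` plane and the FHP is a constant-z
#' plane, with +x toward the patient's left (the MSP normal's direction) and
#' +z superior (the FHP normal's direction). `origin` (conventionally nasion,
#' which lies on the MSP) maps to a point with `x = 0` and `y = 0`.
#'
#' @param fhp Frankfort horizontal [plane], normal oriented superiorly.
#' @param msp Midsagittal [plane], normal oriented toward the patient's left;
#'   must be perpendicular to `fhp` (within 1e-6 rad).
#' @param origin Anatomical origin in mm (default the zero point).
#' @return A [rigid_transform].
#' @export
reorientation_transform <- function(fhp, msp, origin = c(0, 0, 0)) {
  stopifnot(is_plane(fhp), is_plane(msp))
  origin <- as.numeric(origin)
  dt <- sum(fhp$normal * msp$normal)
  if (abs(dt) > 1e-6) {
    stop(sprintf(
      "geometry inconsistency: FHP and MSP are not perpendicular (|cos| = %g)",
      abs(dt)), call. = FALSE)
  }
  ex <- msp$normal                  # patient left
  ez <- fhp$normal                  # superior
  ey <- cross3(ez, ex)              # anterior-posterior axis completing RHS
  rot <- rbind(ex, ey, ez)
  dimnames(rot) <- NULL
  translation <- c(-msp$offset, -sum(ey * origin), -fhp$offset)
  rigid_transform(rot, translation)
}
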