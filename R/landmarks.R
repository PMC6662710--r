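#' Cephalometric landmark sets
#'
#' A landmark set is a tibble with columns `name`, `x`, `y`, `z` (mm, world
#' coordinates) and class `landmark_set`. The canonical names follow standard
#' cephalometric usage: midline points `N` (nasion), `S` (sella), `Me`
#' (menton), `Pog` (pogonion), `B_point` (supramentale; named `B_point` so it
#' cannot be confused with the volume symbol in the similarity index), `G`
#' (genial tubercle); bilateral points `Con` (condylion), `J_lat`, `J_med`
#' (lateral/medial ramus-body junction), `Go_post`, `Go_mid`, `Go_inf`
#' (gonion posterius/midpoint/inferius) with `_left`/`_right` suffixes; and
#' the reference-plane points `Or_left` (left orbitale), `Po_left`,
#' `Po_right` (porion).
#'
#' @param x A data frame with columns `name`, `x`, `y`, `z`, or a named list
#'   of length-3 numeric points.
#' @return A `landmark_set` tibble.
#' @examples
#' lms <- landmark_set(list(N = c(0, 60, 90), S = c(0, 30, 95)))
#' landmark_point(lms, "N")
#' @export
landmark_set <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("name", "x", "y", "z") %in% names(x)))
    nm <- as.character(x[["name"]])
    xs <- as.numeric(x[["x"]]); ys <- as.numeric(x[["y"]])
    zs <- as.numeric(x[["z"]])
    tb <- tibble::tibble(name = nm, x = xs, y = ys, z = zs)
  } else if (is.list(x)) {
    stopifnot(!is.null(names(x)), all(vapply(x, length, 1L) == 3L))
    m <- unname(do.call(rbind, lapply(x, as.numeric)))
    tb <- tibble::tibble(name = names(x), x = m[, 1], y = m[, 2], z = m[, 3])
  } else {
    stop("landmark_set() expects a data frame or a named list of points",
         call. = FALSE)
  }
  if (anyDuplicated(tb$name)) {
    stop("duplicate landmark names: ",
         paste(unique(tb$name[duplicated(tb$name)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(c(tb$x, tb$y, tb$z)))) {
    stop("landmark coordinates must be finite", call. = FALSE)
  }
  class(tb) <- c("landmark_set", class(tb))
  tb
}

#' @rdname landmark_set
#' @param lms A `landmark_set`.
#' @param name Landmark name to extract.
#' @export
landmark_point <- function(lms, name) {
  i <- match(name, lms$name)
  if (is.na(i)) {
    stop("missing landmark: ", name, call. = FALSE)
  }
  unname(c(lms$x[i], lms$y[i], lms$z[i]))
}

require_landmarks <- function(lms, names) {
  missing <- setdiff(names, lms$name)
  if (length(missing)) {
    stop("missing landmarks: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (nm in intersect(names, lms$name)) {
    other <- sub("_left$", "_right", nm)
    if (other != nm && other %in% names && other %in% lms$name) {
      if (all(landmark_point(lms, nm) == landmark_point(lms, other))) {
        stop("left/right landmark pair coincides: ", nm, " / ", other,
             call. = FALSE)
      }
    }
  }
  invisible(lms)
}

#' Read landmarks from JSON or CSV
#'
#' JSON files are an object mapping landmark name to an `[x, y, z]` array in
#' mm; CSV files have columns `name,x,y,z`. Unknown names are preserved and
#' simply ignored by downstream computations.
#'
#' @param path Path to a `.json` or `.csv` landmark file.
#' @return A [landmark_set].
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) {
    stop("landmark file not found: ", path, call. = FALSE)
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    landmark_set(as.list(obj))
  } else {
    landmark_set(utils::read.csv(path, stringsAsFactors = FALSE))
  }
}

#' Write landmarks to JSON
#'
#' @param lms A [landmark_set].
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(lms, path) {
  pts <- stats::setNames(
    lapply(seq_len(nrow(lms)), function(i) c(lms$x[i], lms$y[i], lms$z[i])),
    lms$name)
  jsonlite::write_json(pts, path, digits = NA)
  invisible(path)
}

#' Apply a rigid transform to a landmark set
#'
#' @param lms A [landmark_set].
#' @param tf A [rigid_transform].
#' @return The transformed `landmark_set`.
#' @export
transform_landmarks <- function(lms, tf) {
  m <- apply_transform(tf, as.matrix(lms[, c("x", "y", "z")]))
  out <- lms
  out$x <- m[, 1]; out$y <- m[, 2]; out$z <- m[, 3]
  out
}

#' Construct the cephalometric reference planes
#'
#' Builds, from a landmark set:
#' \describe{
#'   \item{`fhp`}{Frankfort horizontal plane through both porions and the
#'     left orbitale, normal oriented superiorly (nasion on the positive
#'     side).}
#'   \item{`msp`}{facial midsagittal plane through nasion and sella,
#'     perpendicular to the FHP, normal oriented toward the patient's left
#'     (left porion on the positive side).}
#'   \item{`amp`}{mandibular median plane through menton, supramentale and
#'     the genial tubercle, normal co-oriented with the MSP normal.}
#'   \item{`sectioning_left`, `sectioning_right`}{per-side ramus-body
#'     sectioning planes through gonion midpoint and the lateral/medial
#'     junction points, normal oriented toward the condyle (ramus on the
#'     positive side).}
#' }
#'
#' @param lms A [landmark_set] containing the required named landmarks.
#' @return A named list of [plane] objects.
#' @export
reference_planes <- function(lms) {
  require_landmarks(lms, c("N", "S", "Or_left", "Po_left", "Po_right",
                           "Me", "B_point", "G",
                           "Go_mid_left", "Go_mid_right",
                           "J_lat_left", "J_lat_right",
                           "J_med_left", "J_med_right",
                           "Con_left", "Con_right"))
  fhp <- plane_from_points(landmark_point(lms, "Po_left"),
                           landmark_point(lms, "Po_right"),
                           landmark_point(lms, "Or_left"))
  fhp <- orient_plane(fhp, landmark_point(lms, "N"))
  msp <- plane_through_two_points_perpendicular_to(
    landmark_point(lms, "N"), landmark_point(lms, "S"), fhp)
  msp <- orient_plane(msp, landmark_point(lms, "Po_left"))
  amp <- plane_from_points(landmark_point(lms, "Me"),
                           landmark_point(lms, "B_point"),
                           landmark_point(lms, "G"))
  if (sum(amp$normal * msp$normal) < 0) amp <- flip_plane(amp)
  sec <- lapply(c(left = "left", right = "right"), function(side) {
    p <- plane_from_points(landmark_point(lms, paste0("Go_mid_", side)),
                           landmark_point(lms, paste0("J_lat_", side)),
                           landmark_point(lms, paste0("J_med_", side)))
    orient_plane(p, landmark_point(lms, paste0("Con_", side)))
  })
  list(fhp = fhp, msp = msp, amp = amp,
       sectioning_left = sec$left, sectioning_right = sec$right)
}

# flip the normal so that `toward` lies on the positive side
orient_plane <- function(pl, toward) {
  if (signed_distance(toward, pl) < 0) flip_plane(pl) else pl
}

flip_plane <- function(pl) plane(-pl$normal, -pl$offset)
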