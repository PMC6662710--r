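#' Euclidean distance between two landmarks or points
#'
#' @param a,b Length-3 points in mm.
#' @return Distance in mm.
#' @export
linear_distance <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) == 3L, length(b) == 3L, all(is.finite(c(a, b))))
  sqrt(sum((a - b)^2))
}

#' Ramal and body lengths per side
#'
#' Ramal length is the condylion to gonion-midpoint distance; body length
#' is the gonion-midpoint to menton distance.
#'
#' @param landmarks A [landmark_set].
#' @return A tibble with one row per side (`left`, `right`) and columns
#'   `ramal_length`, `body_length` in mm.
#' @export
linear_measurements <- function(landmarks) {
  require_landmarks(landmarks, c("Con_left", "Con_right",
                                 "Go_mid_left", "Go_mid_right", "Me"))
  me <- landmark_point(landmarks, "Me")
  purrr::map_dfr(c("left", "right"), function(side) {
    con <- landmark_point(landmarks, paste0("Con_", side))
    go <- landmark_point(landmarks, paste0("Go_mid_", side))
    tibble::tibble(side = side,
                   ramal_length = linear_distance(con, go),
                   body_length = linear_distance(go, me))
  })
}

#' Deviated-minus-non-deviated difference
#'
#' Bilateral comparisons report the measurement on the deviated (Dev) side
#' minus the measurement on the non-deviated (N-Dev) side.
#'
#' @param dev_value,ndev_value Values in the same units.
#' @param quantity Optional quantity label.
#' @return A one-row tibble: `quantity`, `dev_value`, `ndev_value`,
#'   `difference`.
#' @export
bilateral_difference <- function(dev_value, ndev_value, quantity = NA_character_) {
  tibble::tibble(quantity = quantity,
                 dev_value = as.numeric(dev_value),
                 ndev_value = as.numeric(ndev_value),
                 difference = as.numeric(dev_value) - as.numeric(ndev_value))
}

#' Hemi- and segment-wise surface/volume measurements
#'
#' Splits a preprocessed structure mask (binarize, fill, close already
#' applied) into its two halves by the requested reference plane, optionally
#' sections each half into ramus and body with that side's sectioning plane,
#' and measures volume and surface area of every piece. Halves are labelled
#' `dev`/`ndev` through the menton deviation relative to the midsagittal
#' plane.
#'
#' @param mask A preprocessed [voxel_mask].
#' @param landmarks A [landmark_set] with the reference-plane landmarks.
#' @param reference Which reference plane(s) to split by: `"AMP"` (the
#'   mandibular median plane), `"MSP"` (the facial midsagittal plane), or
#'   both.
#' @param segments Also measure the ramus/body segments of each half.
#' @param exclude_cut_surface Exclude the artificial cut faces (on the
#'   reference and sectioning planes) from surface areas.
#' @param surface_mode Passed to [surface_area_mm2()].
#' @return A tibble with one row per reference plane x side x segment
#'   (`hemi`, and with `segments = TRUE` also `ramus`/`body`), columns
#'   `volume_mm3` and `surface_mm2`, plus `dev_side` and `deviation_mm`.
#' @export
measure_structure <- function(mask, landmarks,
                              reference = c("AMP", "MSP"),
                              segments = TRUE,
                              exclude_cut_surface = TRUE,
                              surface_mode = "face_count") {
  stopifnot(is_voxel_mask(mask))
  reference <- match.arg(reference, several.ok = TRUE)
  planes <- reference_planes(landmarks)
  dev <- assess_deviation(landmarks, planes$msp)
  # positive side = patient left under the orientation convention
  side_label <- function(geom_side) {
    if (dev$dev_side == "midline") return(geom_side)
    if (geom_side == "left") {
      if (dev$dev_side == "left") "dev" else "ndev"
    } else {
      if (dev$dev_side == "right") "dev" else "ndev"
    }
  }
  rows <- list()
  for (ref in reference) {
    split_plane <- if (ref == "AMP") planes$amp else planes$msp
    halves <- split_by_plane(mask, split_plane)
    for (geom_side in c("left", "right")) {
      half <- if (geom_side == "left") halves$positive else halves$negative
      sec <- planes[[paste0("sectioning_", geom_side)]]
      excl_hemi <- if (exclude_cut_surface) list(split_plane) else NULL
      rows[[length(rows) + 1L]] <- tibble::tibble(
        reference_plane = ref, side = side_label(geom_side), segment = "hemi",
        volume_mm3 = volume_mm3(half),
        surface_mm2 = surface_area_mm2(half, surface_mode,
                                       exclude = excl_hemi))
      if (segments) {
        parts <- split_by_plane(half, sec)
        for (seg in c("ramus", "body")) {
          piece <- if (seg == "ramus") parts$positive else parts$negative
          excl <- if (exclude_cut_surface) list(split_plane, sec) else NULL
          rows[[length(rows) + 1L]] <- tibble::tibble(
            reference_plane = ref, side = side_label(geom_side),
            segment = seg,
            volume_mm3 = volume_mm3(piece),
            surface_mm2 = surface_area_mm2(piece, surface_mode,
                                           exclude = excl))
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out$dev_side <- dev$dev_side
  out$deviation_mm <- dev$deviation_mm
  out
}

#' Dev-minus-N-Dev differences from a measurement table
#'
#' @param measurements Output of [measure_structure()] (rows labelled
#'   `dev`/`ndev`).
#' @return A tibble with one row per reference plane x segment x quantity
#'   and columns `dev_value`, `ndev_value`, `difference`.
#' @export
bilateral_differences <- function(measurements) {
  long <- tidyr::pivot_longer(
    measurements[, c("reference_plane", "side", "segment",
                     "volume_mm3", "surface_mm2")],
    cols = c("volume_mm3", "surface_mm2"),
    names_to = "quantity", values_to = "value")
  wide <- tidyr::pivot_wider(long, names_from = "side",
                             values_from = "value")
  if (!all(c("dev", "ndev") %in% names(wide))) {
    stop("measurements must carry dev/ndev side labels (menton off midline)",
         call. = FALSE)
  }
  dplyr::mutate(
    dplyr::rename(wide, dev_value = "dev", ndev_value = "ndev"),
    difference = .data$dev_value - .data$ndev_value)
}
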