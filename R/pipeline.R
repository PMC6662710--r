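#' Pipeline configuration
#'
#' Bundles every tunable parameter of the measurement pipeline with the
#' protocol defaults: bone band 320-520 HU, soft-tissue band -480 to -360
#' HU, spherical closing radius 10 voxels, menton-deviation inclusion
#' threshold 4 mm, face-count surface mode, nearest-neighbor mirroring.
#'
#' @param bone_band,soft_band [hu_band]s for binarization.
#' @param closing_radius Spherical closing radius in voxels.
#' @param surface_mode `"face_count"` or `"slice_perimeter"`.
#' @param reference Reference plane(s) for splitting/mirroring.
#' @param deviation_threshold_mm Menton-deviation inclusion threshold (mm).
#' @param interpolation Mirroring interpolation, `"nearest"` or `"linear"`.
#' @param exclude_cut_surface Drop artificial cut faces from surface areas.
#' @param fill,close Enable hole filling / morphological closing.
#' @param segments Also measure ramus/body segments in [measure_subject()].
#' @param seed Integer seed forwarded to stochastic steps.
#' @return A `run_config` list.
#' @export
run_config <- function(bone_band = hu_band_bone(),
                       soft_band = hu_band_soft_tissue(),
                       closing_radius = 10,
                       surface_mode = "face_count",
                       reference = c("AMP", "MSP"),
                       deviation_threshold_mm = 4,
                       interpolation = "nearest",
                       exclude_cut_surface = TRUE,
                       fill = TRUE,
                       close = TRUE,
                       segments = FALSE,
                       seed = 1L) {
  reference <- match.arg(reference, c("AMP", "MSP"), several.ok = TRUE)
  stopifnot(inherits(bone_band, "hu_band"), inherits(soft_band, "hu_band"),
            closing_radius >= 1, deviation_threshold_mm >= 0)
  structure(list(bone_band = bone_band, soft_band = soft_band,
                 closing_radius = as.integer(closing_radius),
                 surface_mode = surface_mode, reference = reference,
                 deviation_threshold_mm = deviation_threshold_mm,
                 interpolation = interpolation,
                 exclude_cut_surface = exclude_cut_surface,
                 fill = fill, close = close, segments = segments,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Preprocess an HU volume into a clean structure mask
#'
#' Binarization in the requested band, hole filling, and spherical
#' morphological closing — the cleanup chain applied before any
#' measurement.
#'
#' @param volume An [hu_volume] (a [voxel_mask] passes through binarization
#'   untouched).
#' @param band An [hu_band].
#' @param config A [run_config()].
#' @return A [voxel_mask].
#' @export
preprocess_mask <- function(volume, band = hu_band_bone(),
                            config = run_config()) {
  mask <- if (is_voxel_mask(volume)) volume else binarize(volume, band)
  if (config$fill) mask <- fill_holes(mask)
  if (config$close) mask <- morph_close(mask, config$closing_radius)
  if (config$fill) mask <- fill_holes(mask)
  mask
}

#' Measure one subject at one timepoint
#'
#' Runs the full per-scan pipeline: preprocess, build reference planes,
#' assess the menton deviation, split/mirror/superimpose per requested
#' reference plane, segment the non-overlapping volume into ramus and body,
#' and collect the conventional hemi measurements with Dev/N-Dev labels.
#' For `structure = "soft_tissue"` the soft-tissue band is used, the volume
#' above the Frankfort plane is removed, and only the midsagittal plane is
#' used as reference.
#'
#' @param volume An [hu_volume] (or an already preprocessed [voxel_mask]).
#' @param landmarks A [landmark_set].
#' @param config A [run_config()].
#' @param structure `"mandible"` or `"soft_tissue"`.
#' @return A tibble with one row per reference plane: similarity index,
#'   non-overlapping volume, segment distribution, deviation, hemi
#'   volume/surface on the Dev and N-Dev sides and their differences, and
#'   ramal/body lengths.
#' @export
measure_subject <- function(volume, landmarks, config = run_config(),
                            structure = c("mandible", "soft_tissue")) {
  structure <- match.arg(structure)
  planes <- reference_planes(landmarks)
  band <- if (structure == "mandible") config$bone_band else config$soft_band
  mask <- preprocess_mask(volume, band, config)
  if (structure == "soft_tissue") {
    mask <- crop_below_plane(mask, planes$fhp)
  }
  dev <- assess_deviation(landmarks, planes$msp, config$deviation_threshold_mm)
  refs <- if (structure == "soft_tissue") "MSP" else config$reference
  lengths <- linear_measurements(landmarks)
  dev_geom <- dev$dev_side        # "left" / "right" / "midline"
  pick <- function(tb, side_col, value_col, want) {
    if (dev_geom == "midline") return(NA_real_)
    geom <- if (want == "dev") dev_geom else setdiff(c("left", "right"),
                                                     dev_geom)
    tb[[value_col]][tb[[side_col]] == geom]
  }

  purrr::map_dfr(refs, function(ref) {
    split_plane <- if (ref == "AMP") planes$amp else planes$msp
    res <- mirrored_similarity(mask, split_plane,
                               interpolation = config$interpolation)
    # the mirrored left half lands on the right (negative) side: segment
    # the non-overlap with the right-side ramus-body plane
    seg <- segment_distribution(attr(res, "nonoverlap_mask"),
                                planes$sectioning_right)
    halves <- split_by_plane(mask, split_plane)
    excl <- if (config$exclude_cut_surface) list(split_plane) else NULL
    hemi <- list(
      left = list(volume = volume_mm3(halves$positive),
                  surface = surface_area_mm2(halves$positive,
                                             config$surface_mode,
                                             exclude = excl)),
      right = list(volume = volume_mm3(halves$negative),
                   surface = surface_area_mm2(halves$negative,
                                              config$surface_mode,
                                              exclude = excl)))
    hv <- function(want, q) {
      if (dev_geom == "midline") return(NA_real_)
      geom <- if (want == "dev") dev_geom else setdiff(c("left", "right"),
                                                       dev_geom)
      hemi[[geom]][[q]]
    }
    tibble::tibble(
      structure = structure,
      reference_plane = ref,
      dice = res$dice,
      nonoverlap_mm3 = res$nonoverlap_mm3,
      ramus_fraction = seg$ramus_fraction,
      body_fraction = seg$body_fraction,
      deviation_mm = dev$deviation_mm,
      dev_side = dev$dev_side,
      included = dev$included,
      hemi_volume_dev = hv("dev", "volume"),
      hemi_volume_ndev = hv("ndev", "volume"),
      hemi_volume_difference = hv("dev", "volume") - hv("ndev", "volume"),
      hemi_surface_dev = hv("dev", "surface"),
      hemi_surface_ndev = hv("ndev", "surface"),
      hemi_surface_difference = hv("dev", "surface") - hv("ndev", "surface"),
      ramal_length_dev = pick(lengths, "side", "ramal_length", "dev"),
      ramal_length_ndev = pick(lengths, "side", "ramal_length", "ndev"),
      body_length_dev = pick(lengths, "side", "body_length", "dev"),
      body_length_ndev = pick(lengths, "side", "body_length", "ndev"))
  })
}

#' Run the measurement pipeline on one scan
#'
#' File-level wrapper around [measure_subject()]: accepts NIfTI/landmark
#' paths or in-memory objects, optionally writes a per-subject CSV and a
#' JSON result (with the full effective configuration as a provenance
#' block), and returns everything computed.
#'
#' @param volume Path to a NIfTI volume or an [hu_volume]/[voxel_mask].
#' @param landmarks Path to a JSON/CSV landmark file or a [landmark_set].
#' @param config A [run_config()].
#' @param out_dir Optional output directory for `measurements.csv` and
#'   `results.json`.
#' @param structure `"mandible"` or `"soft_tissue"`.
#' @return A list: `records` (the [measure_subject()] tibble), `planes`,
#'   `config`; invisibly writes files when `out_dir` is given.
#' @export
run_measure <- function(volume, landmarks, config = run_config(),
                        out_dir = NULL,
                        structure = c("mandible", "soft_tissue")) {
  structure <- match.arg(structure)
  if (is.character(volume)) volume <- read_hu_volume(volume)
  if (is.character(landmarks)) landmarks <- read_landmarks(landmarks)
  planes <- reference_planes(landmarks)
  records <- measure_subject(volume, landmarks, config, structure)
  out <- list(records = records, planes = planes, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(records, file.path(out_dir, "measurements.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(records = records, config = config_provenance(config)),
      file.path(out_dir, "results.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

config_provenance <- function(config) {
  list(package = "facesym",
       version = as.character(utils::packageVersion("facesym")),
       bone_band = unclass(config$bone_band),
       soft_band = unclass(config$soft_band),
       closing_radius = config$closing_radius,
       surface_mode = config$surface_mode,
       reference = config$reference,
       deviation_threshold_mm = config$deviation_threshold_mm,
       interpolation = config$interpolation,
       exclude_cut_surface = config$exclude_cut_surface,
       fill = config$fill, close = config$close,
       segments = config$segments, seed = config$seed)
}

#' Run the pipeline over a synthetic cohort
#'
#' Realizes every subject x timepoint of a [make_cohort()] table as a
#' phantom, pushes each through [measure_subject()], and returns the
#' combined per-subject records, ready for [build_cohort_tables()].
#'
#' @param cohort A [make_cohort()] table (or any tibble with the same
#'   parameter columns).
#' @param config A [run_config()].
#' @param base_spec Template [phantom_spec()]; defaults to the one attached
#'   to the cohort.
#' @param progress Print one line per realized scan.
#' @return A tibble of records with class `asym_records` (one row per
#'   subject x timepoint x reference plane), carrying the true asymmetry
#'   parameters alongside the measured quantities.
#' @export
run_cohort <- function(cohort, config = run_config(),
                       base_spec = NULL, progress = FALSE) {
  stopifnot(is.data.frame(cohort))
  if (is.null(base_spec)) base_spec <- attr(cohort, "base_spec")
  if (is.null(base_spec)) base_spec <- phantom_spec()
  rows <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    row <- cohort[i, ]
    if (progress) {
      message(sprintf("subject %s %s", row$subject, row$timepoint))
    }
    ph <- realize_subject(row, base_spec)
    rec <- measure_subject(ph$volume, ph$landmarks, config)
    rec$subject <- row$subject
    rec$timepoint <- row$timepoint
    rec$true_shift_mm <- row$lateral_shift_mm
    rec$true_scale_z <- row$right_scale_z
    rec$true_yaw_deg <- row$right_yaw_deg
    rec
  })
  class(rows) <- c("asym_records", class(rows))
  rows
}
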