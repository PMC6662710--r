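#' Tidy an overlap result
#'
#' @param x An `overlap_result` from [overlap_stats()] or
#'   [mirrored_similarity()].
#' @param ... Unused.
#' @return A one-row tibble with the voxel counts, similarity index, and
#'   non-overlapping volume.
#' @method tidy overlap_result
#' @export
tidy.overlap_result <- function(x, ...) {
  tibble::tibble(count_A = x$count_A,
                 count_B = x$count_B,
                 count_intersection = x$count_intersection,
                 count_nonoverlap = x$count_nonoverlap,
                 dice = x$dice,
                 nonoverlap_mm3 = x$nonoverlap_mm3)
}

#' Cohort-level summary of a records table
#'
#' @param x An `asym_records` tibble from [run_cohort()].
#' @param ... Unused.
#' @return One row per reference plane x timepoint with cohort means and
#'   standard deviations of the similarity index and non-overlapping
#'   volume.
#' @method glance asym_records
#' @export
glance.asym_records <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$reference_plane,
                    .data$timepoint),
    n = dplyr::n(),
    dice_mean = mean(.data$dice),
    dice_sd = stats::sd(.data$dice),
    nonoverlap_mm3_mean = mean(.data$nonoverlap_mm3),
    nonoverlap_mm3_sd = stats::sd(.data$nonoverlap_mm3),
    .groups = "drop")
}
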