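#' Paired t test
#'
#' Two-sided paired t test on matched measurement vectors:
#' `t = mean(d) / (sd(d) / sqrt(n))` on the differences `d = x - y`,
#' `df = n - 1`.
#'
#' @param x,y Paired numeric vectors of equal length (n >= 2).
#' @return A one-row tibble: `estimate` (mean difference), `statistic`,
#'   `df`, `p.value`, `conf.low`, `conf.high`, `n`.
#' @export
paired_t <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) == length(y), length(x) >= 2,
            all(is.finite(x)), all(is.finite(y)))
  d <- x - y
  if (stats::sd(d) < .Machine$double.eps * max(1, max(abs(d)))) {
    stop("degenerate variance: paired differences are constant",
         call. = FALSE)
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  tibble::tibble(estimate = unname(ht$estimate),
                 statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p.value = ht$p.value,
                 conf.low = ht$conf.int[1],
                 conf.high = ht$conf.int[2],
                 n = length(x))
}

#' Pearson correlation
#'
#' Product-moment correlation with the two-sided t-based p value.
#'
#' @param x,y Numeric vectors of equal length (n >= 3), each with nonzero
#'   variance.
#' @return A one-row tibble: `estimate` (r), `statistic`, `df`, `p.value`,
#'   `n`.
#' @export
pearson_cor <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate variance: correlation undefined for constant input",
         call. = FALSE)
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(estimate = unname(ht$estimate),
                 statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p.value = ht$p.value,
                 n = length(x))
}

#' Intraclass correlation for two measurement sessions
#'
#' Two-way random-effects, absolute-agreement, single-measure intraclass
#' correlation — ICC(2,1) in the Shrout-Fleiss nomenclature — computed from
#' the two-way mean squares:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`
#' with `n` subjects and `k = 2` sessions. Used to quantify intra- and
#' inter-examiner reliability of repeated landmark-based measurements.
#'
#' @param session1,session2 Numeric vectors of the same measurements from
#'   two sessions (n >= 5 subjects).
#' @return A one-row tibble: `icc`, `msr`, `msc`, `mse`, `n`, `k`.
#' @export
icc_agreement <- function(session1, session2) {
  x <- as.numeric(session1); y <- as.numeric(session2)
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  n <- length(x)
  if (n < 5) {
    stop("icc_agreement() needs at least 5 subjects", call. = FALSE)
  }
  m <- cbind(x, y)
  k <- 2L
  gm <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ssr <- k * sum((row_means - gm)^2)
  ssc <- n * sum((col_means - gm)^2)
  sst <- sum((m - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (abs(denom) < .Machine$double.eps * max(1, abs(msr))) {
    stop("degenerate variance: ICC undefined", call. = FALSE)
  }
  tibble::tibble(icc = (msr - mse) / denom,
                 msr = msr, msc = msc, mse = mse, n = n, k = k)
}

#' Cohort summary tables
#'
#' Reproduces the analysis pattern of a bilateral-asymmetry surgical
#' cohort on a table of per-subject records (one row per subject x
#' timepoint, as produced by [run_cohort()]):
#' \describe{
#'   \item{`bilateral`}{Dev vs N-Dev paired t tests of the hemi volume and
#'     surface per reference plane and timepoint.}
#'   \item{`change`}{T1 vs T2 paired t tests of non-overlapping volume and
#'     similarity index per reference plane (and of the bilateral
#'     differences).}
#'   \item{`correlations`}{Pearson correlations between similarity index
#'     and non-overlapping volume across timepoint combinations, and
#'     between similarity index and the bilateral volume difference.}
#' }
#' Subjects missing one timepoint are dropped with a warning.
#'
#' @param records A records tibble from [run_cohort()] /
#'   [measure_subject()].
#' @param holm Apply a Holm adjustment to each table's p values (off by
#'   default; the source analysis pattern applies none).
#' @return A list of tibbles with class `cohort_tables`.
#' @export
build_cohort_tables <- function(records, holm = FALSE) {
  stopifnot(is.data.frame(records))
  complete <- names(which(table(records$subject) == 2L))
  if (length(complete) < length(unique(records$subject))) {
    warning("dropping subjects without both timepoints", call. = FALSE)
  }
  records <- records[records$subject %in% complete, ]
  planes <- unique(records$reference_plane)

  bilateral <- purrr::map_dfr(planes, function(pl) {
    purrr::map_dfr(c("T1", "T2"), function(tp) {
      r <- records[records$reference_plane == pl & records$timepoint == tp, ]
      purrr::map_dfr(
        c(hemi_volume = "volume", hemi_surface = "surface"),
        .id = "quantity",
        function(q) {
          paired_t(r[[paste0("hemi_", q, "_dev")]],
                   r[[paste0("hemi_", q, "_ndev")]])
        }) |>
        dplyr::mutate(reference_plane = pl, timepoint = tp, .before = 1)
    })
  })

  change <- purrr::map_dfr(planes, function(pl) {
    r1 <- records[records$reference_plane == pl & records$timepoint == "T1", ]
    r2 <- records[records$reference_plane == pl & records$timepoint == "T2", ]
    r1 <- r1[order(r1$subject), ]
    r2 <- r2[order(r2$subject), ]
    purrr::map_dfr(
      c(nonoverlap_mm3 = "nonoverlap_mm3", dice = "dice",
        hemi_volume_difference = "hemi_volume_difference"),
      .id = "quantity",
      function(q) paired_t(r1[[q]], r2[[q]])) |>
      dplyr::mutate(reference_plane = pl, .before = 1)
  })

  correlations <- purrr::map_dfr(planes, function(pl) {
    wide <- records[records$reference_plane == pl, ]
    combos <- expand.grid(dice_tp = c("T1", "T2"), nov_tp = c("T1", "T2"),
                          stringsAsFactors = FALSE)
    purrr::map_dfr(seq_len(nrow(combos)), function(i) {
      a <- wide[wide$timepoint == combos$dice_tp[i], ]
      b <- wide[wide$timepoint == combos$nov_tp[i], ]
      a <- a[order(a$subject), ]
      b <- b[order(b$subject), ]
      dplyr::mutate(pearson_cor(a$dice, b$nonoverlap_mm3),
                    reference_plane = pl,
                    dice_timepoint = combos$dice_tp[i],
                    nov_timepoint = combos$nov_tp[i],
                    pair = "dice_vs_nonoverlap", .before = 1)
    }) |>
      dplyr::bind_rows(
        dplyr::mutate(
          pearson_cor(wide$dice[wide$timepoint == "T1"][
                        order(wide$subject[wide$timepoint == "T1"])],
                      wide$hemi_volume_difference[wide$timepoint == "T1"][
                        order(wide$subject[wide$timepoint == "T1"])]),
          reference_plane = pl, dice_timepoint = "T1", nov_timepoint = "T1",
          pair = "dice_vs_volume_difference", .before = 1))
  })

  if (holm) {
    bilateral$p.value <- stats::p.adjust(bilateral$p.value, "holm")
    change$p.value <- stats::p.adjust(change$p.value, "holm")
    correlations$p.value <- stats::p.adjust(correlations$p.value, "holm")
  }
  structure(list(bilateral = bilateral, change = change,
                 correlations = correlations),
            class = "cohort_tables")
}

#' @export
print.cohort_tables <- function(x, ...) {
  cat("<cohort_tables>\n\n-- Dev vs N-Dev (paired t) --\n")
  print(x$bilateral)
  cat("\n-- T1 vs T2 (paired t) --\n")
  print(x$change)
  cat("\n-- correlations --\n")
  print(x$correlations)
  invisible(x)
}
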