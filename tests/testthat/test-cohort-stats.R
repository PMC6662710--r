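test_that("paired t agrees with the closed-form statistic and t distribution", {
  x <- c(2, 4, 6)
  y <- c(1, 2, 3)           # d = (1, 2, 3)
  res <- paired_t(x, y)
  d <- x - y
  t_hand <- mean(d) / (stats::sd(d) / sqrt(3))
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$statistic, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$p.value, 2 * stats::pt(-abs(t_hand), 2), tolerance = 1e-12)
  expect_equal(res$p.value, 0.0742, tolerance = 1e-3)

  expect_error(paired_t(x, x), "degenerate")

  flipped <- paired_t(y, x)
  expect_equal(flipped$statistic, -res$statistic)
  expect_equal(flipped$p.value, res$p.value)
})

test_that("paired t and Pearson match brute-force formulas on random input", {
  set.seed(12)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    x <- stats::rnorm(n, 10, 3)
    y <- x + stats::rnorm(n, 1, 2)
    d <- x - y
    res <- paired_t(x, y)
    expect_equal(res$statistic, mean(d) / (stats::sd(d) / sqrt(n)),
                 tolerance = 1e-10)
    expect_equal(res$estimate, mean(d), tolerance = 1e-10)

    r_hand <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    pc <- pearson_cor(x, y)
    expect_equal(pc$estimate, r_hand, tolerance = 1e-10)
    t_r <- r_hand * sqrt((n - 2) / (1 - r_hand^2))
    expect_equal(pc$p.value, 2 * stats::pt(-abs(t_r), n - 2),
                 tolerance = 1e-10)
  }
})

test_that("Pearson correlation handles exact linear relations and degeneracy", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_cor(x, 2 * x + 1)$estimate, 1)
  expect_equal(pearson_cor(x, -x)$estimate, -1)
  expect_error(pearson_cor(x, rep(3, 5)), "degenerate")

  # constant total volume: dice and NOV are in exact linear opposition
  set.seed(4)
  total <- 2000
  nov <- sample(0:total, 25)
  dice <- 1 - nov / total
  expect_equal(pearson_cor(dice, nov)$estimate, -1, tolerance = 1e-12)
})

test_that("ICC(2,1) behaves at its anchors and matches aov mean squares", {
  s1 <- c(10, 12, 14, 16, 18, 20)
  expect_equal(icc_agreement(s1, s1)$icc, 1)

  set.seed(9)
  a <- stats::rnorm(50)
  b <- stats::rnorm(50)
  expect_lt(abs(icc_agreement(a, b)$icc), 0.3)

  # permutation invariance: reordering subjects does not change the value
  p <- sample(50)
  expect_equal(icc_agreement(a[p], b[p])$icc, icc_agreement(a, b)$icc)

  # cross-check the mean squares against an independent two-way anova fit
  x <- stats::rnorm(12, 50, 5)
  y <- x + stats::rnorm(12, 0.5, 1)
  res <- icc_agreement(x, y)
  long <- data.frame(value = c(x, y),
                     subject = factor(rep(1:12, 2)),
                     session = factor(rep(1:2, each = 12)))
  ms <- anova(stats::lm(value ~ subject + session, data = long))
  expect_equal(res$msr, ms["subject", "Mean Sq"], tolerance = 1e-10)
  expect_equal(res$msc, ms["session", "Mean Sq"], tolerance = 1e-10)
  expect_equal(res$mse, ms["Residuals", "Mean Sq"], tolerance = 1e-10)
  icc_hand <- (res$msr - res$mse) /
    (res$msr + res$mse + 2 * (res$msc - res$mse) / 12)
  expect_equal(res$icc, icc_hand, tolerance = 1e-12)

  expect_error(icc_agreement(c(1, 2), c(1, 2)), "at least 5")
  # near-perfect repeatability, the regime reported for landmark re-digitization
  noisy <- x + stats::rnorm(12, 0, 0.05)
  expect_gt(icc_agreement(x, noisy)$icc, 0.99)
})

test_that("cohort tables recover the built-in relationships of synthetic records", {
  set.seed(77)
  n <- 12
  total <- 40000                      # constant |A| + |B| across the cohort
  mk_records <- function(tp, nov) {
    tibble::tibble(
      subject = 1:n, timepoint = tp, reference_plane = "MSP",
      dice = 1 - nov / total, nonoverlap_mm3 = nov,
      hemi_volume_dev = 21000 + stats::rnorm(n, 0, 150),
      hemi_volume_ndev = 20000 + stats::rnorm(n, 0, 150),
      hemi_surface_dev = 5200 + stats::rnorm(n, 0, 40),
      hemi_surface_ndev = 5000 + stats::rnorm(n, 0, 40))
  }
  nov1 <- stats::runif(n, 8000, 16000)
  rec <- dplyr::bind_rows(mk_records("T1", nov1), mk_records("T2", 0.6 * nov1))
  rec <- dplyr::mutate(rec,
                       hemi_volume_difference = hemi_volume_dev - hemi_volume_ndev)
  tabs <- build_cohort_tables(rec)

  # Dev > N-Dev volumes -> positive paired-t estimates, small p
  bil <- tabs$bilateral[tabs$bilateral$quantity == "hemi_volume", ]
  expect_true(all(bil$estimate > 0))
  expect_true(all(bil$p.value < 0.05))

  # NOV decreases after surgery, dice increases
  chg <- tabs$change
  expect_gt(chg$estimate[chg$quantity == "nonoverlap_mm3"], 0)
  expect_lt(chg$estimate[chg$quantity == "dice"], 0)
  expect_lt(chg$p.value[chg$quantity == "nonoverlap_mm3"], 0.05)

  # same-timepoint dice-NOV correlation is exactly -1 at constant total
  cor_t1 <- tabs$correlations[
    tabs$correlations$pair == "dice_vs_nonoverlap" &
      tabs$correlations$dice_timepoint == "T1" &
      tabs$correlations$nov_timepoint == "T1", ]
  expect_equal(cor_t1$estimate, -1, tolerance = 1e-10)

  # incomplete subjects are dropped with a warning
  expect_warning(build_cohort_tables(rec[-1, ]), "both timepoints")
})
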