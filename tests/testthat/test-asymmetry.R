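test_that("grid-aligned mirroring is an exact index flip and involution", {
  set.seed(17)
  arr <- random_mask(c(10, 6, 6))
  m <- voxel_mask(arr, origin = c(-4.5, 0, 0))  # x mid-plane at 0
  pl <- plane(c(1, 0, 0), 0)
  mir <- mirror_mask(m, pl)
  expect_equal(mir$data, arr[10:1, , ])
  expect_equal(mirror_mask(mir, pl)$data, arr)
})

test_that("oblique-plane mirroring approximately preserves volume", {
  # sphere of radius 12 voxels in a 40^3 grid, oblique mirror through center
  d <- c(40, 40, 40)
  cc <- seq_len(40) - 20.5
  X <- array(cc, d)
  Y <- array(rep(cc, each = 40), d)
  Z <- array(rep(cc, each = 1600), d)
  sph <- voxel_mask(X^2 + Y^2 + Z^2 <= 12^2, origin = c(-19.5, -19.5, -19.5))
  pl <- plane(c(1, 1, 0.3), 0)
  mir <- mirror_mask(sph, pl)
  dv <- abs(sum(mir$data) - sum(sph$data)) / sum(sph$data)
  expect_lt(dv, 0.02)
  # linear interpolation stays close to nearest neighbor on smooth shapes
  mir_lin <- mirror_mask(sph, pl, interpolation = "linear")
  dv2 <- abs(sum(mir_lin$data) - sum(sph$data)) / sum(sph$data)
  expect_lt(dv2, 0.02)
})

test_that("overlap statistics satisfy the Dice contract on known configurations", {
  base <- array(FALSE, c(12, 12, 12))
  a <- base; a[1:10, 1:10, 1:10] <- TRUE          # 1000 voxels
  A <- voxel_mask(a, spacing = 0.5)
  same <- overlap_stats(A, A)
  expect_equal(same$dice, 1)
  expect_equal(same$count_nonoverlap, 0)

  b <- base; b[1:10, 1:10, 11:12] <- TRUE
  B <- voxel_mask(b, spacing = 0.5)
  disj <- overlap_stats(A, B)
  expect_equal(disj$dice, 0)
  expect_equal(disj$count_nonoverlap, disj$count_A + disj$count_B)

  nested <- base; nested[1:10, 1:10, 1:8] <- TRUE  # 800 inside A
  N <- voxel_mask(nested, spacing = 0.5)
  r <- overlap_stats(A, N)
  expect_equal(r$count_intersection, 800)
  expect_equal(r$dice, 1600 / 1800)
  expect_equal(r$count_nonoverlap, 200)
  expect_equal(r$nonoverlap_mm3, 200 * 0.5^3)

  expect_error(overlap_stats(A, voxel_mask(b, spacing = 0.7)), "same grid")
  empty <- voxel_mask(base)
  expect_error(overlap_stats(empty, empty), "empty")
})

test_that("overlap statistics agree with brute-force per-voxel counts", {
  set.seed(23)
  for (i in 1:25) {
    a <- random_mask(c(16, 16, 16), p = stats::runif(1, 0.1, 0.7))
    b <- random_mask(c(16, 16, 16), p = stats::runif(1, 0.1, 0.7))
    if (!any(a) && !any(b)) next
    got <- overlap_stats(voxel_mask(a), voxel_mask(b))
    want <- brute_overlap_counts(a, b)
    expect_equal(got$count_A, want$count_A)
    expect_equal(got$count_B, want$count_B)
    expect_equal(got$count_intersection, want$count_intersection)
    expect_equal(got$count_nonoverlap, want$count_nonoverlap)
    # Dice-NOV identity (up to one ulp between the two expressions)
    expect_equal(got$dice,
                 1 - got$count_nonoverlap / (got$count_A + got$count_B),
                 tolerance = 1e-15)
    # symmetry of the index
    expect_identical(overlap_stats(voxel_mask(b), voxel_mask(a))$dice,
                     got$dice)
  }
})

test_that("mirrored similarity matches closed forms on box-pair phantoms", {
  sym <- make_box_pair(c(10, 10, 10), c(10, 10, 10))
  expect_equal(mirrored_similarity(sym$whole, sym$plane)$dice, 1)

  shrunk <- make_box_pair(c(10, 10, 10), c(10, 10, 8))
  res <- mirrored_similarity(shrunk$whole, shrunk$plane)
  expect_equal(res$dice, 1600 / 1800)
  expect_equal(res$dice, shrunk$dice_expected)

  apart <- make_box_pair(c(6, 6, 6), c(6, 6, 6), right_offset_vox = c(0, 8, 0))
  expect_equal(mirrored_similarity(apart$whole, apart$plane)$dice, 0)
  expect_equal(apart$dice_expected, 0)

  arr1 <- array(FALSE, c(2, 6, 2))
  arr1[, 4:5, ] <- TRUE              # entirely on the positive side
  one_sided <- voxel_mask(arr1, origin = c(0, 0, 0))
  expect_warning(r0 <- mirrored_similarity(one_sided, plane(c(0, 1, 0), 2.5)),
                 "empty")
  expect_equal(r0$dice, 0)
})

test_that("dice decreases monotonically as the right box shrinks", {
  dices <- vapply(10:4, function(k) {
    bp <- make_box_pair(c(10, 10, 10), c(10, 10, k))
    mirrored_similarity(bp$whole, bp$plane)$dice
  }, numeric(1))
  expect_true(all(diff(dices) < 0))
  expect_equal(dices, 2 * 100 * (10:4) / (1000 + 100 * (10:4)))
})

test_that("hemi and whole-structure mirroring give the same index on clean splits", {
  set.seed(41)
  for (i in 1:10) {
    bp <- make_box_pair(sample(4:10, 3, TRUE), sample(4:10, 3, TRUE),
                        right_offset_vox = c(0, sample(0:2, 1), 0))
    whole <- bp$whole
    hemi <- mirrored_similarity(whole, bp$plane)$dice
    mir_whole <- mirror_mask(whole, bp$plane)
    whole_dice <- overlap_stats(mir_whole, whole)$dice
    expect_equal(hemi, whole_dice, tolerance = 1e-9)
  }
})

test_that("segment distribution splits the non-overlap volume by the sectioning plane", {
  arr <- array(FALSE, c(10, 4, 4))
  arr[1:10, 2, 2] <- TRUE   # 10 voxels along x
  nov <- voxel_mask(arr, spacing = 2, origin = c(0, 0, 0))
  # positive (ramus) side: x >= 7 -> 4 voxels at x = 12, 14, 16, 18
  sec <- plane(c(1, 0, 0), 11)
  seg <- segment_distribution(nov, sec)
  expect_equal(seg$ramus_fraction, 40)
  expect_equal(seg$body_fraction, 60)
  expect_equal(seg$ramus_mm3, 4 * 8)
  expect_equal(seg$body_mm3, 6 * 8)

  all_body <- segment_distribution(nov, plane(c(1, 0, 0), 100))
  expect_equal(all_body$ramus_fraction, 0)
  expect_equal(all_body$body_fraction, 100)

  expect_warning(z <- segment_distribution(
    voxel_mask(array(FALSE, c(3, 3, 3))), sec), "empty")
  expect_equal(z$ramus_fraction + z$body_fraction, 0)

  set.seed(6)
  for (i in 1:10) {
    m <- voxel_mask(random_mask(c(8, 8, 8)))
    if (!any(m$data)) next
    s <- segment_distribution(m, plane(stats::rnorm(3), stats::runif(1, -2, 2)))
    expect_equal(s$ramus_fraction + s$body_fraction, 100)
  }
})

test_that("menton deviation fixes the Dev side and the inclusion flag", {
  msp <- plane(c(1, 0, 0), 0)
  mk <- function(x) landmark_set(list(Me = c(x, 10, -5)))
  d1 <- assess_deviation(mk(5), msp)
  expect_equal(d1$deviation_mm, 5)
  expect_equal(d1$dev_side, "left")
  expect_true(d1$included)

  d2 <- assess_deviation(mk(-4), msp)
  expect_equal(d2$deviation_mm, 4)
  expect_equal(d2$dev_side, "right")
  expect_false(d2$included)   # strictly greater than 4 mm required

  d3 <- assess_deviation(mk(0), msp)
  expect_equal(d3$dev_side, "midline")
  expect_false(d3$included)

  expect_error(assess_deviation(landmark_set(list(N = c(0, 0, 0))), msp),
               "Me")
})
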