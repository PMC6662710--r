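test_that("voxel containers validate geometry and values", {
  arr <- array(0, c(2, 2, 2))
  expect_error(voxel_mask(array(2, c(2, 2, 2))), "0/1")
  expect_error(voxel_mask(arr, spacing = c(1, 1, 2)), "anisotropic")
  expect_error(voxel_mask(matrix(0, 2, 2)), "3D")
  expect_error(hu_volume(array(NA_real_, c(2, 2, 2))), "finite")
  m <- voxel_mask(array(c(1, 0, 0, 1, 1, 0, 0, 1), c(2, 2, 2)),
                  spacing = c(0.39, 0.39, 0.39))
  expect_equal(m$spacing, 0.39)
})

test_that("binarization applies the closed HU band", {
  expect_error(hu_band(520, 320), "invalid HU band")
  vol <- hu_volume(array(c(-1000, 400, 520, 600), c(2, 2, 1)))
  m <- binarize(vol, hu_band_bone())
  expect_equal(as.numeric(m$data), c(0, 1, 1, 0))
  expect_equal(m$spacing, vol$spacing)

  soft <- hu_volume(array(-400, c(3, 3, 3)))
  expect_true(all(binarize(soft, hu_band_soft_tissue())$data))

  expect_warning(binarize(soft, hu_band_bone()), "empty")
})

test_that("hole filling closes enclosed cavities and nothing else", {
  shell <- array(TRUE, c(5, 5, 5))
  shell[2:4, 2:4, 2:4] <- FALSE
  filled <- fill_holes(voxel_mask(shell))
  expect_true(all(filled$data))

  # idempotence and extensivity
  expect_equal(fill_holes(filled)$data, filled$data)
  expect_true(all(filled$data | !shell))

  # a channel open to the boundary must not be filled
  open_box <- array(TRUE, c(5, 5, 5))
  open_box[3, 3, ] <- FALSE          # tunnel through the whole grid
  expect_equal(fill_holes(voxel_mask(open_box))$data, open_box)
})

test_that("spherical closing fills notches and matches the brute-force oracle", {
  slab <- array(FALSE, c(9, 7, 7))
  slab[2:8, 2:6, 2:6] <- TRUE
  slab[5, 2:6, 2:4] <- FALSE   # one-voxel-wide slit, 3 deep, opening downward
  closed <- morph_close(voxel_mask(slab), 2)
  # the ball cannot reach deeper than its radius into the slit, so the deep
  # cells close while the mouth stays open
  expect_true(closed$data[5, 4, 4])
  expect_true(closed$data[5, 4, 3])
  expect_false(closed$data[5, 4, 2])
  expect_equal(closed$data, brute_close(slab, 2))

  expect_error(morph_close(voxel_mask(slab), 0), "radius")

  empty <- voxel_mask(array(FALSE, c(6, 6, 6)))
  expect_equal(sum(morph_close(empty, 3)$data), 0)

  set.seed(42)
  for (i in 1:12) {
    d <- sample(5:8, 3, replace = TRUE)
    arr <- random_mask(d, p = stats::runif(1, 0.15, 0.5))
    r <- sample(1:2, 1)
    got <- morph_close(voxel_mask(arr), r)$data
    expect_equal(got, brute_close(arr, r))
    # extensive and idempotent
    expect_true(all(got | !arr))
    expect_equal(morph_close(voxel_mask(got), r)$data, got)
  }
})

test_that("hole filling and closing are extensive and idempotent on random masks", {
  set.seed(99)
  for (i in 1:100) {
    arr <- random_mask(c(20, 20, 20), p = stats::runif(1, 0.2, 0.6))
    f <- fill_holes(voxel_mask(arr))
    expect_true(all(f$data | !arr))
    expect_equal(fill_holes(f)$data, f$data)
  }
})

test_that("volume is voxel count times the cube of the spacing", {
  arr <- array(FALSE, c(10, 10, 10))
  arr[1:10, 1:10, 1:10][seq_len(1000)] <- TRUE
  expect_equal(volume_mm3(voxel_mask(arr, spacing = 0.39)), 1000 * 0.39^3)
  expect_equal(volume_mm3(voxel_mask(arr, spacing = 0.39)), 59.319)
  expect_equal(volume_mm3(voxel_mask(array(FALSE, c(3, 3, 3)))), 0)
  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  expect_equal(volume_mm3(voxel_mask(one)), 1)
})

test_that("face-count surface area matches hand counts and the box formula", {
  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  expect_equal(surface_area_mm2(voxel_mask(one)), 6)
  expect_equal(surface_area_mm2(voxel_mask(one, spacing = 0.39)), 6 * 0.39^2)
  expect_equal(surface_area_mm2(voxel_mask(one, spacing = 0.39)), 0.9126)

  bar <- array(FALSE, c(4, 3, 3)); bar[2:3, 2, 2] <- TRUE
  expect_equal(surface_area_mm2(voxel_mask(bar)), 10)

  set.seed(8)
  for (i in 1:20) {
    ab <- sample(1:6, 3, replace = TRUE)
    arr <- array(FALSE, ab + 2L)
    arr[1 + seq_len(ab[1]), 1 + seq_len(ab[2]), 1 + seq_len(ab[3])] <- TRUE
    s <- stats::runif(1, 0.2, 2)
    expect_equal(surface_area_mm2(voxel_mask(arr, spacing = s)),
                 2 * (ab[1] * ab[2] + ab[2] * ab[3] + ab[3] * ab[1]) * s^2)
  }
})

test_that("face-count surface area agrees with the per-voxel oracle", {
  set.seed(13)
  for (i in 1:10) {
    arr <- random_mask(c(16, 16, 16), p = stats::runif(1, 0.2, 0.6))
    s <- stats::runif(1, 0.3, 1.5)
    expect_equal(surface_area_mm2(voxel_mask(arr, spacing = s)),
                 brute_face_count(arr) * s^2)
  }
})

test_that("slice-perimeter surface mode sums in-plane boundary edges", {
  # a x b x c box: per axial slice the perimeter is 2(a+b) voxel edges
  arr <- array(FALSE, c(7, 8, 6))
  arr[2:5, 2:7, 2:4] <- TRUE   # 4 x 6 x 3 box
  expect_equal(surface_area_mm2(voxel_mask(arr), mode = "slice_perimeter"),
               2 * (4 + 6) * 3)
  expect_error(surface_area_mm2(voxel_mask(arr), mode = "nope"))
})

test_that("cut-plane faces can be excluded from the surface area", {
  arr <- array(FALSE, c(8, 6, 6))
  arr[3:6, 2:5, 2:5] <- TRUE   # 4 x 4 x 4 cube
  m <- voxel_mask(arr, origin = c(-3.5, 0, 0))  # cube spans x in [-1.5, 1.5]
  cut <- plane(c(1, 0, 0), 0)
  halves <- split_by_plane(m, cut)
  # each half is 2 x 4 x 4: closed surface 64, minus the 16-face cut = 48
  expect_equal(surface_area_mm2(halves$positive), 64)
  expect_equal(surface_area_mm2(halves$positive, exclude = cut), 48)
  expect_equal(surface_area_mm2(halves$negative, exclude = cut), 48)
})

test_that("plane splitting partitions the mask with a deterministic tie-break", {
  cube <- voxel_mask(array(TRUE, c(2, 2, 2)), origin = c(-0.5, -0.5, -0.5))
  halves <- split_by_plane(cube, plane(c(1, 0, 0), 0))
  expect_equal(sum(halves$positive$data), 4)
  expect_equal(sum(halves$negative$data), 4)

  shifted <- voxel_mask(array(TRUE, c(2, 2, 2)), origin = c(5, 0, 0))
  h2 <- split_by_plane(shifted, plane(c(1, 0, 0), 0))
  expect_equal(sum(h2$positive$data), 8)
  expect_equal(sum(h2$negative$data), 0)

  # voxels exactly on the plane go to the positive side
  onplane <- voxel_mask(array(TRUE, c(3, 1, 1)), origin = c(-1, 0, 0))
  h3 <- split_by_plane(onplane, plane(c(1, 0, 0), 0))
  expect_equal(sum(h3$positive$data), 2)

  set.seed(31)
  for (i in 1:20) {
    m <- voxel_mask(random_mask(c(12, 12, 12)), spacing = 0.7,
                    origin = stats::runif(3, -5, 0))
    pl <- plane(stats::rnorm(3), stats::runif(1, -3, 3))
    h <- split_by_plane(m, pl)
    expect_equal(h$positive$data | h$negative$data, m$data)
    expect_false(any(h$positive$data & h$negative$data))
    expect_equal(volume_mm3(h$positive) + volume_mm3(h$negative),
                 volume_mm3(m))
  }
})

test_that("cropping below a plane removes the superior part only", {
  cube <- voxel_mask(array(TRUE, c(4, 4, 4)), origin = c(0, 0, -1.5))
  fhp <- plane(c(0, 0, 1), 0)
  kept <- crop_below_plane(cube, fhp)
  expect_equal(sum(kept$data), 32)
  expect_true(all(which(kept$data, arr.ind = TRUE)[, 3] <= 2))

  below <- voxel_mask(array(TRUE, c(3, 3, 3)), origin = c(0, 0, -10))
  expect_equal(crop_below_plane(below, fhp)$data, below$data)

  above <- voxel_mask(array(TRUE, c(3, 3, 3)), origin = c(0, 0, 10))
  expect_equal(sum(crop_below_plane(above, fhp)$data), 0)
})
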