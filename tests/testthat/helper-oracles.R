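# Independent brute-force oracles used to validate the voxel operations.
# All of them work by explicit set arithmetic over voxel index tuples, with
# none of the package's distance-transform machinery.

vcrossprod <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

ball_offsets <- function(radius) {
  g <- expand.grid(dx = -radius:radius, dy = -radius:radius,
                   dz = -radius:radius)
  g[g$dx^2 + g$dy^2 + g$dz^2 <= radius^2, , drop = FALSE]
}

shift_within <- function(idx, off, d) {
  out <- cbind(idx[, 1] + off[1], idx[, 2] + off[2], idx[, 3] + off[3])
  keep <- out[, 1] >= 1 & out[, 1] <= d[1] &
    out[, 2] >= 1 & out[, 2] <= d[2] &
    out[, 3] >= 1 & out[, 3] <= d[3]
  out[keep, , drop = FALSE]
}

brute_dilate <- function(arr, radius) {
  d <- dim(arr)
  idx <- which(arr, arr.ind = TRUE)
  out <- array(FALSE, d)
  offs <- ball_offsets(radius)
  for (r in seq_len(nrow(offs))) {
    out[shift_within(idx, as.numeric(offs[r, ]), d)] <- TRUE
  }
  out
}

brute_erode <- function(arr, radius) {
  # outside the grid counts as background
  d <- dim(arr)
  out <- array(FALSE, d)
  offs <- as.matrix(ball_offsets(radius))
  idx <- which(arr | TRUE, arr.ind = TRUE)  # every voxel
  for (r in seq_len(nrow(idx))) {
    p <- idx[r, ]
    q <- cbind(p[1] + offs[, 1], p[2] + offs[, 2], p[3] + offs[, 3])
    inside <- q[, 1] >= 1 & q[, 1] <= d[1] &
      q[, 2] >= 1 & q[, 2] <= d[2] & q[, 3] >= 1 & q[, 3] <= d[3]
    out[p[1], p[2], p[3]] <- all(inside) && all(arr[q])
  }
  out
}

# closing over an unbounded background: embed in a generously padded grid
brute_close <- function(arr, radius) {
  d <- dim(arr)
  p <- 2L * radius + 1L
  padded <- array(FALSE, d + 2L * p)
  padded[p + seq_len(d[1]), p + seq_len(d[2]), p + seq_len(d[3])] <- arr
  closed <- brute_erode(brute_dilate(padded, radius), radius)
  closed[p + seq_len(d[1]), p + seq_len(d[2]), p + seq_len(d[3])]
}

brute_overlap_counts <- function(a, b) {
  list(count_A = sum(a), count_B = sum(b),
       count_intersection = sum(a & b),
       count_nonoverlap = sum(xor(a, b)))
}

# exposed-face count by looping over foreground voxels and their 6 neighbors
brute_face_count <- function(arr) {
  d <- dim(arr)
  idx <- which(arr, arr.ind = TRUE)
  total <- 0L
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (r in seq_len(nrow(idx))) {
    p <- idx[r, ]
    for (s in seq_len(6)) {
      q <- p + offs[s, ]
      outside <- any(q < 1) || q[1] > d[1] || q[2] > d[2] || q[3] > d[3]
      if (outside || !arr[q[1], q[2], q[3]]) total <- total + 1L
    }
  }
  total
}

random_mask <- function(d, p = 0.4) {
  array(stats::runif(prod(d)) < p, dim = d)
}

# small phantom spec used throughout the tests to keep runtimes short
test_spec <- function(...) {
  args <- utils::modifyList(
    list(shape = c(72, 46, 48), origin = c(-35.5, -14, -10),
         arc_radius = 20, body_width = 7, body_height = 9,
         ramus_width = 7, ramus_depth = 9, ramus_height = 22,
         condyle_radius = 4, shell_mm = 2),
    list(...))
  do.call(phantom_spec, args)
}

test_config <- function(...) {
  run_config(closing_radius = 3, ...)
}
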