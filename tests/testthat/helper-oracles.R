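# Independent brute-force oracles used across the suite.

# Per-point voxel binning: returns the set of occupied voxel keys as
# "i/j/k" strings, looping over points one at a time.
brute_voxel_keys <- function(points, voxel_size) {
  origin <- c(min(points[, 1]), min(points[, 2]), min(points[, 3]))
  keys <- character(nrow(points))
  for (r in seq_len(nrow(points))) {
    idx <- floor((points[r, ] - origin) / voxel_size)
    keys[r] <- paste(idx, collapse = "/")
  }
  sort(unique(keys))
}

grid_keys <- function(grid) {
  sort(apply(grid$voxels, 1, paste, collapse = "/"))
}

# Direct shoelace area and edge-sum perimeter of the polygon formed by the
# scanner position (0, 0) followed by the given (d, z) vertices in order.
brute_polygon_metrics <- function(verts) {
  v <- rbind(c(0, 0), verts)
  n <- nrow(v)
  area2 <- 0
  per <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    area2 <- area2 + v[i, 1] * v[j, 2] - v[j, 1] * v[i, 2]
    per <- per + sqrt(sum((v[i, ] - v[j, ])^2))
  }
  list(area = unname(abs(area2) / 2), perimeter = unname(per))
}

# Direct inverse Simpson from a vector of per-layer counts.
brute_inverse_simpson <- function(counts) {
  p <- counts / sum(counts)
  1 / sum(p^2)
}

# Cloud with prescribed filled-voxel counts per 25 cm layer (5 cm voxels):
# one point per desired voxel, placed at distinct x positions.
layered_cloud <- function(counts_per_layer, voxel_size = 0.05,
                          slice = 0.25) {
  pts <- NULL
  for (l in seq_along(counts_per_layer)) {
    n <- counts_per_layer[l]
    if (n == 0) next
    z <- (l - 1) * slice + voxel_size / 2
    pts <- rbind(pts, cbind(x = (seq_len(n) - 0.5) * voxel_size,
                            y = 0.025, z = z))
  }
  point_cloud(pts, scanner_origin = c(0, 0, 1.3))
}

# Reduced-size config used for whole-pipeline simulations in tests.
test_config <- function(seed, ...) {
  run_config(seed = seed, n_sections = 360L, points_per_tree = 40L,
             ground_points = 500L, ...)
}
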