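test_that("XYZ and PLY files round-trip point coordinates", {
  set.seed(1)
  cl <- point_cloud(matrix(runif(3000, -5, 15), ncol = 3))
  xyz <- withr::local_tempfile(fileext = ".xyz")
  write_cloud(cl, xyz)
  back <- read_cloud(xyz)
  expect_lt(max(abs(back$points - cl$points)), 1e-6)

  ply <- withr::local_tempfile(fileext = ".ply")
  write_cloud(cl, ply)                       # binary double: exact
  expect_identical(read_cloud(ply)$points, cl$points)
  write_cloud(cl, ply, binary = FALSE)       # ascii body
  expect_lt(max(abs(read_cloud(ply)$points - cl$points)), 1e-9)
})

test_that("XYZ parsing reports malformed lines and tolerates comments", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("# header", "1 2 3", "", "4 5 6"), f)
  expect_equal(nrow(read_cloud(f)$points), 2L)
  writeLines(c("1 2 3", "4 5"), f)
  expect_error(read_cloud(f), "line 2")
  writeLines(c("1 2 3", "4 five 6"), f)
  expect_error(read_cloud(f), "line 2")
  writeLines(character(0), f)
  expect_warning(empty <- read_cloud(f), "empty")
  expect_equal(nrow(empty$points), 0L)
})

test_that("clipping uses closed-left/open-right bounds", {
  pts <- rbind(c(0, 0, 1),       # on min corner: kept
               c(5, 5, 1),       # inside
               c(11, 5, 1),      # on max-x edge: excluded
               c(5, 11, 1),      # on max-y edge: excluded
               c(-1, 5, 1))      # outside
  cl <- clip_to_plot(point_cloud(pts), c(0, 11, 0, 11))
  expect_equal(nrow(cl$points), 2L)

  set.seed(2)
  rnd <- matrix(runif(300, -2, 13), ncol = 3)
  inside <- rnd[, 1] >= 0 & rnd[, 1] < 11 & rnd[, 2] >= 0 & rnd[, 2] < 11
  expect_equal(nrow(clip_to_plot(point_cloud(rnd), c(0, 11, 0, 11))$points),
               sum(inside))
  # all inside -> identity
  cube <- matrix(runif(300, 2, 8), ncol = 3)
  expect_equal(clip_to_plot(point_cloud(cube), c(0, 11, 0, 11))$points,
               point_cloud(cube)$points)
})

test_that("soil removal strips the bottom layer measured from z_min", {
  # synthetic ground at z in [0, 0.05], canopy above 0.2
  set.seed(3)
  ground <- cbind(runif(200, 0, 11), runif(200, 0, 11), runif(200, 0, 0.05))
  canopy <- cbind(runif(300, 0, 11), runif(300, 0, 11), runif(300, 0.2, 6))
  cl <- point_cloud(rbind(ground, canopy))
  clean <- remove_soil_layer(cl, 0.10)
  expect_equal(nrow(clean$points), 300L)
  expect_true(all(clean$points[, 3] > 0.1))

  # soil_height = 0 removes exactly the minimum-height points
  flat <- point_cloud(cbind(1:5, 1:5, c(0, 0, 1, 2, 3)))
  expect_equal(nrow(remove_soil_layer(flat, 0)$points), 3L)
  # all points at one height -> empty result with a warning
  plane <- point_cloud(cbind(1:5, 1:5, rep(2, 5)))
  expect_warning(out <- remove_soil_layer(plane, 0.1), "empty")
  expect_equal(nrow(out$points), 0L)
})

test_that("voxel occupancy equals the per-point binning oracle", {
  g1 <- voxelize(point_cloud(matrix(c(1, 2, 3), 1)), 0.05)
  expect_equal(g1$n_filled, 1L)
  # two points 1 cm apart share a 5 cm voxel
  g2 <- voxelize(point_cloud(rbind(c(0.50, 0.5, 0.5), c(0.51, 0.5, 0.5))),
                 0.05)
  expect_equal(g2$n_filled, 1L)

  set.seed(4)
  pts <- matrix(runif(3e4), ncol = 3)            # 1e4 points in a 1 m^3 box
  g <- voxelize(point_cloud(pts), 0.05)
  expect_identical(grid_keys(g), brute_voxel_keys(pts, 0.05))
  expect_equal(g$fill_ratio, g$n_filled / prod(g$dims))

  # occupancy idempotent under point duplication
  gd <- voxelize(point_cloud(rbind(pts, pts)), 0.05)
  expect_identical(grid_keys(gd), grid_keys(g))
  expect_error(voxelize(point_cloud(matrix(numeric(0), 0, 3))), "empty")
  expect_error(voxelize(point_cloud(pts), 0), "> 0")
})

test_that("clip -> soil removal -> voxelize never gains points", {
  set.seed(5)
  pts <- matrix(runif(3000, -1, 12), ncol = 3)
  cl <- point_cloud(pts)
  clipped <- clip_to_plot(cl, c(0, 11, 0, 11))
  cleaned <- remove_soil_layer(clipped, 0.10)
  grid <- voxelize(cleaned, 0.05)
  expect_lte(nrow(clipped$points), nrow(cl$points))
  expect_lte(nrow(cleaned$points), nrow(clipped$points))
  expect_lte(grid$n_filled, nrow(cleaned$points))
  expect_lte(grid$n_filled, grid$n_total)
})
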