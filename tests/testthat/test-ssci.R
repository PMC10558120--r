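test_that("ENL reproduces the inverse Simpson index on hand-built grids", {
  # all filled voxels in one 25 cm layer
  one <- effective_number_of_layers(voxelize(layered_cloud(5)))
  expect_equal(one$ENL, 1)
  # equal split over four layers
  four <- effective_number_of_layers(voxelize(layered_cloud(c(3, 3, 3, 3))))
  expect_equal(four$ENL, 4)
  # p = (0.5, 0.25, 0.25) -> 1 / 0.375
  skew <- effective_number_of_layers(voxelize(layered_cloud(c(2, 1, 1))))
  expect_equal(skew$ENL, brute_inverse_simpson(c(2, 1, 1)))
  expect_equal(skew$ENL, 2.666667, tolerance = 1e-6)
  expect_equal(sum(skew$layer_profile$p), 1)

  # profile proportions always sum to 1; ENL bounded by nonempty layers
  set.seed(6)
  cl <- point_cloud(matrix(runif(900, 0, 3), ncol = 3))
  enl <- effective_number_of_layers(voxelize(cl))
  expect_equal(sum(enl$layer_profile$p), 1)
  expect_gte(enl$ENL, 1)
  expect_lte(enl$ENL, sum(enl$layer_profile$n_filled > 0))
})

test_that("ENL is invariant to point duplication", {
  set.seed(7)
  pts <- matrix(runif(600, 0, 4), ncol = 3)
  e1 <- effective_number_of_layers(voxelize(point_cloud(pts)))$ENL
  e2 <- effective_number_of_layers(voxelize(point_cloud(rbind(pts, pts))))$ENL
  expect_identical(e1, e2)
})

test_that("cross sections honour the sector count and flag degeneracy", {
  set.seed(8)
  pts <- cbind(runif(400, 0, 11), runif(400, 0, 11), runif(400, 0.2, 6))
  cl <- point_cloud(pts, scanner_origin = c(5.5, 5.5, 1.3))
  cs <- build_cross_sections(cl)            # default 4500 sectors
  expect_equal(nrow(cs), 4500L)
  expect_equal(sum(cs$n_points), 400L)

  # all points in a single sector
  narrow <- point_cloud(cbind(6:9, 5.5, 2), scanner_origin = c(5.5, 5.5, 1.3))
  cs2 <- build_cross_sections(narrow, n_sections = 8)
  expect_equal(sum(cs2$valid), 1L)
  expect_equal(sum(!cs2$valid), 7L)
})

test_that("section polygons match the brute-force shoelace oracle", {
  set.seed(9)
  pts <- cbind(runif(300, 0, 11), runif(300, 0, 11), runif(300, 0, 7))
  cl <- point_cloud(pts, scanner_origin = c(5.5, 5.5, 1.3))
  cs <- build_cross_sections(cl, n_sections = 24, vertices = TRUE)
  for (i in which(cs$valid)) {
    oracle <- brute_polygon_metrics(cs$vertices[[i]])
    expect_equal(cs$area[i], oracle$area, tolerance = 1e-12)
    expect_equal(cs$perimeter[i], oracle$perimeter, tolerance = 1e-12)
  }

  # constructed section with known vertices along one azimuth: the section
  # metrics must equal the oracle applied to the elevation-sorted vertices
  sq <- cbind(d = c(3, 5, 5, 3), z = c(1, 1, 3, 3))
  oracle <- brute_polygon_metrics(sq[order(atan2(sq[, 2], sq[, 1])), ])
  xyz <- cbind(sq[, "d"], 0, sq[, "z"])      # along the +x azimuth
  cl2 <- point_cloud(xyz, scanner_origin = c(0, 0, 0))
  cs2 <- build_cross_sections(cl2, n_sections = 4)
  i <- which(cs2$valid)
  expect_equal(length(i), 1L)
  expect_equal(cs2$area[i], oracle$area)
  expect_equal(cs2$perimeter[i], oracle$perimeter)
})

test_that("fractal dimension is 1 for squares and clamps at 2", {
  expect_equal(fractal_dimension(8, 4), 1)      # side 2
  expect_equal(fractal_dimension(12, 9), 1)     # side 3: scale-free
  expect_equal(fractal_dimension(40, 4), 2)     # star-like: 3.32 clamped
  expect_true(is.na(fractal_dimension(4, 1)))   # A ~ 1 m^2 log-degenerate
  expect_true(is.na(fractal_dimension(0, 4)))
  expect_true(is.na(fractal_dimension(8, 0)))
  f <- fractal_dimension(c(8, 40), c(4, 4))
  expect_equal(f, c(1, 2))
})

test_that("SSCI combines its components exactly and hits the known limits", {
  # single-layer cloud: ENL = 1 so SSCI = 1 whatever MeanFrac is
  set.seed(10)
  slab <- point_cloud(cbind(runif(500, 0, 11), runif(500, 0, 11),
                            runif(500, 2, 2.2)),
                      scanner_origin = c(5.5, 5.5, 1.3))
  s <- compute_ssci(slab, n_sections = 90, soil_height = NULL)
  expect_equal(s$ENL, 1)
  expect_equal(s$SSCI, 1)

  # the identity SSCI = MeanFrac^ln(ENL) holds to machine precision
  trees <- layout_plot(c("AM1", "EM5"), seed = 2)
  census <- simulate_growth(trees, species_pool(), seed = 3)
  cloud <- simulate_scan(census, species_pool(),
                         scan_params(points_per_tree = 30,
                                     ground_points = 200), seed = 4)
  s2 <- compute_ssci(cloud, n_sections = 360)
  expect_identical(s2$SSCI, s2$MeanFrac^log(s2$ENL))
  expect_true(s2$MeanFrac >= 1 && s2$MeanFrac <= 2)

  # MeanFrac = 1 and ENL = e give SSCI = MeanFrac and 1 respectively
  expect_equal(1^log(7.3), 1)
  expect_equal(1.5^log(exp(1)), 1.5)
  expect_error(compute_ssci(point_cloud(matrix(numeric(0), 0, 3))), "empty")
})

test_that("SSCI increases with ENL when MeanFrac exceeds 1", {
  enl_grid <- seq(1, 30, by = 0.5)
  ssci <- 1.4^log(enl_grid)
  expect_true(all(diff(ssci) > 0))
  flat <- 1^log(enl_grid)
  expect_true(all(flat == 1))
})

test_that("two-layer stands have higher ENL than one-layer stands", {
  set.seed(11)
  n <- 600
  xy <- cbind(runif(n, 0, 11), runif(n, 0, 11))
  single <- point_cloud(cbind(xy, runif(n, 2, 3)),
                        scanner_origin = c(5.5, 5.5, 1.3))
  double <- point_cloud(cbind(xy, c(runif(n / 2, 1, 2), runif(n / 2, 5, 6))),
                        scanner_origin = c(5.5, 5.5, 1.3))
  e1 <- effective_number_of_layers(voxelize(single))$ENL
  e2 <- effective_number_of_layers(voxelize(double))$ENL
  expect_gt(e2, e1)
})
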