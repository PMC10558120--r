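test_that("generated designs reproduce the experimental combinatorics", {
  pool <- species_pool()
  am <- pool$species_id[pool$mycorrhizal_type == "AM"]
  em <- pool$species_id[pool$mycorrhizal_type == "EM"]
  for (seed in c(1, 7, 42)) {
    d <- generate_design(pool, seed = seed)
    p <- d$plots
    expect_equal(nrow(p), 80L)
    expect_equal(as.vector(table(p$richness)), c(20L, 30L, 30L))
    expect_equal(as.integer(table(p$mycorrhizal_assoc)[c("AM", "EM", "AM+EM")]),
                 c(30L, 30L, 20L))
    expect_equal(as.vector(table(p$block)), c(40L, 40L))

    mono <- p[p$richness == 1L, ]
    expect_equal(sort(unique(mono$composition)), sort(pool$species_id))
    expect_true(all(table(mono$composition) == 2L))
    expect_equal(sort(unique(mono$block[mono$composition == am[1]])), 1:2)

    two <- p[p$richness == 2L, ]
    expect_false(anyDuplicated(two$composition) > 0)
    within_am <- apply(combn(sort(am), 2), 2, paste, collapse = "+")
    expect_true(all(within_am %in% two$composition))

    four <- p[p$richness == 4L, ]
    am4 <- four$composition[four$mycorrhizal_assoc == "AM"]
    expect_equal(length(unique(am4)), 5L)      # all 4-subsets of 5 species
    expect_true(all(table(am4) == 2L))         # each twice, split by block
    mixed4 <- four$composition[four$mycorrhizal_assoc == "AM+EM"]
    expect_equal(length(unique(mixed4)), 10L)
    for (comp in composition_species(mixed4)) {
      expect_equal(sum(comp %in% am), 2L)
      expect_equal(sum(comp %in% em), 2L)
    }
  }
})

test_that("designs are deterministic under a seed and reject bad pools", {
  pool <- species_pool()
  d1 <- generate_design(pool, seed = 11)
  d2 <- generate_design(pool, seed = 11)
  expect_identical(d1$plots, d2$plots)
  d3 <- generate_design(pool, seed = 12)
  expect_false(identical(d1$plots$composition, d3$plots$composition))
  bad <- species_pool()
  bad$mycorrhizal_type <- c(rep("AM", 6), rep("EM", 4))
  expect_error(generate_design(bad), "invalid pool")
})

test_that("plot layouts place 140 trees with exact per-species counts", {
  for (comp in list("AM1", c("AM1", "EM1"),
                    c("AM1", "AM2", "EM1", "EM2"))) {
    trees <- layout_plot(comp, seed = 3)
    expect_equal(nrow(trees), 140L)
    expect_true(all(table(trees$species_id) == 140L / length(comp)))
    expect_true(all(trees$x >= 0 & trees$x <= 11 &
                    trees$y >= 0 & trees$y <= 11))
    # corners removed, all positions distinct on the 1 m grid
    pos <- paste(trees$x, trees$y)
    expect_equal(anyDuplicated(pos), 0L)
    expect_false(any(pos %in% c("0 0", "0 11", "11 0", "11 11")))
  }
  a <- layout_plot(c("AM1", "EM1"), seed = 1)
  b <- layout_plot(c("AM1", "EM1"), seed = 2)
  expect_equal(table(a$species_id), table(b$species_id))
  expect_false(identical(a$species_id, b$species_id))
})

test_that("growth simulation responds to the injected diversity effect", {
  pool <- species_pool()
  # null effect: per-species expected increment identical across richness
  set.seed(10)
  mono <- simulate_growth(layout_plot("AM1"), pool, diversity_effect = 0,
                          mortality_prob = 0)
  four <- simulate_growth(layout_plot(c("AM1", "AM2", "EM1", "EM2")), pool,
                          diversity_effect = 0, mortality_prob = 0)
  inc1 <- mean(mono$D2 - mono$D1)
  inc4 <- mean(four$D2 - four$D1)
  expect_lt(abs(inc1 - inc4) / inc1, 0.15)   # same expectation, finite n

  # positive effect: mean volume increment strictly increasing in richness,
  # >= 200 trees per level
  set.seed(11)
  vol_inc <- sapply(list("AM1", c("AM1", "EM1"),
                         c("AM1", "AM2", "EM1", "EM2")), function(comp) {
    inc <- replicate(2, {
      cc <- simulate_growth(layout_plot(comp), pool, diversity_effect = 0.08,
                            mortality_prob = 0)
      mean(stem_volume(cc$D2, cc$H2) - stem_volume(cc$D1, cc$H1))
    })
    mean(inc)
  })
  expect_true(all(diff(vol_inc) > 0))
})

test_that("mortality flags follow the requested probabilities", {
  pool <- species_pool()
  trees <- layout_plot("AM1", seed = 1)
  all_alive <- simulate_growth(trees, pool, mortality_prob = 0, seed = 2)
  expect_true(all(all_alive$alive))
  all_dead <- simulate_growth(trees, pool, mortality_prob = 1, seed = 2)
  expect_equal(mortality_rate(all_dead), 1)
  expect_equal(all_dead$D2, all_dead$D1)   # dead trees keep planting size
  expect_equal(all_dead$H2, all_dead$H1)
  expect_error(simulate_growth(trees, pool, diversity_effect = -2), ">= -1")
  expect_error(simulate_growth(trees, pool, mortality_prob = 1.5), "\\[0, 1\\]")
})

test_that("scan simulator geometry matches its construction", {
  pool <- species_pool()
  census <- data.frame(plot_id = "X", species_id = "AM1", x = 5, y = 6,
                       D2 = 0.05, H2 = 4, alive = TRUE)
  # no crown points, no noise: everything within the stem radius of (x, y)
  cl <- simulate_scan(census, pool,
                      scan_params(points_per_tree = 50,
                                  crown_point_fraction = 0, noise_sd = 0,
                                  ground_points = 0), seed = 1)
  r <- sqrt((cl$points[, 1] - 5)^2 + (cl$points[, 2] - 6)^2)
  expect_true(all(r <= 0.025 + 1e-12))
  expect_equal(cl$scanner_origin, c(5.5, 5.5, 1.3))

  # max height tracks the tallest tree
  census2 <- data.frame(plot_id = "X", species_id = c("AM1", "EM1"),
                        x = c(3, 8), y = c(3, 8), D2 = 0.05,
                        H2 = c(2, 8), alive = TRUE)
  cl2 <- simulate_scan(census2, pool,
                       scan_params(points_per_tree = 400,
                                   crown_point_fraction = 0, noise_sd = 0.01,
                                   ground_points = 0), seed = 2)
  expect_lt(abs(max(cl2$points[, 3]) - 8), 0.1)

  # seeded determinism and the empty-census error
  cl3 <- simulate_scan(census2, pool, scan_params(points_per_tree = 40),
                       seed = 9)
  cl4 <- simulate_scan(census2, pool, scan_params(points_per_tree = 40),
                       seed = 9)
  expect_identical(cl3$points, cl4$points)
  expect_error(simulate_scan(census2[0, ], pool), "empty census")
})

test_that("stratification places tolerant crowns lower", {
  pool <- species_pool()
  tol_lo <- which.min(pool$shade_tolerance)   # least tolerant -> high crown
  tol_hi <- which.max(pool$shade_tolerance)
  mk <- function(i) data.frame(plot_id = "X",
                               species_id = pool$species_id[i],
                               x = 5.5, y = 5.5, D2 = 0.05, H2 = 6,
                               alive = TRUE)
  par <- scan_params(points_per_tree = 300, crown_point_fraction = 1,
                     noise_sd = 0, ground_points = 0, stratification = 1)
  hi <- simulate_scan(mk(tol_lo), pool, par, seed = 1)
  lo <- simulate_scan(mk(tol_hi), pool, par, seed = 1)
  expect_gt(mean(hi$points[, 3]), mean(lo$points[, 3]))
  # no stratification: identical crown placement
  par0 <- scan_params(points_per_tree = 300, crown_point_fraction = 1,
                      noise_sd = 0, ground_points = 0, stratification = 0)
  hi0 <- simulate_scan(mk(tol_lo), pool, par0, seed = 1)
  lo0 <- simulate_scan(mk(tol_hi), pool, par0, seed = 1)
  expect_equal(hi0$points, lo0$points)
})

test_that("light simulator attenuates with canopy and zeroes the night", {
  pool <- species_pool()
  empty <- data.frame(plot_id = "X", species_id = "AM1", x = 1, y = 1,
                      D2 = 0.05, H2 = 5, alive = TRUE)[0, ]
  grid <- expand.grid(x = 2:9, y = 2:9)
  dense <- data.frame(plot_id = "X", species_id = "AM1",
                      x = grid$x, y = grid$y, D2 = 0.08, H2 = 8,
                      alive = TRUE)
  lp <- light_params(noise_sd = 0)
  open <- simulate_light(empty, pool, lp, seed = 1)
  shaded <- simulate_light(dense, pool, lp, seed = 1)
  expect_gt(mean(open$value[open$value > 0]),
            mean(shaded$value[shaded$value > 0]))
  # nighttime hours are exactly zero
  expect_true(all(open$value[open$hour <= 6 | open$hour >= 20] == 0))
  # with no interception and no noise, readings equal the diel curve
  day <- open$hour > 6 & open$hour < 20
  expect_equal(open$value[day],
               1000 * sin(pi * (open$hour[day] - 6) / 14))
  # k -> large under cover: daytime readings -> 0
  dark <- simulate_light(dense, pool, light_params(extinction_k = 500,
                                                   noise_sd = 0), seed = 1)
  expect_lt(max(dark$value), 1e-6)
})
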