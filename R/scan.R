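#' Parameters of the single-scan point-cloud simulator
#'
#' @param points_per_tree baseline number of points per living tree
#'   (>= 10). The realized count per tree scales with its intercepting
#'   surface as `points_per_tree * (H2 / size_ref)^2` (floored at 10),
#'   mimicking a scanner returning more echoes from larger trees.
#' @param size_ref reference height (m) at which a tree receives exactly
#'   `points_per_tree` points.
#' @param crown_point_fraction fraction of a tree's points placed in its
#'   crown ellipsoid; the rest sample the stem.
#' @param stratification strength in `[0, 1]` of the shade-tolerance-driven
#'   vertical placement of crowns: at 1, shade-tolerant species' crowns sit
#'   low in the canopy and intolerant species' crowns high; at 0, all crowns
#'   sit at the same relative height and species identity has no structural
#'   signature.
#' @param noise_sd sd (m) of isotropic Gaussian coordinate noise.
#' @param ground_points number of soil-surface points added over the plot
#'   (z in `[0, 0.05]` m) so soil removal is exercised.
#' @return A list of class `"scan_params"`.
#' @export
scan_params <- function(points_per_tree = 200L, crown_point_fraction = 0.7,
                        stratification = 1, noise_sd = 0.01,
                        ground_points = 4000L, size_ref = 6) {
  if (points_per_tree < 10) stop("points_per_tree must be >= 10")
  if (size_ref <= 0) stop("size_ref must be > 0")
  if (crown_point_fraction < 0 || crown_point_fraction > 1)
    stop("crown_point_fraction must lie in [0, 1]")
  if (stratification < 0 || stratification > 1)
    stop("stratification must lie in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(points_per_tree = as.integer(points_per_tree),
                 crown_point_fraction = crown_point_fraction,
                 stratification = stratification,
                 noise_sd = noise_sd,
                 ground_points = as.integer(ground_points),
                 size_ref = size_ref),
            class = "scan_params")
}

## relative crown-centre height: 0.62 H at stratification 0, spread to
## [0.37, 0.87] H across the tolerance range at stratification 1
crown_center_rel <- function(tol01, stratification) {
  0.62 + stratification * 0.25 * (1 - 2 * tol01)
}

#' Simulate a central-scanner point cloud of one plot
#'
#' Emulates the geometry of a single terrestrial laser scan taken from a
#' tripod at the plot centre, 1.3 m above ground. For every living tree,
#' stem points are sampled on a linearly tapered vertical cone of height
#' `H2` and basal radius `D2 / 2`, and crown points uniformly inside an
#' ellipsoid whose vertical placement reflects the species' shade tolerance
#' (tolerant species' crowns sit lower; see [scan_params()]). A thin layer
#' of soil-surface points is added. Dead trees contribute no points.
#' Occlusion and scanner hardware effects are not modelled.
#'
#' @param census tree table from [simulate_growth()] (needs `x`, `y`, `D2`,
#'   `H2`, `alive`, `species_id`).
#' @param pool the [species_pool()].
#' @param params a [scan_params()] list.
#' @param bounds plot rectangle `c(xmin, xmax, ymin, ymax)`; default
#'   [plot_bounds()].
#' @param plot_id identifier stored on the cloud.
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @return A [point_cloud()] with scanner origin at the plot centre,
#'   `z = 1.3` m.
#' @examples
#' trees <- layout_plot("AM1", seed = 1)
#' census <- simulate_growth(trees, species_pool(), seed = 1)
#' cloud <- simulate_scan(census, species_pool(),
#'                        scan_params(points_per_tree = 20), seed = 1)
#' @export
simulate_scan <- function(census, pool, params = scan_params(),
                          bounds = plot_bounds(), plot_id = census$plot_id[1],
                          seed = NULL) {
  validate_pool(pool)
  if (nrow(census) == 0L) stop("empty census: cannot simulate a scan")
  if (!is.null(seed)) set.seed(as.integer(seed))
  live <- census[census$alive %||% rep(TRUE, nrow(census)), , drop = FALSE]

  tol <- pool$shade_tolerance
  tol_rng <- range(tol)
  tol01 <- if (diff(tol_rng) > 0) (tol - tol_rng[1]) / diff(tol_rng)
           else rep(0.5, length(tol))

  pts <- vector("list", nrow(live) + 1L)
  for (t in seq_len(nrow(live))) {
    i <- match(live$species_id[t], pool$species_id)
    h <- live$H2[t]; r0 <- live$D2[t] / 2
    xy <- c(live$x[t], live$y[t])
    npt <- max(10L, as.integer(round(
      params$points_per_tree * (h / params$size_ref)^2)))
    n_crown <- round(params$crown_point_fraction * npt)
    n_stem <- npt - n_crown
    out <- matrix(0, npt, 3L)
    if (n_stem > 0) {
      z <- stats::runif(n_stem, 0, h)
      r <- r0 * (1 - z / h)
      a <- stats::runif(n_stem, 0, 2 * pi)
      out[seq_len(n_stem), ] <- cbind(xy[1] + r * cos(a), xy[2] + r * sin(a), z)
    }
    if (n_crown > 0) {
      zc <- h * crown_center_rel(tol01[i], params$stratification)
      rx <- pool$crown_radius[i] * h
      rz <- pool$crown_depth[i] * h / 2
      u <- matrix(stats::rnorm(3 * n_crown), ncol = 3L)
      u <- u / sqrt(rowSums(u^2)) * stats::runif(n_crown)^(1 / 3)
      out[n_stem + seq_len(n_crown), ] <-
        cbind(xy[1] + rx * u[, 1], xy[2] + rx * u[, 2], zc + rz * u[, 3])
    }
    pts[[t]] <- out
  }
  ng <- params$ground_points
  if (ng > 0) {
    pts[[length(pts)]] <- cbind(stats::runif(ng, bounds[1], bounds[2]),
                                stats::runif(ng, bounds[3], bounds[4]),
                                stats::runif(ng, 0, 0.05))
  }
  p <- do.call(rbind, pts)
  if (params$noise_sd > 0)
    p <- p + matrix(stats::rnorm(length(p), 0, params$noise_sd), ncol = 3L)
  origin <- c(mean(bounds[1:2]), mean(bounds[3:4]), 1.3)
  point_cloud(p, scanner_origin = origin, plot_id = plot_id)
}

#' Parameters of the ground-light simulator
#'
#' @param i_max peak clear-sky intensity of the diel curve (arbitrary
#'   units); the curve is a half-sine between 06:00 and 20:00, zero at
#'   night.
#' @param extinction_k Beer-Lambert extinction coefficient (>= 0) applied to
#'   the leaf-area proxy of crowns overhanging a sensor.
#' @param noise_sd sd of additive Gaussian noise on daytime readings
#'   (clipped at zero).
#' @param days number of days in the series (hourly resolution).
#' @return A list of class `"light_params"`.
#' @export
light_params <- function(i_max = 1000, extinction_k = 0.5, noise_sd = 20,
                         days = 31L) {
  if (extinction_k < 0) stop("extinction_k must be >= 0")
  structure(list(i_max = i_max, extinction_k = extinction_k,
                 noise_sd = noise_sd, days = as.integer(days)),
            class = "light_params")
}

diel_curve <- function(hour, i_max) {
  ifelse(hour > 6 & hour < 20, i_max * sin(pi * (hour - 6) / 14), 0)
}

#' Simulate hourly ground-light series for one plot
#'
#' Four sensors at 20 cm height, one per plot quadrant, record hourly light
#' over a month. Each daytime reading is the clear-sky diel curve attenuated
#' by `exp(-k * L)`, where `L` is a leaf-area proxy summed over living
#' crowns overhanging the sensor (a tree contributes `1 - (d/r)^2` when its
#' horizontal distance `d` to the sensor is within its crown radius `r`),
#' plus Gaussian noise clipped at zero. Nighttime readings are exactly zero.
#'
#' @inheritParams simulate_scan
#' @param params a [light_params()] list.
#' @return A long-format data.frame: `plot_id`, `sensor`, `day`, `hour`,
#'   `value`.
#' @export
simulate_light <- function(census, pool, params = light_params(),
                           bounds = plot_bounds(), plot_id = census$plot_id[1],
                           seed = NULL) {
  validate_pool(pool)
  if (!is.null(seed)) set.seed(as.integer(seed))
  qx <- bounds[1] + c(0.25, 0.25, 0.75, 0.75) * (bounds[2] - bounds[1])
  qy <- bounds[3] + c(0.25, 0.75, 0.25, 0.75) * (bounds[4] - bounds[3])
  live <- census[census$alive %||% rep(TRUE, nrow(census)), , drop = FALSE]
  i <- match(live$species_id, pool$species_id)
  r_crown <- pool$crown_radius[i] * live$H2

  hours <- 0:23
  grid <- expand.grid(hour = hours, day = seq_len(params$days))
  base <- diel_curve(grid$hour, params$i_max)
  out <- vector("list", 4L)
  for (s in 1:4) {
    d <- sqrt((live$x - qx[s])^2 + (live$y - qy[s])^2)
    over <- d < r_crown
    l_above <- sum((1 - (d[over] / r_crown[over])^2))
    att <- exp(-params$extinction_k * l_above)
    val <- base * att
    day <- val > 0
    val[day] <- pmax(0, val[day] + stats::rnorm(sum(day), 0, params$noise_sd))
    out[[s]] <- data.frame(plot_id = plot_id, sensor = s,
                           day = grid$day, hour = grid$hour, value = val,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
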