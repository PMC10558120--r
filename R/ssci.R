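#' Effective number of layers (ENL) of a voxel grid
#'
#' Cuts the filled-voxel set into horizontal layers of `slice_thickness`
#' (default 25 cm), anchored at the lowest filled voxel, and computes the
#' inverse Simpson diversity of the per-layer filled-voxel proportions:
#' `ENL = 1 / sum(p_i^2)` with `p_i` the share of filled voxels in layer
#' `i`. ENL is 1 when all filled voxels share one layer and equals the
#' number of layers when they are spread evenly; it captures the vertical
#' stratification of a stand and grows with stand height.
#'
#' @param grid a [voxelize()]d grid with at least one filled voxel.
#' @param slice_thickness layer height in m; default 0.25.
#' @return A list with `ENL` and `layer_profile` (data.frame `layer`,
#'   `n_filled`, `p`).
#' @examples
#' cl <- point_cloud(cbind(runif(100), runif(100), runif(100)))
#' effective_number_of_layers(voxelize(cl))$ENL
#' @export
effective_number_of_layers <- function(grid, slice_thickness = 0.25) {
  if (!inherits(grid, "voxel_grid")) stop("grid must be a voxel_grid")
  if (grid$n_filled < 1L) stop("grid has no filled voxels")
  if (slice_thickness <= 0) stop("slice_thickness must be > 0")
  k <- grid$voxels[, "k"]
  z_low <- (k - min(k)) * grid$voxel_size
  layer <- floor(z_low / slice_thickness + 1e-9)
  n <- tabulate(layer + 1L)
  p <- n / sum(n)
  list(ENL = 1 / sum(p^2),
       layer_profile = data.frame(layer = seq_along(n) - 1L,
                                  n_filled = n, p = p))
}

#' Azimuthal cross sections of a central scan
#'
#' Bins the points of a cloud into `n_sections` equal azimuth sectors about
#' the scanner position (default 4500 sectors of 0.08 degrees). Within each
#' sector every point is mapped into the vertical plane as `(d, z)` —
#' horizontal distance from the scanner and height relative to the scanner
#' — and the points, sorted by elevation angle `atan2(z, d)`, are joined
#' into a polygon closed through the scanner position at `(0, 0)`. The
#' polygon's perimeter is the sum of its edge lengths and its area comes
#' from the shoelace formula. Sectors with fewer than 3 points are flagged
#' degenerate and excluded from downstream averaging.
#'
#' @param cloud a nonempty [point_cloud()].
#' @param scanner_origin `(x, y, z)` of the scanner; defaults to the
#'   cloud's recorded origin.
#' @param n_sections number of azimuth sectors; default 4500.
#' @param vertices if `TRUE`, also return the sorted `(d, z)` vertices of
#'   each section (list column `vertices`); intended for small clouds.
#' @return A data.frame with one row per section: `azimuth_index` (0-based),
#'   `n_points`, `perimeter` (m), `area` (m^2), `valid`.
#' @export
build_cross_sections <- function(cloud, scanner_origin = cloud$scanner_origin,
                                 n_sections = 4500L, vertices = FALSE) {
  p <- cloud$points
  if (nrow(p) == 0L) stop("cannot section an empty cloud")
  if (is.null(scanner_origin) || length(scanner_origin) != 3L)
    stop("scanner_origin (x, y, z) is required")
  if (n_sections < 1L) stop("n_sections must be >= 1")

  dx <- p[, 1] - scanner_origin[1]
  dy <- p[, 2] - scanner_origin[2]
  z <- p[, 3] - scanner_origin[3]
  d <- sqrt(dx^2 + dy^2)
  az <- atan2(dy, dx) %% (2 * pi)
  sec <- pmin(floor(az / (2 * pi / n_sections)), n_sections - 1L)
  elev <- atan2(z, d)

  o <- order(sec, elev)
  g <- sec[o]; x1 <- d[o]; y1 <- z[o]
  n <- length(g)
  ## consecutive-pair terms within each sector; edges through (0, 0)
  ## contribute nothing to the shoelace sum and |v| each to the perimeter
  lev <- seq_len(n_sections) - 1L
  by_sector <- function(x, grp) {
    out <- numeric(n_sections)
    if (length(x)) {
      rs <- rowsum(x, grp)
      out[as.integer(rownames(rs)) + 1L] <- rs[, 1L]
    }
    out
  }
  same <- g[-n] == g[-1L]
  cross <- (x1[-n] * y1[-1L] - x1[-1L] * y1[-n]) * same
  seg <- sqrt((x1[-n] - x1[-1L])^2 + (y1[-n] - y1[-1L])^2) * same
  area2 <- by_sector(cross, g[-n])
  inner <- by_sector(seg, g[-n])
  first <- !duplicated(g)
  last <- rev(!duplicated(rev(g)))
  radius <- sqrt(x1^2 + y1^2)
  ends <- by_sector(radius * first, g) + by_sector(radius * last, g)
  npts <- tabulate(g + 1L, nbins = n_sections)

  res <- data.frame(azimuth_index = lev, n_points = npts,
                    perimeter = inner + ends, area = abs(area2) / 2,
                    valid = npts >= 3L)
  if (vertices) {
    vl <- rep(list(matrix(numeric(0), 0L, 2L)), n_sections)
    sp <- split(seq_len(n), g)
    for (nm in names(sp)) {
      ii <- sp[[nm]]
      vl[[as.integer(nm) + 1L]] <- cbind(d = x1[ii], z = y1[ii])
    }
    res$vertices <- vl
  }
  res
}

#' Fractal dimension of a cross-section polygon
#'
#' A perimeter-area fractal dimension in the FRAGSTATS tradition:
#' `frac = 2 * ln(0.25 * P) / ln(A)`, clamped to `[1, 2]`. Squares attain
#' the minimum of 1 at any scale; increasingly convoluted outlines approach
#' 2. Sections whose area is within `eps` of 1 m^2 are excluded as
#' log-degenerate (the denominator vanishes), as are non-positive inputs;
#' excluded sections return `NA`.
#'
#' @param perimeter polygon perimeter(s), m.
#' @param area polygon area(s), m^2.
#' @param eps exclusion half-width around `A = 1`; default `1e-6`.
#' @return Numeric vector of fractal dimensions in `[1, 2]`, `NA` where
#'   degenerate.
#' @examples
#' fractal_dimension(8, 4)   # square of side 2 -> 1
#' @export
fractal_dimension <- function(perimeter, area, eps = 1e-6) {
  bad <- !(perimeter > 0 & area > 0) | abs(area - 1) <= eps
  f <- 2 * log(0.25 * perimeter) / log(area)
  f <- pmin(pmax(f, 1), 2)
  f[bad] <- NA_real_
  f
}

#' Stand structural complexity index (SSCI) of a plot cloud
#'
#' Runs the full index computation on a single-scan plot cloud: removes the
#' soil-surface layer, voxelizes at `voxel_size`, computes the effective
#' number of layers over `slice_thickness` slices, builds `n_sections`
#' azimuthal cross sections and averages their fractal dimension
#' (`MeanFrac`), and combines the two components as
#'
#' `SSCI = MeanFrac ^ ln(ENL)`.
#'
#' `MeanFrac` (in `[1, 2]`) captures the density and convolution of
#' structural elements; `ENL` (>= 1) the vertical stratification. SSCI is 1
#' whenever `ENL = 1` or `MeanFrac = 1`.
#'
#' @param cloud a [point_cloud()] with a scanner origin.
#' @param voxel_size voxel edge (m), default 0.05.
#' @param slice_thickness ENL layer height (m), default 0.25.
#' @param n_sections azimuth sectors for `MeanFrac`, default 4500.
#' @param soil_height removed soil layer (m), default 0.10; set to `NULL`
#'   to skip soil removal.
#' @return An object of class `"ssci"`: `SSCI`, `ENL`, `MeanFrac`,
#'   `n_valid_sections`, `layer_profile`, `plot_id`, plus the parameters
#'   used.
#' @examples
#' trees <- layout_plot("AM1", seed = 1)
#' census <- simulate_growth(trees, species_pool(), seed = 1)
#' cloud <- simulate_scan(census, species_pool(),
#'                        scan_params(points_per_tree = 30), seed = 1)
#' compute_ssci(cloud, n_sections = 360)
#' @export
compute_ssci <- function(cloud, voxel_size = 0.05, slice_thickness = 0.25,
                         n_sections = 4500L, soil_height = 0.10) {
  if (nrow(cloud$points) == 0L) stop("cannot compute SSCI of an empty cloud")
  clean <- if (is.null(soil_height)) cloud
           else remove_soil_layer(cloud, soil_height)
  if (nrow(clean$points) == 0L)
    stop("no points left after soil removal; SSCI undefined")
  grid <- voxelize(clean, voxel_size)
  enl <- effective_number_of_layers(grid, slice_thickness)
  cs <- build_cross_sections(clean, cloud$scanner_origin, n_sections)
  frac <- fractal_dimension(cs$perimeter[cs$valid], cs$area[cs$valid])
  frac <- frac[!is.na(frac)]
  if (!length(frac))
    stop("no valid cross sections (all degenerate or log-excluded); ",
         "SSCI undefined")
  mean_frac <- mean(frac)
  structure(list(SSCI = mean_frac^log(enl$ENL), ENL = enl$ENL,
                 MeanFrac = mean_frac, n_valid_sections = length(frac),
                 n_sections = nrow(cs), layer_profile = enl$layer_profile,
                 plot_id = cloud$plot_id,
                 params = list(voxel_size = voxel_size,
                               slice_thickness = slice_thickness,
                               n_sections = n_sections,
                               soil_height = soil_height)),
            class = "ssci")
}

#' @export
print.ssci <- function(x, ...) {
  cat(sprintf(
    "SSCI %s= %.4f  (ENL = %.3f, MeanFrac = %.4f, %d/%d valid sections)\n",
    if (!is.null(x$plot_id)) paste0("[", x$plot_id, "] ") else "",
    x$SSCI, x$ENL, x$MeanFrac, x$n_valid_sections, x$n_sections))
  invisible(x)
}

#' @export
plot.ssci <- function(x, ...) {
  pr <- x$layer_profile
  graphics::barplot(pr$p, names.arg = pr$layer, horiz = TRUE,
                    xlab = "share of filled voxels",
                    ylab = sprintf("layer (%.2g m slices)",
                                   x$params$slice_thickness), ...)
  invisible(x)
}
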