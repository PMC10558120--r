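#' Select the center trees of a plot
#'
#' Growth analyses avoid edge effects by restricting to the trees inside a
#' centered window (default 8 m by 8 m). On the standard 140-tree layout
#' this retains exactly the 64 trees of the 8 x 8 core.
#'
#' @param trees tree table with `x`, `y` columns.
#' @param bounds plot rectangle `c(xmin, xmax, ymin, ymax)`.
#' @param window side length (m) of the centered square; default 8.
#' @return The subset of `trees` inside the closed window.
#' @examples
#' nrow(select_center_trees(layout_plot("AM1", seed = 1)))  # 64
#' @export
select_center_trees <- function(trees, bounds = plot_bounds(), window = 8) {
  cx <- mean(bounds[1:2]); cy <- mean(bounds[3:4])
  half <- window / 2
  keep <- abs(trees$x - cx) <= half & abs(trees$y - cy) <= half
  trees[keep, , drop = FALSE]
}

#' Stem volume from diameter and height
#'
#' Estimates the wood volume of a tree from its stem diameter `D` (m,
#' measured at 5 cm aboveground) and height `H` (m) with a cylindrical form
#' factor `f` (default 0.5, an average for young broadleaves) that corrects
#' for stem taper. Two conventions are provided:
#'
#' * `"literal"` (default): `V = pi * D^2 * H * f`;
#' * `"cylinder-quarter"`: `V = pi * (D^2 / 4) * H * f`, the geometric
#'   cylinder with the same form factor.
#'
#' The two differ by a constant factor of 4, which cancels out of every
#' relative quantity downstream (overyielding ratios, effect sizes).
#'
#' @param D stem diameter(s), m; `>= 0`.
#' @param H tree height(s), m; `>= 0`.
#' @param form_factor form factor in `(0, 1]`; default 0.5.
#' @param convention `"literal"` or `"cylinder-quarter"`.
#' @return Volume(s), m^3.
#' @examples
#' stem_volume(0.05, 2)               # 0.0078540
#' @export
stem_volume <- function(D, H, form_factor = 0.5,
                        convention = c("literal", "cylinder-quarter")) {
  convention <- match.arg(convention)
  if (any(D < 0) || any(H < 0)) stop("D and H must be >= 0")
  if (form_factor <= 0 || form_factor > 1)
    stop("form_factor must lie in (0, 1]")
  v <- pi * D^2 * H * form_factor
  if (convention == "cylinder-quarter") v <- v / 4
  v
}

#' Annual wood productivity (AWP) of a set of trees
#'
#' Sums the annual stem-volume increment `(V2 - V1) / (t2 - t1)` over all
#' trees alive at the second census; dead trees are excluded. Per-species
#' totals are returned alongside the plot total and always sum to it.
#'
#' @param trees census table with `species_id`, `D1`, `D2`, `H1`, `H2`,
#'   `alive` (missing `alive` counts every tree as living).
#' @param t1,t2 census years; `t2 > t1`. Defaults 2015 and 2021.
#' @param form_factor,convention passed to [stem_volume()].
#' @return An object of class `"stand_productivity"`: `AWP` (m^3/yr),
#'   `per_species_awp` (named vector), `n_living`, `interval`.
#' @examples
#' trees <- simulate_growth(layout_plot("AM1", seed = 1), species_pool(),
#'                          seed = 1)
#' annual_wood_productivity(select_center_trees(trees))
#' @export
annual_wood_productivity <- function(trees, t1 = 2015, t2 = 2021,
                                     form_factor = 0.5,
                                     convention = "literal") {
  if (t2 <= t1) stop("t2 must be after t1")
  needed <- c("species_id", "D1", "D2", "H1", "H2")
  if (!all(needed %in% names(trees)))
    stop("census table lacks columns: ",
         paste(setdiff(needed, names(trees)), collapse = ", "))
  alive <- trees$alive %||% rep(TRUE, nrow(trees))
  live <- trees[alive, , drop = FALSE]
  dt <- t2 - t1
  inc <- (stem_volume(live$D2, live$H2, form_factor, convention) -
          stem_volume(live$D1, live$H1, form_factor, convention)) / dt
  per_species <- if (nrow(live)) tapply(inc, live$species_id, sum)
                 else numeric(0)
  per_species <- unlist(as.list(per_species))
  structure(list(AWP = sum(inc), per_species_awp = per_species,
                 n_living = nrow(live), interval = c(t1 = t1, t2 = t2)),
            class = "stand_productivity")
}

#' @export
print.stand_productivity <- function(x, ...) {
  cat(sprintf("AWP = %.5f m^3/yr over %d living trees (%d-%d)\n",
              x$AWP, x$n_living, x$interval[1], x$interval[2]))
  if (length(x$per_species_awp) > 1L) {
    cat("  per species:\n")
    print(round(x$per_species_awp, 6))
  }
  invisible(x)
}

#' Plot-level tree mortality rate
#'
#' The fraction of planted trees that died over the census interval,
#' computed over every planted tree (not just the center trees).
#'
#' @param trees census table with an `alive` flag.
#' @return Mortality rate in `[0, 1]`.
#' @export
mortality_rate <- function(trees) {
  if (nrow(trees) == 0L) stop("cannot compute mortality of an empty tree set")
  if (is.null(trees$alive)) stop("census table lacks an 'alive' column")
  mean(!trees$alive)
}
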