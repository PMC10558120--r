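#' Community-weighted mean of a trait
#'
#' Abundance-weighted average trait value, `sum(w_j * x_j)` with weights
#' `w_j = a_j / sum(a_j)`. Abundances are typically the mortality-corrected
#' 2021 living-tree counts per species.
#'
#' @param x trait values per species (e.g. shade-tolerance indices).
#' @param a abundances per species; nonnegative, not all zero. Default:
#'   equal weights.
#' @return The community-weighted mean (trait units).
#' @examples
#' cwm(c(1, 3), c(3, 1))   # 1.5
#' @export
cwm <- function(x, a = rep(1, length(x))) {
  check_trait_args(x, a)
  sum(a / sum(a) * x)
}

#' Functional dispersion of a single trait
#'
#' One-dimensional functional dispersion (FDis): the abundance-weighted
#' mean absolute distance of species' trait values to the
#' abundance-weighted centroid, `FD = sum(w_j * |x_j - c|)` with
#' `c = cwm(x, a)`. Zero for monocultures; translation-invariant in `x` and
#' linear under rescaling of `x`.
#'
#' @inheritParams cwm
#' @return The functional dispersion (trait units).
#' @examples
#' fdis(c(0, 1))          # 0.5
#' fdis(c(1, 3), c(3, 1)) # 0.75
#' @export
fdis <- function(x, a = rep(1, length(x))) {
  check_trait_args(x, a)
  w <- a / sum(a)
  sum(w * abs(x - sum(w * x)))
}

check_trait_args <- function(x, a) {
  if (length(x) != length(a)) stop("x and a must have equal length")
  if (any(a < 0)) stop("abundances must be >= 0")
  if (sum(a) <= 0) stop("abundances must not be all zero")
  invisible(NULL)
}

#' Ground-light interception proxy of a plot
#'
#' Averages a month of hourly ground-light readings into one plot-level
#' intensity: per sensor, the mean of the strictly positive readings
#' (nighttime zeros excluded); then the mean over the four sensors. Lower
#' values indicate stronger light interception by the canopy overhead.
#'
#' @param series long-format data.frame with columns `sensor` and `value`
#'   (from [simulate_light()] or a sensor export).
#' @return An object of class `"light_summary"`: `mean_intensity`,
#'   `per_sensor` (named vector), `n_sensors`.
#' @export
light_interception_proxy <- function(series) {
  if (!all(c("sensor", "value") %in% names(series)))
    stop("series needs 'sensor' and 'value' columns")
  pos <- series[series$value > 0, , drop = FALSE]
  if (nrow(pos) == 0L) stop("no positive light readings")
  per_sensor <- tapply(pos$value, pos$sensor, mean)
  per_sensor <- unlist(as.list(per_sensor))
  n_all <- length(unique(series$sensor))
  if (length(per_sensor) < n_all)
    warning("some sensors recorded no positive readings; ",
            "plot mean uses the remaining sensors")
  structure(list(mean_intensity = mean(per_sensor), per_sensor = per_sensor,
                 n_sensors = n_all),
            class = "light_summary")
}

#' @export
print.light_summary <- function(x, ...) {
  cat(sprintf("Ground light: mean intensity %.2f over %d sensors\n",
              x$mean_intensity, x$n_sensors))
  invisible(x)
}

#' Classify plots into light-intensity quantile classes
#'
#' Splits a set of plot-level intensities at their `q_low` and `q_high`
#' quantiles (default the 25% and 75% quantiles): values at or below the
#' lower quantile are `"low"`, values at or above the upper quantile
#' `"high"`, the rest `"mid"`. A degenerate split (the two quantiles
#' coincide, e.g. all values equal) is flagged with a warning and the
#' attribute `degenerate`.
#'
#' @param values numeric plot-level intensities.
#' @param q_low,q_high quantile probabilities; defaults 0.25 and 0.75.
#' @return A character vector of classes with attribute `breaks` (the two
#'   quantiles) and `degenerate`.
#' @export
classify_quantiles <- function(values, q_low = 0.25, q_high = 0.75) {
  if (q_low >= q_high) stop("q_low must be below q_high")
  qs <- stats::quantile(values, c(q_low, q_high), names = FALSE, na.rm = TRUE)
  degenerate <- !(qs[2] > qs[1])
  if (degenerate) warning("degenerate quantile split: identical quantiles")
  cls <- rep("mid", length(values))
  cls[values <= qs[1]] <- "low"
  cls[values >= qs[2]] <- "high"
  if (degenerate) cls <- rep("mid", length(values))
  structure(cls, breaks = qs, degenerate = degenerate)
}
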