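#' Build a species pool for a synthetic tree diversity experiment
#'
#' The design generator expects a pool of 10 deciduous tree species, five
#' preferring arbuscular mycorrhiza (AM) and five preferring ectomycorrhiza
#' (EM). Each species carries a shade-tolerance index (dimensionless, higher
#' means more tolerant of low light; values on the usual 1--5 literature
#' scale), expected stem diameters and heights at the two censuses, a
#' dispersion parameter for lognormal growth variation, and crown-shape
#' coefficients used by the scan simulator.
#'
#' The default pool is synthetic: the shade-tolerance values, allometry and
#' crown coefficients are plausible for young temperate broadleaves but are
#' not tied to any real species list. All ten species share the same expected
#' growth by default, so that systematic differences between richness levels
#' arise only from the effects a simulation explicitly injects
#' (`diversity_effect`, `stratification`) and not from species identity.
#'
#' @param species_id character vector of species labels.
#' @param mycorrhizal_type character vector, `"AM"` or `"EM"` per species.
#' @param shade_tolerance numeric shade-tolerance index per species.
#' @param d1_mean,d2_mean expected stem diameter (m, at 5 cm aboveground) at
#'   the first and second census.
#' @param h1_mean,h2_mean expected tree height (m) at the two censuses.
#' @param growth_sdlog lognormal sd (log scale) of individual growth variation.
#' @param crown_depth crown depth as a fraction of tree height.
#' @param crown_radius crown radius as a fraction of tree height.
#' @return A `data.frame` with one row per species and class
#'   `"species_pool"`.
#' @examples
#' pool <- species_pool()
#' table(pool$mycorrhizal_type)
#' @export
species_pool <- function(species_id = c(paste0("AM", 1:5), paste0("EM", 1:5)),
                         mycorrhizal_type = rep(c("AM", "EM"), each = 5),
                         shade_tolerance = c(1.2, 2.0, 2.9, 3.7, 4.5,
                                             1.5, 2.3, 3.1, 3.9, 4.3),
                         d1_mean = 0.015, d2_mean = 0.06,
                         h1_mean = 1.0, h2_mean = 6.0,
                         growth_sdlog = 0.25,
                         crown_depth = 0.45, crown_radius = 0.18) {
  n <- length(species_id)
  pool <- data.frame(
    species_id = as.character(species_id),
    mycorrhizal_type = rep_len(as.character(mycorrhizal_type), n),
    shade_tolerance = rep_len(shade_tolerance, n),
    d1_mean = rep_len(d1_mean, n), d2_mean = rep_len(d2_mean, n),
    h1_mean = rep_len(h1_mean, n), h2_mean = rep_len(h2_mean, n),
    growth_sdlog = rep_len(growth_sdlog, n),
    crown_depth = rep_len(crown_depth, n),
    crown_radius = rep_len(crown_radius, n),
    stringsAsFactors = FALSE
  )
  validate_pool(pool)
  class(pool) <- c("species_pool", "data.frame")
  pool
}

validate_pool <- function(pool) {
  stopifnot(is.data.frame(pool))
  needed <- c("species_id", "mycorrhizal_type", "shade_tolerance",
              "d1_mean", "d2_mean", "h1_mean", "h2_mean",
              "growth_sdlog", "crown_depth", "crown_radius")
  missing <- setdiff(needed, names(pool))
  if (length(missing))
    stop("species pool lacks columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(pool$species_id))
    stop("duplicated species_id in pool")
  if (!all(pool$mycorrhizal_type %in% c("AM", "EM")))
    stop("mycorrhizal_type must be 'AM' or 'EM'")
  if (!all(is.finite(pool$shade_tolerance)))
    stop("shade_tolerance must be finite")
  if (!all(pool$d1_mean > 0 & pool$d2_mean > 0 &
           pool$h1_mean > 0 & pool$h2_mean > 0))
    stop("expected diameters and heights must be strictly positive")
  if (!all(pool$d2_mean >= pool$d1_mean & pool$h2_mean >= pool$h1_mean))
    stop("expected size at second census must not be below first census")
  invisible(pool)
}

#' @export
print.species_pool <- function(x, ...) {
  cat("Species pool:", nrow(x), "species (",
      sum(x$mycorrhizal_type == "AM"), "AM /",
      sum(x$mycorrhizal_type == "EM"), "EM )\n")
  print.data.frame(x, ...)
  invisible(x)
}
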