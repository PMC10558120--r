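#' Additive partitioning of the net biodiversity effect
#'
#' Partitions the net biodiversity effect (NBE, overyielding) of a mixture
#' into complementarity and selection effects in the Loreau-Hector sense.
#' With `N` species, observed per-species mixture yields `Y_O_i`,
#' monoculture means `M_i` and expected relative yields `RY_E_i` (the
#' planted proportions), the relative-yield deviations are
#' `dRY_i = Y_O_i / M_i - RY_E_i` and
#'
#' * `NBE = sum(Y_O_i) - sum(RY_E_i * M_i)`
#' * `CE  = N * mean(dRY) * mean(M)`
#' * `SE  = N * cov_pop(dRY, M)` (population covariance, divide by `N`)
#'
#' so that `NBE = CE + SE` holds exactly. A positive CE indicates that
#' species on average yield more than their monoculture expectation
#' (resource partitioning, facilitation); a positive SE that high-yielding
#' species dominate the deviations.
#'
#' @param y_obs named numeric: observed yield of each species in the
#'   mixture (e.g. per-species AWP, m^3/yr).
#' @param mono_means named numeric: monoculture mean yield of each species;
#'   all strictly positive.
#' @param proportions expected relative yields (planted proportions);
#'   default equal; must sum to 1.
#' @return An object of class `"bef_partition"`: `NBE`, `CE`, `SE`, `N`,
#'   `delta_ry`, `mono_means`, `y_obs`, `proportions`.
#' @examples
#' additive_partitioning(c(a = 7, b = 12), c(a = 10, b = 20))
#' @export
additive_partitioning <- function(y_obs, mono_means,
                                  proportions = rep(1 / length(y_obs),
                                                    length(y_obs))) {
  n <- length(y_obs)
  if (length(mono_means) != n || length(proportions) != n)
    stop("y_obs, mono_means and proportions must have equal length")
  if (!is.null(names(y_obs)) && !is.null(names(mono_means)))
    mono_means <- mono_means[names(y_obs)]
  if (anyNA(mono_means) || any(mono_means <= 0))
    stop("all monoculture means must be strictly positive ",
         "(relative yields undefined otherwise)")
  if (abs(sum(proportions) - 1) > 1e-8)
    stop("expected relative yields must sum to 1")
  d_ry <- y_obs / mono_means - proportions
  ce <- n * mean(d_ry) * mean(mono_means)
  se <- sum((d_ry - mean(d_ry)) * (mono_means - mean(mono_means)))
  structure(list(NBE = sum(y_obs) - sum(proportions * mono_means),
                 CE = ce, SE = se, N = n, delta_ry = d_ry,
                 mono_means = mono_means, y_obs = y_obs,
                 proportions = proportions),
            class = "bef_partition")
}

#' @export
print.bef_partition <- function(x, ...) {
  cat(sprintf("Net biodiversity effect over %d species:\n", x$N))
  cat(sprintf("  NBE = %.6g  (CE = %.6g, SE = %.6g)\n", x$NBE, x$CE, x$SE))
  invisible(x)
}

#' Net biodiversity effect on stand structural complexity (delta-SSCI)
#'
#' Compares the observed SSCI of a mixture plot with the SSCI predicted
#' from the monoculture plots of its component species:
#' `delta = SSCI_obs - sum(p_i * mono_mean_i)`, where `p_i` are the 2021
#' relative abundances of the species in the plot (living trees, i.e.
#' corrected for mortality) and `mono_mean_i` the average SSCI of the
#' species' monocultures. Positive values mean the stand is structurally
#' more complex than expected from its parts.
#'
#' @param ssci_obs observed SSCI of the plot (number, or an `"ssci"`
#'   object).
#' @param mono_means named numeric: mean monoculture SSCI per species.
#' @param p named numeric: relative abundances of the plot's species;
#'   nonnegative, summing to 1.
#' @return An object of class `"delta_ssci"`: `delta`, `ssci_obs`,
#'   `ssci_pred`, `p`, `mono_means`.
#' @examples
#' delta_ssci(6.0, c(a = 4, b = 5), c(a = 0.5, b = 0.5))   # delta = 1.5
#' @export
delta_ssci <- function(ssci_obs, mono_means, p) {
  if (inherits(ssci_obs, "ssci")) ssci_obs <- ssci_obs$SSCI
  if (any(p < 0)) stop("relative abundances must be >= 0")
  if (abs(sum(p) - 1) > 1e-8) stop("relative abundances must sum to 1")
  if (!is.null(names(p))) {
    missing <- setdiff(names(p), names(mono_means))
    if (length(missing))
      stop("no monoculture mean for species: ",
           paste(missing, collapse = ", "))
    mono_means <- mono_means[names(p)]
  } else if (length(mono_means) != length(p)) {
    stop("p and mono_means must match")
  }
  pred <- sum(p * mono_means)
  structure(list(delta = ssci_obs - pred, ssci_obs = ssci_obs,
                 ssci_pred = pred, p = p, mono_means = mono_means),
            class = "delta_ssci")
}

#' @export
print.delta_ssci <- function(x, ...) {
  cat(sprintf("delta-SSCI = %.4f (observed %.4f, predicted %.4f)\n",
              x$delta, x$ssci_obs, x$ssci_pred))
  invisible(x)
}

#' Hedges' g standardized mean difference
#'
#' Effect size between two groups: difference of means divided by the
#' pooled standard deviation, multiplied by the small-sample correction
#' `J = 1 - 3 / (4 * (n1 + n2) - 9)`. Positive values mean group 1 exceeds
#' group 2; conventional thresholds of 0.2, 0.5 and 0.8 mark small,
#' moderate and large effects.
#'
#' @param x1,x2 numeric samples of the two groups, each of length >= 2.
#' @param correction apply the small-sample correction `J` (default
#'   `TRUE`).
#' @return An object of class `"hedges_g"`: `g`, `mean_diff`, `pooled_sd`,
#'   `J`, `n1`, `n2`.
#' @examples
#' hedges_g(rnorm(10, 1), rnorm(10))
#' @export
hedges_g <- function(x1, x2, correction = TRUE) {
  n1 <- length(x1); n2 <- length(x2)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 values")
  sp <- sqrt(((n1 - 1) * stats::var(x1) + (n2 - 1) * stats::var(x2)) /
             (n1 + n2 - 2))
  if (sp == 0) stop("pooled standard deviation is zero")
  j <- if (correction) 1 - 3 / (4 * (n1 + n2) - 9) else 1
  structure(list(g = (mean(x1) - mean(x2)) / sp * j,
                 mean_diff = mean(x1) - mean(x2), pooled_sd = sp, J = j,
                 n1 = n1, n2 = n2),
            class = "hedges_g")
}

#' @export
print.hedges_g <- function(x, ...) {
  cat(sprintf("Hedges' g = %.4f (pooled SD %.4g, n = %d/%d, J = %.4f)\n",
              x$g, x$pooled_sd, x$n1, x$n2, x$J))
  invisible(x)
}
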