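#' Configuration of a full synthetic experiment run
#'
#' Bundles every tunable parameter of the simulate -> clean -> SSCI ->
#' productivity -> effects -> traits chain. Defaults encode the standard
#' study conditions: an 80-plot two-block design, 140 trees per plot,
#' censuses in 2015 and 2021, a 5 cm voxel grid with 25 cm ENL slices and
#' 4500 azimuthal cross sections, a 0.10 m soil layer, a moderate injected
#' overyielding signal (`diversity_effect = 0.08` per unit log2 richness),
#' full shade-tolerance-driven crown stratification, and 10% six-year
#' mortality. Light sensors are installed in a random half of the plots.
#'
#' @param seed integer master seed; every random draw of the run descends
#'   from it.
#' @param diversity_effect fractional growth bonus per unit log2 richness
#'   (see [simulate_growth()]); 0 gives the null generator.
#' @param stratification crown stratification strength in `[0, 1]` (see
#'   [scan_params()]); 0 removes the structural species signature.
#' @param mortality_prob per-tree six-year death probability.
#' @param t1,t2 census years.
#' @param voxel_size,slice_thickness,n_sections,soil_height SSCI
#'   parameters, see [compute_ssci()].
#' @param volume_convention `"literal"` or `"cylinder-quarter"`, see
#'   [stem_volume()].
#' @param form_factor stem form factor.
#' @param points_per_tree,crown_point_fraction,noise_sd,ground_points scan
#'   simulator parameters, see [scan_params()].
#' @param extinction_k,light_days light simulator parameters, see
#'   [light_params()].
#' @param light_plot_fraction fraction of plots instrumented with light
#'   sensors.
#' @param out_dir optional directory where [run_pipeline()] persists every
#'   stage's tables; `NULL` keeps everything in memory.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(seed = 1L,
                       diversity_effect = 0.08,
                       stratification = 1,
                       mortality_prob = 0.10,
                       t1 = 2015, t2 = 2021,
                       voxel_size = 0.05, slice_thickness = 0.25,
                       n_sections = 4500L, soil_height = 0.10,
                       volume_convention = "literal", form_factor = 0.5,
                       points_per_tree = 200L, crown_point_fraction = 0.7,
                       noise_sd = 0.01, ground_points = 4000L,
                       extinction_k = 0.5, light_days = 31L,
                       light_plot_fraction = 0.5,
                       out_dir = NULL) {
  cfg <- list(seed = as.integer(seed), diversity_effect = diversity_effect,
              stratification = stratification,
              mortality_prob = mortality_prob, t1 = t1, t2 = t2,
              voxel_size = voxel_size, slice_thickness = slice_thickness,
              n_sections = as.integer(n_sections), soil_height = soil_height,
              volume_convention = volume_convention,
              form_factor = form_factor,
              points_per_tree = as.integer(points_per_tree),
              crown_point_fraction = crown_point_fraction,
              noise_sd = noise_sd, ground_points = as.integer(ground_points),
              extinction_k = extinction_k, light_days = as.integer(light_days),
              light_plot_fraction = light_plot_fraction,
              out_dir = out_dir)
  validate_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

validate_config <- function(cfg) {
  stopifnot(cfg$diversity_effect >= -1,
            cfg$mortality_prob >= 0, cfg$mortality_prob <= 1,
            cfg$stratification >= 0, cfg$stratification <= 1,
            cfg$t2 > cfg$t1, cfg$voxel_size > 0, cfg$slice_thickness > 0,
            cfg$n_sections >= 1, cfg$soil_height >= 0,
            cfg$volume_convention %in% c("literal", "cylinder-quarter"),
            cfg$form_factor > 0, cfg$form_factor <= 1,
            cfg$points_per_tree >= 10, cfg$extinction_k >= 0,
            cfg$light_plot_fraction >= 0, cfg$light_plot_fraction <= 1)
  invisible(cfg)
}

#' Read or write a run configuration as YAML
#'
#' The configuration round-trips losslessly; the seed is stored explicitly.
#'
#' @param cfg a [run_config()].
#' @param path YAML file path.
#' @return `read_config()` a [run_config()]; `write_config()` the path,
#'   invisibly.
#' @export
write_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$out_dir <- x$out_dir %||% ""
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (identical(x$out_dir, "")) x$out_dir <- NULL
  do.call(run_config, x)
}

## tiny FNV-1a hash of the serialized config (scientific parameters only;
## the output location does not change what was computed), for table headers
config_hash <- function(cfg) {
  x <- unclass(cfg)
  x$out_dir <- NULL
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) {
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b)   # xor the low byte
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

write_stage_csv <- function(df, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# standweave %s config %s seed %d",
                     as.character(utils::packageVersion("standweave")),
                     config_hash(cfg), cfg$seed), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
}

#' Run the full synthetic experiment pipeline
#'
#' Generates a complete two-block diversity experiment and takes it through
#' every stage: design and planting, growth and mortality to the second
#' census, a central-scanner point cloud and SSCI per plot, annual wood
#' productivity on the 64 center trees, whole-plot mortality, ground-light
#' series for the instrumented half of the plots, additive partitioning of
#' overyielding and delta-SSCI for every mixture, and community-weighted
#' mean and functional dispersion of shade tolerance. The run is
#' deterministic under its seed; identical configurations give identical
#' tables.
#'
#' Monoculture reference yields per species are the mean center-tree AWP of
#' the species' two monoculture plots; monoculture reference SSCI values
#' are whole-plot means. Effect columns are `NA` for monocultures.
#'
#' @param config a [run_config()].
#' @param pool the [species_pool()]; defaults to the standard synthetic
#'   pool.
#' @param progress emit a short message per stage.
#' @return An object of class `"stand_experiment"`: `results` (one row per
#'   plot: richness, association, SSCI components, AWP, mortality, NBE, CE,
#'   SE, delta_ssci, CWM, FD, light mean), `design`, `config`, `mono_awp`,
#'   `mono_ssci`, and `timings` (seconds per stage).
#' @examples
#' \donttest{
#' ex <- run_pipeline(run_config(seed = 1, n_sections = 360,
#'                               points_per_tree = 40, ground_points = 500))
#' head(ex$results)
#' }
#' @export
run_pipeline <- function(config = run_config(), pool = species_pool(),
                         progress = FALSE) {
  validate_config(config)
  set.seed(config$seed)
  t0 <- proc.time()[3]
  say <- function(...) if (progress) message(...)
  timings <- c()
  tick <- function(stage) {
    timings[stage] <<- proc.time()[3] - t0
    t0 <<- proc.time()[3]
  }

  design <- generate_design(pool, seed = config$seed)
  plots <- design$plots
  n_plot <- nrow(plots)
  tick("design")
  say("design: ", n_plot, " plots")

  light_n <- round(config$light_plot_fraction * n_plot)
  light_ids <- sort(sample.int(n_plot, light_n))

  sp <- scan_params(points_per_tree = config$points_per_tree,
                    crown_point_fraction = config$crown_point_fraction,
                    stratification = config$stratification,
                    noise_sd = config$noise_sd,
                    ground_points = config$ground_points)
  lp <- light_params(extinction_k = config$extinction_k,
                     days = config$light_days)

  censuses <- vector("list", n_plot)
  ssci_vals <- matrix(NA_real_, n_plot, 4,
                      dimnames = list(NULL, c("SSCI", "ENL", "MeanFrac",
                                              "n_valid_sections")))
  awp <- numeric(n_plot)
  per_species_awp <- vector("list", n_plot)
  mort <- numeric(n_plot)
  light_mean <- rep(NA_real_, n_plot)

  for (i in seq_len(n_plot)) {
    comp <- composition_species(plots$composition[i])[[1]]
    trees <- layout_plot(comp, plot_id = plots$plot_id[i])
    census <- simulate_growth(trees, pool,
                              diversity_effect = config$diversity_effect,
                              mortality_prob = config$mortality_prob)
    censuses[[i]] <- census
    cloud <- simulate_scan(census, pool, sp)
    s <- compute_ssci(cloud, voxel_size = config$voxel_size,
                      slice_thickness = config$slice_thickness,
                      n_sections = config$n_sections,
                      soil_height = config$soil_height)
    ssci_vals[i, ] <- c(s$SSCI, s$ENL, s$MeanFrac, s$n_valid_sections)
    prod <- annual_wood_productivity(select_center_trees(census),
                                     t1 = config$t1, t2 = config$t2,
                                     form_factor = config$form_factor,
                                     convention = config$volume_convention)
    awp[i] <- prod$AWP
    per_species_awp[[i]] <- prod$per_species_awp
    mort[i] <- mortality_rate(census)
    if (i %in% light_ids) {
      series <- simulate_light(census, pool, lp)
      light_mean[i] <- light_interception_proxy(series)$mean_intensity
    }
  }
  tick("plots")
  say("plots: scanned and measured ", n_plot)

  ## monoculture reference means per species
  mono <- plots$richness == 1L
  mono_sp <- plots$composition[mono]
  mono_awp <- tapply(awp[mono], mono_sp, mean)
  mono_ssci <- tapply(ssci_vals[mono, "SSCI"], mono_sp, mean)

  nbe <- ce <- se <- dssci <- rep(NA_real_, n_plot)
  cwm_v <- fd_v <- rep(NA_real_, n_plot)
  for (i in seq_len(n_plot)) {
    comp <- composition_species(plots$composition[i])[[1]]
    census <- censuses[[i]]
    counts <- table(factor(census$species_id[census$alive], levels = comp))
    counts <- stats::setNames(as.numeric(counts), comp)
    tol <- pool$shade_tolerance[match(comp, pool$species_id)]
    if (sum(counts) > 0) {
      cwm_v[i] <- cwm(tol, counts)
      fd_v[i] <- fdis(tol, counts)
    }
    if (plots$richness[i] > 1L) {
      y_obs <- stats::setNames(rep(0, length(comp)), comp)
      obs <- per_species_awp[[i]]
      y_obs[names(obs)] <- obs
      m <- mono_awp[comp]
      if (!anyNA(m) && all(m > 0)) {
        part <- additive_partitioning(y_obs, m)
        nbe[i] <- part$NBE; ce[i] <- part$CE; se[i] <- part$SE
      }
      if (sum(counts) > 0 && !anyNA(mono_ssci[comp])) {
        dssci[i] <- delta_ssci(ssci_vals[i, "SSCI"], mono_ssci[comp],
                               counts / sum(counts))$delta
      }
    }
  }
  tick("effects")

  results <- data.frame(plots,
                        SSCI = ssci_vals[, "SSCI"], ENL = ssci_vals[, "ENL"],
                        MeanFrac = ssci_vals[, "MeanFrac"],
                        n_valid_sections = ssci_vals[, "n_valid_sections"],
                        AWP = awp, mortality = mort,
                        NBE = nbe, CE = ce, SE = se, delta_ssci = dssci,
                        CWM = cwm_v, FD = fd_v, light_mean = light_mean,
                        stringsAsFactors = FALSE)
  row.names(results) <- NULL

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_stage_csv(plots, file.path(config$out_dir, "design.csv"), config)
    census_all <- do.call(rbind, censuses)
    write_stage_csv(census_all, file.path(config$out_dir, "census.csv"),
                    config)
    write_stage_csv(results, file.path(config$out_dir, "results.csv"),
                    config)
    write_config(config, file.path(config$out_dir, "config.yaml"))
    say("artifacts written to ", config$out_dir)
  }
  tick("output")

  structure(list(results = results, design = design, config = config,
                 mono_awp = mono_awp, mono_ssci = mono_ssci,
                 timings = timings),
            class = "stand_experiment")
}

#' @export
print.stand_experiment <- function(x, ...) {
  r <- x$results
  cat("Synthetic stand experiment (seed ", x$config$seed, "): ",
      nrow(r), " plots\n", sep = "")
  agg <- stats::aggregate(cbind(SSCI, AWP) ~ richness, r, mean)
  cat("  mean SSCI / AWP by richness:\n")
  print(agg, row.names = FALSE)
  invisible(x)
}

#' Summarize an experiment run
#'
#' Produces the standard descriptive summary of a results table: group
#' means by richness level and by mycorrhizal association, Hedges' g effect
#' sizes of richness on SSCI and AWP (2 vs 1, 4 vs 1, 4 vs 2 species), and
#' the ordinary-least-squares slope of NBE on delta-SSCI across mixtures.
#' No inferential p-values are emitted.
#'
#' @param x a `"stand_experiment"` or its `results` data.frame.
#' @return An object of class `"stand_summary"`: `richness_means`,
#'   `association_means`, `effect_sizes` (data.frame `response`,
#'   `comparison`, `g`), `nbe_dssci_slope`, `n_plots`.
#' @export
report_summary <- function(x) {
  r <- if (inherits(x, "stand_experiment")) x$results else x
  if (nrow(r) < 2L) stop("need at least 2 plots to summarize")
  num <- intersect(c("SSCI", "ENL", "MeanFrac", "AWP", "mortality", "NBE",
                     "CE", "SE", "delta_ssci", "CWM", "FD", "light_mean"),
                   names(r))
  gmean <- function(key) {
    out <- stats::aggregate(r[num], by = r[key], FUN = mean, na.rm = TRUE)
    out
  }
  levels_pairs <- list(c(2, 1), c(4, 1), c(4, 2))
  es <- do.call(rbind, lapply(c("SSCI", "AWP"), function(resp) {
    do.call(rbind, lapply(levels_pairs, function(pr) {
      g <- tryCatch(hedges_g(r[[resp]][r$richness == pr[1]],
                             r[[resp]][r$richness == pr[2]])$g,
                    error = function(e) NA_real_)
      data.frame(response = resp,
                 comparison = sprintf("%dsp_vs_%dsp", pr[1], pr[2]), g = g,
                 stringsAsFactors = FALSE)
    }))
  }))
  mix <- r[!is.na(r$NBE) & !is.na(r$delta_ssci), , drop = FALSE]
  slope <- if (nrow(mix) >= 3L)
    unname(stats::coef(stats::lm(NBE ~ delta_ssci, data = mix))[2L])
  else NA_real_
  structure(list(richness_means = gmean("richness"),
                 association_means = gmean("mycorrhizal_assoc"),
                 effect_sizes = es, nbe_dssci_slope = slope,
                 n_plots = nrow(r)),
            class = "stand_summary")
}

#' @export
print.stand_summary <- function(x, digits = 4, ...) {
  cat("Summary over", x$n_plots, "plots\n\nGroup means by richness:\n")
  print(format(x$richness_means, digits = digits), row.names = FALSE)
  cat("\nGroup means by mycorrhizal association:\n")
  print(format(x$association_means, digits = digits), row.names = FALSE)
  cat("\nHedges' g of richness contrasts:\n")
  print(format(x$effect_sizes, digits = digits), row.names = FALSE)
  cat(sprintf("\nOLS slope of NBE on delta-SSCI: %.5g\n", x$nbe_dssci_slope))
  invisible(x)
}
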