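#' Generate the experimental design of a two-block tree diversity experiment
#'
#' Builds the full plot list of a MyDiv-style design crossing tree species
#' richness (1, 2, 4) with mycorrhizal association (AM only, EM only,
#' AM+EM), from a pool of 5 AM and 5 EM species:
#'
#' * 20 monocultures — every species twice, once per block;
#' * 30 two-species mixtures, all with distinct composition — all 10 AM
#'   pairs, all 10 EM pairs, and 10 seeded-random AM-by-EM pairs;
#' * 30 four-species mixtures — within AM (and EM), every 4-subset of the 5
#'   species twice (once per block); plus 10 distinct seeded-random AM+EM
#'   compositions of 2 AM + 2 EM species.
#'
#' This yields 80 plots: 30 AM-only, 30 EM-only and 20 AM+EM, each plot an
#' 11 m by 11 m square planted with 140 trees (see [layout_plot()]).
#' Replicated compositions are split across the two blocks; unreplicated
#' plots are assigned to blocks at random under the balance constraint of 40
#' plots per block.
#'
#' @param pool a [species_pool()] with exactly 5 AM and 5 EM species.
#' @param seed integer seed controlling the random composition draws and the
#'   block assignment.
#' @return An object of class `"stand_design"`: a list with `plots` (a
#'   data.frame with `plot_id`, `block`, `richness`, `mycorrhizal_assoc` and
#'   a `composition` string of `+`-separated species ids), the `pool`, and
#'   the `seed`.
#' @examples
#' d <- generate_design(species_pool(), seed = 1)
#' table(d$plots$richness)
#' @export
generate_design <- function(pool = species_pool(), seed = 1L) {
  validate_pool(pool)
  am <- pool$species_id[pool$mycorrhizal_type == "AM"]
  em <- pool$species_id[pool$mycorrhizal_type == "EM"]
  if (length(am) != 5L || length(em) != 5L)
    stop("invalid pool: need exactly 5 AM and 5 EM species (got ",
         length(am), " AM, ", length(em), " EM)")
  set.seed(as.integer(seed))

  paste_comp <- function(m) apply(m, 2, function(s) paste(sort(s), collapse = "+"))

  rows <- list()
  add <- function(richness, assoc, comp, block) {
    rows[[length(rows) + 1L]] <<- data.frame(
      block = block, richness = richness, mycorrhizal_assoc = assoc,
      composition = comp, stringsAsFactors = FALSE)
  }

  ## monocultures: each species twice, one replicate per block
  for (sp in am) for (b in 1:2) add(1L, "AM", sp, b)
  for (sp in em) for (b in 1:2) add(1L, "EM", sp, b)

  ## two-species mixtures: all within-type pairs + 10 random cross-type pairs
  am_pairs <- paste_comp(utils::combn(am, 2))
  em_pairs <- paste_comp(utils::combn(em, 2))
  cross <- expand.grid(a = am, e = em, stringsAsFactors = FALSE)
  cross_pairs <- paste_comp(t(as.matrix(cross[sample.int(nrow(cross), 10L), ])))
  two_blocks <- sample(rep(1:2, length.out = 30L))
  comps2 <- c(am_pairs, em_pairs, cross_pairs)
  assoc2 <- rep(c("AM", "EM", "AM+EM"), each = 10L)
  for (i in seq_along(comps2)) add(2L, assoc2[i], comps2[i], two_blocks[i])

  ## four-species mixtures: within-type 4-subsets twice; 10 AM+EM combos
  am_quads <- paste_comp(utils::combn(am, 4))
  em_quads <- paste_comp(utils::combn(em, 4))
  for (q in am_quads) for (b in 1:2) add(4L, "AM", q, b)
  for (q in em_quads) for (b in 1:2) add(4L, "EM", q, b)
  am_duos <- utils::combn(am, 2)
  em_duos <- utils::combn(em, 2)
  mixed <- expand.grid(i = seq_len(ncol(am_duos)), j = seq_len(ncol(em_duos)))
  pick <- mixed[sample.int(nrow(mixed), 10L), ]
  mixed_quads <- mapply(function(i, j)
    paste(sort(c(am_duos[, i], em_duos[, j])), collapse = "+"),
    pick$i, pick$j)
  mq_blocks <- sample(rep(1:2, length.out = 10L))
  for (i in seq_along(mixed_quads)) add(4L, "AM+EM", mixed_quads[i], mq_blocks[i])

  plots <- do.call(rbind, rows)
  plots$plot_id <- sprintf("P%02d", seq_len(nrow(plots)))
  plots <- plots[c("plot_id", "block", "richness", "mycorrhizal_assoc",
                   "composition")]
  design <- structure(list(plots = plots, pool = pool, seed = as.integer(seed)),
                      class = "stand_design")
  validate_design(design)
  design
}

#' Split a composition string into species ids
#'
#' @param composition character vector of `+`-separated species ids as
#'   stored in a design's `plots$composition`.
#' @return A list of character vectors.
#' @export
composition_species <- function(composition) strsplit(composition, "+", fixed = TRUE)

validate_design <- function(design) {
  p <- design$plots
  stopifnot(nrow(p) == 80L)
  if (sum(p$richness == 1L) != 20L || sum(p$richness == 2L) != 30L ||
      sum(p$richness == 4L) != 30L)
    stop("richness counts must be 20/30/30")
  tab <- table(p$mycorrhizal_assoc)
  if (tab[["AM"]] != 30L || tab[["EM"]] != 30L || tab[["AM+EM"]] != 20L)
    stop("association counts must be 30 AM / 30 EM / 20 AM+EM")
  if (anyDuplicated(p$composition[p$richness == 2L]))
    stop("two-species compositions must be pairwise distinct")
  mixed4 <- p$composition[p$richness == 4L & p$mycorrhizal_assoc == "AM+EM"]
  if (length(unique(mixed4)) != 10L)
    stop("need exactly 10 distinct AM+EM four-species compositions")
  sizes <- lengths(composition_species(p$composition))
  if (!all(sizes == p$richness)) stop("composition size must equal richness")
  if (!all(table(p$block) == 40L)) stop("blocks must hold 40 plots each")
  invisible(design)
}

#' @export
print.stand_design <- function(x, ...) {
  p <- x$plots
  cat(sprintf("Tree diversity experiment design: %d plots in %d blocks (seed %d)\n",
              nrow(p), length(unique(p$block)), x$seed))
  print(table(richness = p$richness, association = p$mycorrhizal_assoc))
  invisible(x)
}

#' Planting grid and plot geometry
#'
#' Plots are 11 m by 11 m squares. The only regular 1 m layout holding 140
#' trees in such a plot with an 8 m by 8 m 64-tree core is a 12 x 12 grid of
#' positions at 1 m spacing (coordinates 0..11 m on both axes) with the four
#' corner positions removed; this is what [layout_plot()] uses.
#'
#' @return `plot_bounds()`: numeric vector `c(xmin, xmax, ymin, ymax)`.
#' @export
plot_bounds <- function() c(xmin = 0, xmax = 11, ymin = 0, ymax = 11)

planting_grid <- function() {
  g <- expand.grid(x = 0:11, y = 0:11)
  corner <- (g$x %in% c(0, 11)) & (g$y %in% c(0, 11))
  g[!corner, , drop = FALSE]
}

#' Lay out the planting of one plot
#'
#' Places 140 trees on the 12 x 12 grid at 1 m spacing minus the four
#' corners and assigns species by a seeded random permutation with exact
#' per-species counts `140 / S` (140, 70 or 35 individuals per species for
#' richness 1, 2 and 4).
#'
#' @param composition character vector of species ids in the plot, or a
#'   single `+`-separated composition string.
#' @param plot_id plot identifier carried into the output.
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @return A data.frame with one row per planted tree: `tree_id`, `plot_id`,
#'   `species_id`, `x`, `y`.
#' @examples
#' trees <- layout_plot(c("AM1", "AM2"), plot_id = "P01", seed = 1)
#' table(trees$species_id)
#' @export
layout_plot <- function(composition, plot_id = "P01", seed = NULL) {
  if (length(composition) == 1L && grepl("+", composition, fixed = TRUE))
    composition <- composition_species(composition)[[1L]]
  s <- length(composition)
  g <- planting_grid()
  n <- nrow(g)                          # 140
  if (n %% s != 0L)
    stop("richness ", s, " does not divide ", n, " planting positions")
  if (!is.null(seed)) set.seed(as.integer(seed))
  species <- sample(rep(composition, each = n %/% s))
  data.frame(tree_id = sprintf("%s-T%03d", plot_id, seq_len(n)),
             plot_id = plot_id, species_id = species,
             x = g$x, y = g$y, stringsAsFactors = FALSE)
}
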