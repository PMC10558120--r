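# standweave

Quantitative tools for the structure–productivity side of forest
biodiversity experiments. standweave computes, from terrestrial laser
scanning (TLS) point clouds and tree census tables, the quantities used to
ask whether mixing tree species makes young stands structurally more
complex and more productive:

* **SSCI**, the stand structural complexity index
  `SSCI = MeanFrac^ln(ENL)`, where **ENL** (effective number of layers) is
  the inverse Simpson diversity `1 / Σ p_i²` of filled-voxel proportions
  across 25 cm height slices of a 5 cm occupancy grid, and **MeanFrac** is
  the mean perimeter–area fractal dimension `2·ln(0.25·P) / ln(A)`
  (clamped to [1, 2]) of 4500 azimuthal cross-section polygons around the
  scanner;
* **AWP**, annual wood productivity: the summed stem-volume increment
  `Σ (V₂ − V₁)/(t₂ − t₁)` over living trees, with `V = π D² H f` and a
  form factor `f = 0.5`, computed on the 64 trees of the central
  8 m × 8 m window of each plot;
* **additive partitioning** of the net biodiversity effect
  `NBE = CE + SE` into complementarity (`N·mean(ΔRY)·mean(M)`) and
  selection (`N·cov_pop(ΔRY, M)`) effects;
* **ΔSSCI**, the net biodiversity effect on structure:
  `SSCI_obs − Σ p_i·SSCĪ_i,mono` with mortality-corrected abundances;
* community-weighted mean and single-trait functional dispersion of shade
  tolerance, Hedges' g effect sizes, and a ground-light interception
  proxy from hourly sensor series.

Because TLS campaigns of this kind are rarely public, the package also
ships a fully seeded synthetic-data generator that emulates a two-block
tree diversity experiment (10 species, 5 AM + 5 EM mycorrhizal types,
richness 1/2/4, 80 plots of 11 m × 11 m planted with 140 trees at 1 m
spacing) including growth with an injectable diversity effect, mortality,
central-scanner point clouds with shade-tolerance-driven canopy
stratification, and diel light series. Every analysis stage is therefore
testable against known ground truth. It is aimed at forest ecologists
working on biodiversity–ecosystem functioning relationships and at anyone
needing a reference implementation of the SSCI chain.

## Worked example

Simulate one four-species plot, scan it, and push it through the indices:

```r
library(standweave)

trees  <- layout_plot(c("AM1", "AM3", "EM2", "EM5"), plot_id = "P42", seed = 7)
census <- simulate_growth(trees, species_pool(), diversity_effect = 0.08,
                          mortality_prob = 0.1, seed = 7)
cloud  <- simulate_scan(census, species_pool(), scan_params(), seed = 7)
cloud
#> Point cloud [P42] : 38312 points
#>   x: [-1.38, 12.59]  y: [-1.62, 12.67]  z: [-0.03, 11.33] m
#>   scanner at (5.50, 5.50, 1.30)

compute_ssci(cloud, n_sections = 360)
#> SSCI [P42] = 9.7972  (ENL = 27.272, MeanFrac = 1.9944, 360/360 valid sections)

annual_wood_productivity(select_center_trees(census))
#> AWP = 0.49489 m^3/yr over 60 living trees (2015-2021)
#>   per species:
#>      AM1      AM3      EM2      EM5
#> 0.150689 0.092374 0.135657 0.116173

mortality_rate(census)
#> [1] 0.07142857
```

The SSCI line reads: the plot's filled voxels spread over an effective
27.3 vertical layers (a tall, well-stratified canopy), its cross-section
polygons are highly convoluted (MeanFrac near the ceiling of 2), and the
combined index is 9.80. The plot produced 0.495 m³ of wood per year over
its 60 surviving center trees, and 7.1% of its 140 planted trees died.

Overyielding of a two-species mixture against its monoculture references:

```r
additive_partitioning(c(AM1 = 0.11, EM2 = 0.09), c(AM1 = 0.32, EM2 = 0.30))
#> Net biodiversity effect over 2 species:
#>   NBE = -0.11  (CE = -0.110438, SE = 0.0004375)
```

Here the mixture underyields (NBE < 0), almost entirely through a
negative complementarity effect; `NBE = CE + SE` holds exactly.

A whole 80-plot experiment, end to end:

```r
ex <- run_pipeline(run_config(seed = 1, n_sections = 360))
report_summary(ex)   # group means, Hedges' g, NBE ~ delta-SSCI slope
```

A thin command-line wrapper for the same operations lives in
`inst/scripts/standweave.R` (`run`, `ssci`, `report` subcommands).

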