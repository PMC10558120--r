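---
title: "Stand structural complexity, productivity and biodiversity effects: methods"
author: "standweave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stand structural complexity, productivity and biodiversity effects: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(standweave)
```

## Scope

standweave implements the computational chain that links tree species
richness to the three-dimensional structural complexity of planted forest
stands and to their wood productivity: single-scan point-cloud processing
(clipping, soil removal, voxelization), the stand structural complexity
index (SSCI) with its two components, annual wood productivity (AWP) from
two-census stem measurements, additive partitioning of overyielding,
the net biodiversity effect on structure (delta-SSCI), community trait
metrics (CWM and FDis of shade tolerance) and a ground-light interception
proxy. Because real scan campaigns of this kind are rarely public, the
package ships a synthetic-data generator that emulates a two-block tree
diversity experiment end to end, with controllable ground truth, so every
stage is testable offline.

Statistical modelling of field data (mixed-effect models, structural
equation models, Tukey comparisons) is deliberately out of scope; the
summary layer reports group means, Hedges' g effect sizes and an ordinary
least-squares slope only.

## The structural complexity index

A plot is scanned from its centre at 1.3 m height. After removing the
soil-surface layer (default: everything within 0.10 m of the lowest
point), the cloud enters two independent computations.

**Effective number of layers (ENL).** The cloud is converted to a 5 cm
occupancy voxel grid anchored at its minimum corner (half-open voxel
intervals; a voxel is filled if it holds at least one point). Filled
voxels are cut into horizontal layers of 25 cm, counted from the lowest
filled voxel, and ENL is the inverse Simpson diversity of the layer
proportions $p_i$:

$$\mathrm{ENL} = \frac{1}{\sum_i p_i^2}.$$

ENL is 1 when all material sits in one layer and equals the layer count
under an even spread; it captures vertical stratification and grows with
stand height. Because occupancy ignores point multiplicity, ENL is
invariant to point-density changes that do not move voxels.

**Mean fractal dimension (MeanFrac).** Points are binned into 4500 equal
azimuth sectors around the scanner. Within a sector, each point maps to
$(d, z)$ — horizontal distance and height relative to the scanner — and
the points, sorted by elevation angle, form a polygon closed through the
scanner position. For each polygon with perimeter $P$ and area $A$ we use
a perimeter–area fractal dimension in the FRAGSTATS tradition,

$$\mathrm{FRAC} = \frac{2\,\ln(0.25\,P)}{\ln A},$$

clamped to $[1, 2]$; squares attain the minimum at any scale. Sections
with fewer than 3 points are flagged degenerate, and sections with
$|A - 1\,\mathrm{m}^2| \le 10^{-6}$ are excluded because the denominator
vanishes. MeanFrac is the arithmetic mean over the remaining sections,
and

$$\mathrm{SSCI} = \mathrm{MeanFrac}^{\,\ln(\mathrm{ENL})},$$

so SSCI equals 1 whenever either component is at its floor.

Numerical choices worth stating: the polygon closure through the scanner
and the exclusion of sub-3-point sections make every section a simple,
well-defined polygon; the layer datum at the lowest filled voxel makes
ENL invariant to a vertical shift of the whole cloud; the voxel-grid
anchor at the cloud minimum makes occupancy deterministic without a
global georeference.

**Section density and cloud size.** The fractal component is only
meaningful when sectors hold enough points to trace the outline of the
vegetation; field scans provide thousands of points per sector at 4500
sections. The synthetic clouds used throughout the tests and the
acceptance script are two to three orders of magnitude sparser (a few
tens of thousands of points), so whole-experiment runs use 360 sectors
(roughly 100 points per sector), which restores an adequate
points-per-sector budget while the method default remains 4500. A single
default-parameter SSCI computation is still exercised to confirm the
4500-section configuration.

## Productivity and mortality

Stem volume is $V = \pi D^2 H f$ with a form factor $f = 0.5$ typical of
young broadleaves; `stem_volume()` also offers a `cylinder-quarter`
convention ($\pi D^2 H f / 4$) because the literal formula is a constant
factor 4 above the geometric cylinder — the choice cancels from every
relative quantity (overyielding ratios, effect sizes, slopes on
standardized data). AWP sums $(V_2 - V_1)/(t_2 - t_1)$ over trees alive
at the second census. Growth analyses use the 64 trees of the central
8 m × 8 m window to avoid edge effects, while mortality is the dead
fraction of all 140 planted trees; both scopes are explicit function
arguments.

## Biodiversity effects

Overyielding is partitioned in the classical additive way: with expected
relative yields $RY_{E,i}$ (the planted proportions), deviations
$\Delta RY_i = Y_{O,i}/M_i - RY_{E,i}$, complementarity
$CE = N\,\overline{\Delta RY}\,\overline{M}$ and selection
$SE = N\,\mathrm{cov_{pop}}(\Delta RY, M)$, so that $NBE = CE + SE$
exactly. The population (divide-by-$N$) covariance follows the original
partitioning method; a sample covariance would rescale SE by
$N/(N-1)$ and break the identity.

The structural analogue compares a mixture's observed SSCI with the
abundance-weighted mean of its species' monoculture SSCI values, using
2021 relative abundances of living trees (mortality-corrected):
$\Delta\mathrm{SSCI} = \mathrm{SSCI_{obs}} - \sum_i p_i\,
\overline{\mathrm{SSCI}}_{i,\mathrm{mono}}$. Monoculture reference means
use the same response scope as the quantity they predict: center-tree
AWP for the yield partition, whole-plot SSCI for delta-SSCI.

Hedges' g is the pooled-SD standardized mean difference with the
small-sample correction $J = 1 - 3/(4(n_1+n_2) - 9)$ (toggleable). The
summary layer computes it from observed group values at each richness
level, not from model predictions, since model fitting is out of scope.

## Community metrics

CWM is the abundance-weighted trait mean. FDis is implemented in its
single-trait specialization — the abundance-weighted mean absolute
deviation from the abundance-weighted centroid — which is what the
general Gower-distance dispersion reduces to in one dimension;
multi-trait machinery is a non-goal. Abundances are living-tree counts
at the second census. The light proxy averages strictly positive hourly
readings per sensor over a month and then across the four sensors;
nighttime zeros never enter.

## The synthetic generator

The generator emulates the design of a two-block mycorrhizal × richness
experiment: 10 species (5 AM, 5 EM), 80 plots of 11 m × 11 m, richness
levels 1/2/4 with 20/30/30 plots, associations AM/EM/AM+EM with 30/30/20
plots, every monoculture and within-type four-species subset replicated
once per block, all within-type pairs present, and seeded-random
cross-type pairs and 2+2 four-species compositions (the realized
compositions of the field experiment are not public). Each plot plants
140 trees on a 12 × 12 grid at 1 m spacing minus the four corners — the
only regular 1 m layout that reconciles 140 trees, an 11 m × 11 m plot
and a 64-tree 8 m × 8 m core. Species are assigned by seeded permutation
in exact proportions (140/70/35 per species).

Growth draws mean-preserving lognormal first-census sizes and
increments, with expected increments scaled by
$1 + \delta \log_2 S$; the injectable `diversity_effect` $\delta$ is the
overyielding ground truth. Mortality is i.i.d. per tree (default 10%
over the six-year interval, a plausible figure for a young plantation);
dead trees keep their planting size and contribute no scan points —
death timing is not modelled. All ten species share the same expected
allometry by default, deliberately: under the null generator
(`diversity_effect = 0`, `stratification = 0`) no systematic richness
signal exists, so any recovered effect is attributable to the injected
parameters rather than to species identity.

The scan model samples, per living tree, stem points on a tapered cone
and crown points in an ellipsoid whose vertical placement reflects shade
tolerance: at `stratification = 1`, crown centres range from 0.87·H
(least tolerant, light-demanding species stay high) down to 0.37·H
(most tolerant species persist low), which is the mechanism by which
mixing species of unlike tolerance creates multi-layered canopies. The
per-tree point count scales with $(H/6\,\mathrm{m})^2$ — larger trees
intercept more of the beam — which matters for MeanFrac, whose polygon
perimeters grow with return density. A thin soil-point layer is always
added so soil removal is exercised. No occlusion, beam divergence or
reflectance physics is modelled: the generator reproduces the geometry
the indices respond to, not a scanner.

The light model attenuates a half-sine diel curve (06:00–20:00) by
$\exp(-k L)$, where $L$ sums crown-overlap contributions of living trees
above each of four sensors and $k$ defaults to 0.5, a typical broadleaf
extinction coefficient; nighttime readings are exactly zero.

What passing tests on these data do show: the indices, filters and
effect statistics compute what they claim, recover injected signals with
the right sign, and collapse to noise under the null. What they do not
show: realistic magnitudes for any field system — absolute SSCI or AWP
levels depend on allometry, scan density and crown geometry choices that
stand in for real measurements.

## Problem sizes and determinism

Whole-experiment runs in the test-suite and acceptance script use
40-point-per-tree (tests) or 200-point-per-tree (acceptance) clouds, 360
sectors and the full 80-plot design; parameter-recovery checks average
20 replicate experiments for the effect case and 20 for the null. All
randomness flows from a single integer seed per run; two runs with equal
configuration are byte-identical, including persisted CSV artifacts
(whose headers carry a config hash that ignores the output path).

```{r example, eval = FALSE}
ex <- run_pipeline(run_config(seed = 1, n_sections = 360))
report_summary(ex)
```

## Known limitations

* The perimeter–area fractal dimension is applied to raw polygons; the
  source method's possible normalizations are not recoverable from the
  text it is cited in, so the raw-polygon choice is documented and the
  section count configurable.
* Scan realism is geometric only; occlusion in dense stands (which
  flattens observed ENL in the field) is absent, so synthetic ENL values
  run high.
* The additive partition requires strictly positive monoculture yields;
  plots whose reference species all died would be reported `NA` rather
  than extrapolated.
* Hedges' g on observed group values ignores the blocking and
  composition random effects a mixed model would absorb.
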