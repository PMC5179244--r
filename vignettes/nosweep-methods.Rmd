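---
title: "Quantifying spatial ecological structure with node overlap-segregation scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spatial ecological structure with node overlap-segregation scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nosweep)
```

## The statistic

A binary species-by-site matrix is a bipartite incidence: species are
linked to the sites they occupy. For two nodes of the same class --- two
species, or two sites --- with degrees $d_i$ and $d_j$ among $n$ nodes of
the opposite class, the observed number of shared neighbours $S_{ij}$ is
compared with its expectation under random placement of the two
neighbourhoods,

$$P_{ij} \;=\; \sum_{k=1}^{\min(d_i,d_j)}
  k\,\frac{\binom{n}{k}\binom{n-k}{d_j-k}\binom{n-d_j}{d_i-k}}
         {\binom{n}{d_j}\binom{n}{d_i}},$$

the mean of a hypergeometric law, which collapses algebraically to
$d_i d_j / n$ (the package evaluates the full sum in log-gamma space and
the test suite proves the two routes equal to $10^{-10}$ over an
exhaustive sweep). The pair score standardizes the deviation by the
largest deviation feasible in its direction:

$$\mathcal{N}_{ij} \;=\;
  \frac{(S_{ij}-P_{ij})/\min(d_i,d_j)}{\Omega_{ij}},
  \qquad
  \Omega_{ij} =
  \begin{cases}
    \dfrac{\min(d_i,d_j)-P_{ij}}{\min(d_i,d_j)} & S_{ij} > P_{ij},\\[2ex]
    \dfrac{P_{ij}-\max(0,\,d_i+d_j-n)}{\min(d_i,d_j)} & S_{ij} < P_{ij},
  \end{cases}$$

so that maximal sharing scores exactly $+1$ (one neighbourhood nested in
the other), minimal sharing exactly $-1$ (segregation), and $S = P$
scores 0. At matrix level, `nbar` is the mean of all pair scores (by
default row pairs and column pairs pooled), *modularity* is their
population standard deviation --- large when scores split into a $+1$-ish
within-block and a $-1$-ish between-block population --- and a one-sample
Z test, $Z = \bar{\mathcal{N}} / (\sigma/\sqrt{m})$ over the $m$ scorable
pairs, flags departure from 0, with $|Z| > 2$ read as significance at
about $p < 0.05$.

Three numerical choices deserve note.

* **Sign-dependent $\Omega$.** Standardizing both directions by the
  positive bound cannot reach $-1$; the bounded $[-1, 1]$ range requires
  the direction-matched denominators above. The package computes the
  ratio in the cancellation-safe form $(S-P)/(S_{\max}-P)$ (or
  $(S-P)/(P-S_{\min})$), so the endpoints are attained exactly in
  floating point, not merely approached.
* **Degenerate pairs.** The feasible range of $S$ collapses to a single
  point exactly when $\max(d_i, d_j) = n$ (if $d_i = n$ then
  $S = d_j$ is forced, and conversely); such pairs carry no information
  and are excluded from the mean and the SD rather than scored 0, which
  would dilute `nbar` arbitrarily. A matrix in which fewer than two
  pairs remain scorable is flagged non-computable.
* **Population SD.** Modularity uses the population (not sample)
  standard deviation, which guarantees the $[0, 1]$ range; the same SD
  is used in the Z test, and both choices are pinned by the two-block
  worked example in the test suite ($\bar{\mathcal{N}} = -2/15$,
  modularity $0.991$, $Z \approx -1.04$).

One property of the sign-dependent standardization is worth knowing when
interpreting values near zero: the *per-pair* null expectation is not
exactly zero but depends on fill. For two singleton species
($d_i = d_j = 1$) the null mean score is $2/n - 1$, close to $-1$; for
near-saturated pairs it approaches $+1$. In matrices of moderate
occupancy the two tails balance and random landscapes centre near 0 (the
test suite checks $|\overline{\text{nbar}}| < 0.1$ at cell occupancy
around 0.4), but very sparse matrices lean negative and very dense ones
positive. The bounded range --- an explicit design constraint --- is what
buys this trade-off.

## The moving window

Occurrence records (species, longitude, latitude in decimal degrees) are
analysed inside a 1-degree window of 10 x 10 cells, each 0.1 x 0.1
degrees, stepped across the landscape at 0.1-degree increments. Cells
bin records half-open, $[a, a + 0.1)$ on both axes, so a record exactly
on a cell's upper edge belongs to the next cell and no record is counted
twice; the anchor lattice snaps to the data bounding box's south-west
corner (both choices are conventions the data formats leave open; the
half-open rule and the snapped origin make results deterministic).
Within-cell multiplicity is irrelevant for presence-absence, so records
deduplicate to (species, cell) pairs before matrix building. Empty rows
and columns are pruned, and a window is retained only if at least 5
species and 5 occupied cells remain --- small matrices make the score
statistics unstable. Each retained window's `nbar`, Z and modularity are
georeferenced at the window centroid (anchor + 0.5 degrees), giving maps
at 0.1-degree resolution. Windows are computed independently, so results
are invariant to record order and evaluation order; coordinates are
plain geographic degrees with no projection, matching the grid's
definition in degrees.

Polygon maps (vegetation units, habitat masks, ecoregions, intact
areas) travel as GeoJSON. Containment uses an even-odd ray cast with two
explicit tie-breaks the analysis depends on: a point on a boundary
counts as inside, and when several polygons contain a point the first in
file order wins. Both situations occur systematically here ---
window centroids fall exactly on the shared edges of a rectangular
ecoregion tiling --- and generic containment routines leave them
unspecified.

## Synthetic landscapes

The generators produce datasets whose structure is known by
construction, so each pipeline stage can be validated end to end.

* **Nested**: one latent suitability field (the south-to-north
  latitudinal gradient, mirroring the broad climatic gradient of the
  study system); species $k$ occurs wherever suitability exceeds its
  threshold $t_k$, thresholds strictly ordered (default
  $t_k = (k-1)/n$). Because a cell's species set is determined by the
  largest suitability among its points, occupancy sets form *exact*
  subset chains at cell level, and every retained window scores
  `nbar` $= 1$, modularity $0$ --- for any seed. Optional bounded
  longitudinal ranges (`lon_ranges`, drawn by `sample_lon_ranges()`)
  add east-west species turnover: windows then differ in how much their
  resident ranges overlap, `nbar` varies smoothly across the landscape,
  and --- because the variation is carried by dense, cell-level
  deterministic range blocks rather than individual records --- it is
  robust to record subsampling.
* **Modular**: longitudinal blocks aligned to the 0.1-degree lattice,
  each populated only from its own disjoint species pool; no cell ever
  mixes pools, and windows straddling block boundaries show high
  modularity.
* **Segregated**: every cell owned by one species.
* **Random**: species and locations independent and uniform.

Disturbance (`disturb()`) combines two orthogonal channels, scaled by an
overall intensity: deletion of a fixed fraction of records (exactly
`round(n * f)`, so a 50% removal of 1,000 records leaves exactly 500)
and relocation of a fraction of survivors to uniform positions.
Deletion alone cannot reduce nestedness of a dense nested landscape
(subset chains survive thinning); relocation mixes species across cells
and destroys both nestedness and block structure. `disturb_gradient()`
applies the same model with intensity rising west to east in
longitudinal strips, relocating *within* each strip so that lightly
disturbed areas are not contaminated by heavily disturbed ones. In the
bundled study configuration, disturbed records relocated into intact
areas are dropped: disturbance does not deposit trees inside reserves,
and without that rule the intact-versus-disturbed contrast would partly
measure contamination rather than protection.

The potential-vegetation stand-in (`generate_pnv_map()`) tiles the
extent into latitudinal bands whose species pools form a subset chain
(richest band first), so projecting any set of plot locations onto it
(`pnv_project()`) yields perfectly nested matrices --- the structural
ceiling the actual data are compared against. Disjoint pools per band
are available to produce modular projections instead. Ecoregions are a
rectangular tiling (the divisor pair of the requested count closest to
the extent's aspect ratio), with a seeded random subset flagged intact.

What the generators deliberately do *not* emulate: real species
distribution processes (climate envelopes, dispersal, abundance
structure), coastlines and irregular polygon shapes, spatially
autocorrelated sampling effort, and taxonomic error. Passing tests
therefore show that the *method* behaves as specified on landscapes with
known structure --- boundary attainment, directional responses,
robustness regimes --- not that any particular empirical dataset will
show a given pattern.

## Downstream comparisons

`difference_map()` joins the actual and potential window sets on the
0.1-degree centroid lattice and reports per-centroid differences
(ACV $-$ PNV), keeping one-sided centroids with an explicit flag.
`ecoregion_aggregate()` averages window statistics per containing
ecoregion, unweighted: overlapping windows mean a region's windows are
not independent, but with no stated weighting rule the plain mean is the
transparent choice. `intact_contrast()` computes Welch's
unequal-variance t (Welch-Satterthwaite df, two-sided p) between
non-intact and intact windows for `nbar` and modularity; windows (not
plots) are the test unit, since the structure statistics exist only at
window level. `sensitivity_run()` removes a seeded random fraction of
records (default half, without replacement), reruns the sweep on the
same lattice, and regresses the half-data statistic on the full-data
statistic over windows retained in both runs (that direction --- degraded
data explained by complete data --- is the substantive question: how much
of the full-data signal survives). Fewer than 10 paired windows flags
low power; zero variance in the predictor flags the regression
degenerate rather than reporting a fabricated fit. Summary tables use
the six-number layout (min, quartiles, median, mean, max) with type-7
(linear-interpolation) quantiles, recorded in the output metadata.

## Problem sizes and reproducibility

The bundled study configuration (`pipeline_config()`) uses a 2 x 2
degree extent, 24 species, 12,000 plot locations (about 1.2e5 records),
a four-band potential-vegetation map, four ecoregions with one intact,
and disturbance `deletion = 0.3`, `relocation = 0.5`,
`intensity = 0.8` outside the intact region --- a landscape dense enough
that every one of the 121 window anchors is retained, while a full
pipeline run stays around half a minute. The sensitivity stage's dense
landscape uses 5 x 2 degrees, 24 species with staggered 1-3-degree
ranges and 30,000 plots (about 1.5e5 records). These sizes were chosen
as the smallest at which windows are saturated and the directional
contrasts are unambiguous.

Every stochastic step takes an explicit integer seed, routed through a
helper that restores the caller's RNG state; stage seeds derive from one
master seed, are written into file headers and the bundle manifest, and
identical configuration yields byte-identical outputs --- a property the
test suite asserts file by file.

## Known limitations

* Cells are degree-rectangles: no equal-area correction, so cell area
  shrinks with latitude exactly as in the grid definition this follows.
* The per-pair null mean is fill-dependent (see above); `nbar` values
  from matrices of very different occupancy are not exactly exchangeable
  near zero.
* "Modularity" here is the SD of pair scores, a heterogeneity measure;
  it identifies that distinct blocks exist, not which nodes form them
  (no community detection).
* The Z test treats pair scores as independent, which overlapping pairs
  within one matrix are not; it is a screening statistic, and its
  conventional $|Z| > 2$ reading should be taken as such.
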