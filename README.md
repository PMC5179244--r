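# nosweep

Spatial community ecology asks whether the species assemblages we
observe still carry the spatial structure that undisturbed ecological
processes build up — nestedness (poor assemblages as subsets of rich
ones), segregation (checkerboard non-overlap), and modularity (distinct
internally-similar blocks of species and sites). `nosweep` quantifies
that structure from plain point occurrence records and compares an
observed ("actual vegetation") landscape against a structural baseline
("potential natural vegetation") projected from an expert polygon map,
with intact areas as a naturalness reference. It is aimed at
macroecologists working with occurrence tables and vegetation maps, and
ships synthetic-landscape generators so the entire workflow is testable
without any external data.

## The statistic

For two species (or two sites) with degrees $d_i, d_j$ among $n$
opposite-class nodes of a binary presence–absence matrix, the observed
shared-neighbour count $S_{ij}$ is standardized against its
hypergeometric expectation $P_{ij} = d_i d_j / n$ (evaluated as the full
probabilistic sum):

$$\mathcal{N}_{ij} = \frac{S_{ij} - P_{ij}}{\min(d_i, d_j)\,\Omega_{ij}}$$

with $\Omega_{ij}$ the maximum feasible deviation in the observed
direction, so $\mathcal{N}_{ij} \in [-1, 1]$ exactly: $+1$ is perfect
nestedness, $-1$ complete segregation. Per matrix, **nbar** is the mean
over all row and column pairs, **modularity** the population SD of the
same scores, and a one-sample **Z** test flags departure from 0
($|Z| > 2 \approx p < 0.05$). The statistics are computed inside a
1°×1° moving window of 0.1° cells stepped at 0.1° across the landscape,
georeferenced at window centroids; windows with fewer than 5 species or
5 occupied cells after pruning are discarded.

## Worked example

```r
library(nosweep)

# two blocks: species 1-3 on sites 1-5, species 4-6 on sites 6-10
m <- rbind(cbind(matrix(1, 3, 5), matrix(0, 3, 5)),
           cbind(matrix(0, 3, 5), matrix(1, 3, 5)))
nos_structure(m)
#> Node overlap-segregation structure (both, 60 pairs)
#>   nbar = -0.1333  modularity = 0.9911  Z = -1.042
```

Within-block pairs share everything (+1), cross-block pairs nothing
(−1): near-zero mean overlap, but maximal heterogeneity — the modularity
signature. The same function drives the landscape sweep:

```r
ext <- c(8, 10, 44, 46)                                   # 2° x 2°
occ <- generate_landscape(ext, n_species = 24, n_points = 12000,
                          structure = "nested", seed = 42)
res <- nos_sweep(occ, origin = c(8, 44), extent = c(10, 46))
range(res$nbar)
#> [1] 1 1
```

A nested landscape scores exactly 1 in every one of the 121 retained
windows; disturbing it (`disturb()`) drives nbar down and modularity
up, which is what the downstream comparisons measure. Running the full
synthetic study (`analysis/01_simulate.R` … `04_sensitivity.R`) prints,
among other things:

```
Potential vegetation is the structural ceiling: mean nbar 1.000 (PNV)
  vs 0.612 (ACV); mean modularity 0.000 (PNV) vs 0.453 (ACV)
Intact-forest contrast (Welch, non-intact minus intact):
   statistic       t    df         p
1       nbar -13.329 75.47 1.599e-21
2 modularity   7.192 39.36 1.108e-08
(a) bundle ACV records:
  nbar       y = 0.874x + 0.134   R2 = 0.836
```

i.e. the potential baseline is more nested and less modular than the
disturbed actual landscape, intact windows beat disturbed ones in both
directions, and halving the records recovers the full-data nestedness
along a near-identity regression line.

## Analysis workflow

Numbered drivers under `analysis/` run the study end to end, writing
tables under `results/`:

1. `01_simulate.R` — synthetic bundle: occurrences, PNV map, habitat
   mask, ecoregions, intact areas, seed manifest.
2. `02_sweep.R` — mask filter, PNV projection, moving-window sweeps,
   descriptive summary table.
3. `03_compare.R` — ACV−PNV difference map, per-ecoregion means, Welch
   contrast of intact vs non-intact windows.
4. `04_sensitivity.R` — 50% record-removal regression on the bundle and
   on a dense range-turnover landscape.

Equivalently, `simulate_bundle()` + `run_pipeline()` perform the whole
workflow in one call each; identical configuration and seed give
byte-identical outputs.

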