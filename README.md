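# nestarid

Trait–environment analysis of avian egg shape and nest architecture on
equal-area grids.

## The scientific problem

Across a continent, which egg shapes and nest types occur where — and does
climate explain the pattern? Eggs in hot, arid, sparsely vegetated regions
face acute water loss and solar exposure; a rounder egg (lower surface area
per volume) and a roofed (domed) nest both buffer those stresses. The
package implements the full analysis chain for testing this idea with
assemblage-level comparative data, for macroecologists working with species
trait tables and gridded breeding occurrence records:

1. **Species level** — egg elongation `E = L/B` (length over breadth) per
   species, compared across nest types (cup, dome, cavity) with one-way
   ANOVA, Tukey–Kramer pairwise comparisons, and a taxonomic-family
   random-intercept REML model as a shared-ancestry robustness check.
2. **Assemblages** — breeding occurrences are projected to an Albers
   equal-area conic grid (100 km cells by default; standard Australian
   Albers parameters); each cell's assemblage is the set of species breeding
   there, summarised as mean elongation per nest type and the proportion of
   dome-nesting species. Cells are screened by a bias-corrected Chao2
   sampling-completeness index and minimum per-nest-type richness.
3. **Environment** — vapour pressure deficit
   `VPD = e_sat(T_max) − VP`, with
   `e_sat(T) = 0.61375 · exp(17.502 T / (240.97 + T))` kPa, computed daily
   and then averaged; leaf area index (LAI) as the canopy covariate; both
   aggregated to the analysis grid by exact area-weighted means.
4. **Spatial models** — each assemblage response is regressed on
   `VPD * LAI` (main effects plus interaction) by OLS; residual spatial
   autocorrelation is diagnosed with Moran's I correlograms over 20 distance
   bands; where detected, a simultaneous autoregressive (SAR) **spatial
   error** model

   `y = Xβ + u,  u = λWu + ε,  ε ~ N(0, σ²I)`

   is fitted by profile maximum likelihood, with the log-Jacobian
   `log|I − λW| = Σ log(1 − λω_i)` from the eigenvalues of the spatial
   weights `W` (distance-band neighbours within 200 km, binary or
   row-standardised), and summarised with a Nagelkerke-style pseudo-R².
5. **Synthetic worlds** — a seeded generator produces species (truncated
   normal elongation, 62/33/5% cup/dome/cavity mix), spatially
   autocorrelated VPD/LAI surfaces (Gaussian random fields, correlation
   −0.6), niche-driven occurrences, and SAR responses with known `(β, λ, σ)`
   so every stage is testable end-to-end without any data download.

The central containers are S4 classes with validity checks (`GridSpec`,
`EnvSurface`, `SpatialWeights`, `OLSFit`, `SARFit`) and accessor generics
(`surfaceValues()`, `lambdaHat()`, `pseudoR2()`, ...).

## Worked example

A complete run on a synthetic world (seed 1, 30 × 30 grid, 300 species):

```r
library(nestarid)

cfg   <- syntheticConfig(seed = 1)
world <- simulateWorld(cfg)
cells <- buildAssemblages(world$occurrences, world$species, cfg$grid)
cells$vpd <- surfaceAt(world$env$vpd, cells$cell_ix, cells$cell_iy)
cells$lai <- surfaceAt(world$env$lai, cells$cell_ix, cells$cell_iy)

report <- runAssemblageLevel(cells)     # filter, OLS, correlogram, SAR
report$prop_dome$sar
#> SAR error fit: y ~ vpd + lai + interaction  (n = 487)
#>   lambda = 0.4924 in (-2.657, 1.000)
#> (Intercept)         vpd         lai     vpd:lai
#>    0.059202    0.090465   -0.046584    0.016455
#>   logLik = 1082.515, Nagelkerke pseudo-R2 = 0.9480
```

The positive `vpd` coefficient says the proportion of dome-nesting species
rises with aridity — the generator builds that coupling in
(`nicheStrength = 0.8`), and the fitted model recovers it; `lambda ≈ 0.49`
is the estimated strength of residual spatial autocorrelation absorbed by
the error term. The species-level report from the same world:

```r
sp <- runSpeciesLevel(world$species)
sp$summary
#>  nest_type   n mean_elongation se_elongation
#>        cup 184        1.374017   0.005346144
#>       dome  93        1.384643   0.006831990
#>     cavity  23        1.368798   0.013499641
sp$anova
#> F(2, 297) = 0.88, p = 0.416
```

Here nest types share an elongation distribution by construction (the
generator draws elongation independently of nest type), so the ANOVA is
correctly null — species-level and assemblage-level signals are distinct
things, which is the point of the spatial analysis.

Real data enter through the same doors: `readTraitTable()` for trait CSVs,
`buildAssemblages()` for occurrence CSVs (point records or pre-gridded
species-by-cell tables), `readAsciiGrid()` for ESRI ASCII rasters.

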