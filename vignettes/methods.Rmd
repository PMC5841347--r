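---
title: "Models and methods: egg shape, nest type, and aridity on equal-area grids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistical machinery:
the models, the tunable parameters and why their defaults are what they
are, what the synthetic-data generator does and does not emulate, and the
numerical decisions that a maintainer would otherwise have to reverse
engineer.

## 1. The analysis in one paragraph

Species traits (egg elongation `E = L/B`; nest type cup / dome / cavity)
are combined with gridded breeding occurrences into per-cell assemblages on
an equal-area grid. Each cell carries mean elongation for cup and for dome
nesters (cavity nesters, few and distinctive, are excluded from elongation
summaries), the proportion of dome-nesting species, and a
sampling-completeness index. Two environmental covariates — vapour pressure
deficit (VPD, the air's drying capacity) and leaf area index (LAI, canopy
shade) — are averaged onto the same grid. Each assemblage response is
modelled as `y ~ VPD * LAI`, first by OLS; residual spatial autocorrelation
is diagnosed with Moran's I correlograms, and where present the model is
refitted as a maximum-likelihood simultaneous autoregressive (SAR)
spatial-error model.

## 2. Species-level models

* **ANOVA / Tukey.** One-way ANOVA of elongation across nest types (for a
  single factor the Type II Wald F reduces to the classical F), then
  Tukey–Kramer pairwise comparisons on the studentized range, with the
  harmonic-mean adjustment because the nest-type groups are strongly
  unbalanced. Both run through `stats::aov()` / `stats::TukeyHSD()`.
* **Family random intercept.** As a robustness check against shared
  ancestry, elongation is refitted with nest type fixed and taxonomic
  family as a random intercept. The REML criterion is profiled analytically
  down to the single variance ratio `γ = σ²_family / σ²_resid` — for one
  grouping factor the per-family covariance `σ²(I + γJ)` has closed-form
  inverse and determinant — and `γ` is found by a bounded 1-D search on the
  log scale, with the `γ = 0` boundary checked explicitly. This
  implementation exists (rather than a call into a mixed-model package)
  because the surface contract includes pinning the group variance at zero
  to demonstrate exact collapse to OLS; the test suite cross-checks fixed
  effects, variances and the REML log-likelihood against `lme4::lmer()`.
  Inference on the fixed factor is a plain Wald F with residual degrees of
  freedom; small-sample df corrections are deliberately out of scope.
* **Outlier screening.** Species outside `k = 3` sample standard deviations
  of the overall elongation mean are flagged, and the species-level
  analyses run both with and without them; both sets are always returned.

## 3. Grid, assemblages, completeness

* **Projection.** Ellipsoidal (GRS80) Albers equal-area conic, closed-form
  forward and inverse; defaults are the standard Australian Albers
  parameters (central meridian 132°E, standard parallels −18°/−36°,
  latitude of origin 0, no false offsets). All parameters are configurable;
  only equal-area matters for the method, since it makes all cells
  comparable sampling units. The inverse iterates the equal-area latitude
  to below 1e−13 radians (a handful of iterations).
* **Cells.** Half-open squares `[x, x+s) × [y, y+s)`, lower-left origin,
  integer `(ix, iy)` ids; a point exactly on a shared edge belongs to the
  cell whose lower edge it sits on. Cell size defaults to 100 km.
* **Assemblages.** The distinct species set per cell (set semantics:
  duplicate records are harmless). The proportion-domed denominator
  defaults to all trait-classified species in the cell (cup + dome +
  cavity); a `"cup_dome"` switch exists because either convention is
  defensible and the choice is not determined by the method itself.
* **Completeness.** Bias-corrected Chao2 on sampling-event incidence:
  `S_est = S_obs + ((m−1)/m) · Q1(Q1−1) / (2(Q2+1))`, index
  `S_obs / S_est`, undefined below two events. The default retention rule —
  at least 10 cup and 10 dome species per cell (inclusive) and completeness
  at least 0.7 — uses a threshold that is a documented placeholder: the
  estimator and cut-off are reasonable field practice, and both are plain
  config keys rather than claims about any particular study's supplementary
  choices.

## 4. Environment

`e_sat(T) = 0.61375 · exp(17.502 T / (240.97 + T))` kPa (Jones 1992
constants, fixed for bit-stable tests; alternative constant sets are out of
scope). `VPD = max(e_sat(T_max) − VP, 0)`; supersaturated inputs clamp to
zero with a counted warning. VPD is computed **daily and then averaged**:
`e_sat` is convex, so the order matters, and the daily-first order is the
faithful reading of a variable defined from daily quantities; the
alternative order is exposed behind a flag for sensitivity analysis.
Aggregation to the analysis grid is an exact rectangle-intersection
area-weighted mean (equal weights when fine cells nest), with missing fine
cells excluded from the weight sum. Rasters travel as ESRI ASCII grids —
a plain-text format read and written by a small built-in parser.

## 5. Spatial statistics

* **Weights.** Distance-band neighbours: centroid pairs within 200 km
  (inclusive at the threshold), binary or row-standardised. Isolated cells
  keep empty rows and are reported. 200 km on a 100 km grid gives interior
  cells 12 neighbours (rook + diagonal + second-order orthogonal).
* **Moran's I** with the analytic normality-null mean `−1/(n−1)` and
  variance; a seeded permutation alternative (999 draws) is available. The
  implementation is neighbour-list based; the tests pin it to a dense
  brute-force double summation at 1e−12 and to `ape::Moran.I` (which
  row-standardises internally, so only that coding is directly comparable;
  its variance is the randomisation one, so the variance is instead checked
  against a direct re-assembly of the normality moments).
* **Correlogram.** Moran's I per distance band with binary weights; bands
  are upper-inclusive `((k−1)w, kw]` so that lattice neighbours at exactly
  one cell size land in band 1, with band width defaulting to the cell
  size. Empty bands are reported missing.
* **SAR error model.** `y = Xβ + u`, `u = λWu + ε`. Profile likelihood in
  `λ`: the filtered regression of `(I−λW)y` on `(I−λW)X` gives `β(λ)` and
  `σ²(λ)` in closed form, and `log|I−λW| = Σ log(1−λω_i)` uses the
  eigenvalues of `W`, computed once per weights object. Row-standardised
  `W = D⁻¹A` with symmetric binary `A` is similar to the symmetric
  `D^{-1/2}AD^{-1/2}`, so its spectrum is real; zero rows contribute zero
  eigenvalues. `λ` is maximised by R's bounded search strictly inside
  `(1/ω_min, 1/ω_max)` at tolerance 1e−8 (the tests verify agreement with a
  1e−4-step grid search to 2e−4); a solution within 1e−4 of a bound
  triggers a boundary warning. Coefficient standard errors are
  conditional-on-λ GLS errors. Supplying `lambda = 0` evaluates the profile
  there and reproduces OLS exactly, which the tests assert at 1e−6.
* **Pseudo-R².** The Nagelkerke rescaling
  `R²_CS / (1 − exp(2ℓ₀/n))` (null: intercept-only, non-spatial Gaussian)
  is reported when its divisor is positive. For continuous-density nulls
  with small response variance — precisely the situation of elongation
  responses with sd around 0.01 — `ℓ₀ > 0` and the rescaling is undefined;
  the fitters then report the unrescaled likelihood-ratio statistic
  `1 − exp(−(2/n)(ℓ_M − ℓ₀))`, which equals classical R² for Gaussian OLS
  and matches the convention of the spatial-regression software family this
  analysis descends from. The standalone `nagelkerkeR2()` keeps the strict
  contract and errors on a non-positive divisor.
* **SAR trigger.** In the pipeline, the SAR refit is triggered when the OLS
  residual correlogram shows autocorrelation anywhere in the first 20 bands
  at the family-wise level: band p-values are Holm-corrected before
  comparison with α = 0.05. An uncorrected any-band rule would false-trigger
  on half of all spatially independent residual fields (20 tests at 0.05);
  Holm keeps the null trigger rate near α while genuine autocorrelation
  (band-1 p far below α/20) always fires. Both OLS and SAR are reported
  regardless, so the trigger only selects which is labelled final.
* **Weights selection.** The comparison across neighbourhood distances
  (200–1000 km) and codings is tabulated — SAR fit plus mean/max |I| of the
  innovations over the first 20 bands — with no automatic winner; choosing
  a configuration with uniformly low |I| is a documented heuristic, not an
  algorithm.

## 6. The synthetic world

The generator's defaults are the study conditions, chosen once:

| parameter | default | rationale |
|---|---|---|
| species | 300 | continental passerine pool size |
| nest mix | 62/33/5% cup/dome/cavity | observed class frequencies |
| elongation | N(1.37, 0.07) on [1.05, 1.70] | species-level marginals |
| egg breadth | U(14, 18) mm | small-passerine eggs; length back-solved |
| grid | 30 × 30 × 100 km | continental window at analysis resolution |
| GRF range | 500 km | climate-scale smoothness (band-1 I ≈ 0.3+) |
| VPD, LAI | [0.2, 4.5] kPa, [0.05, 5.5]; corr −0.6 | continental ranges; dry places have sparse canopies |
| niche width | 0.9 kPa | ranges span a few cells of VPD |
| niche strength | 0.8 | strong trait–aridity coupling for recovery tests |
| response model | β = (1, 0.5, −0.3, 0.1), λ = 0.7, σ = 1 | known-parameter recovery |

Occupancy is Bernoulli with a Gaussian niche on the VPD axis; dome-nesting
and round-egged species have optima pulled toward high VPD in proportion to
`nicheStrength`. Occupied cells emit one to three point records with
sampling-event ids for completeness estimation. A single root seed derives
fixed per-stage sub-seeds, so stages regenerate independently and every
output is a pure function of (config, seed). Truncated-normal draws use
rejection sampling — the truncation is ~4.5 sd each side, so waste is
negligible.

What the generator does *not* emulate: observation effort gradients,
coastline/irregular study regions, phylogenetic trait conservatism beyond
family blocks, temporal dynamics, or record-level noise (misidentification,
coordinate error). Passing tests therefore demonstrate that the estimators
recover known structure under idealised sampling, not that any particular
empirical dataset is clean.

One property of the generator is worth a caution: with `nicheStrength = 0`,
the per-world correlation between the proportion domed and VPD is *not*
near zero — the realised niche optima of the finite dome-species pool are
a shared random draw, so each world has a smooth composition trend with a
random sign (magnitude shrinking with species count, not with cell count).
The null test therefore asserts the property the null actually has — sign
balance around zero across worlds — against the strong-coupling case where
the correlation is consistently positive.

## 7. Problem sizes and test design

The suite pins every estimator to an independent oracle at small scale
(dense Moran summation at n = 100; determinant route for the log-Jacobian
at n = 49; `lme4`, `ape`, normal-equation and closed-form hand values), and
runs recovery at moderate scale: 200 SAR simulations on a 20 × 20 lattice
with λ = 0.7; 100 REML recovery draws at 300 species / 30 families; 50
end-to-end worlds at 30 × 30 cells for sign recovery of the VPD effects
(evaluated at mean LAI, since with an interaction the main effect alone is
not the effect of interest); 200 white-noise correlograms for null
calibration, restricted to bands with at least 30 pairs where the normal
reference is trustworthy. These sizes were chosen as the smallest at which
the Monte-Carlo noise of the checked summaries is comfortably below the
asserted margins.

## 8. Known limitations

* Spatial weights are dense in construction (distance matrix), fine to a
  few thousand cells; continental 100 km grids are hundreds of cells, so
  this is comfortable, but the implementation is not intended for
  1 km national grids.
* Asymmetric custom weights (not derived from a symmetric neighbour
  relation) are rejected by the eigenvalue machinery rather than handled.
* The SAR intercept is estimated with roughly `(1−λ)⁻¹` times the slopes'
  sampling error (the spatial filter shrinks the constant column), which is
  visible in recovery summaries that include it.
* The family random intercept is the only concession to phylogeny; no
  phylogenetic GLS.
* Inference after model selection (OLS vs SAR by the correlogram trigger)
  is reported as-is, unadjusted — standard practice in this literature, but
  still selection.
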