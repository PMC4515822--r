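---
title: "Delineating urban acid islands from precipitation-chemistry gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating urban acid islands from precipitation-chemistry gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acidisland)
```

## The problem

Large cities concentrate emissions of the three acid precursors — SO₂ from
combustion, NOₓ from traffic and industry, NH₃ from waste and agriculture —
and the deposition they drive decays with distance from the urban core. In
regions with acid-sensitive soils this produces *acid islands*: discs
around cities within which the deposited acidity exceeds what soils can
buffer. This package estimates the size of those islands from site-level
precipitation chemistry: monitoring sites at known locations report
volume-weighted mean (VWM) pH and concentrations of SO₄²⁻, NO₃⁻ and NH₄⁺
in bulk precipitation (open-field collectors) and in throughfall
(collectors under the forest canopy, which add canopy-captured dry
deposition and are therefore the closer proxy for total deposition).

## Chemistry conventions

All ion amounts are in charge equivalents: concentrations in μeq L⁻¹,
fluxes in keq ha⁻¹ yr⁻¹. The conversions are exact identities:

* `ph_to_h()`: [H⁺] = 10^(6 − pH) μeq L⁻¹, and its inverse `h_to_ph()`.
* `conc_to_flux()`: F = C·P·10⁻⁵ — 1 mm of rain over 1 ha is 10⁴ L, and
  1 keq is 10⁹ μeq, hence the constant.
* `volume_weighted_mean()`: Σvᵢcᵢ/Σvᵢ over sampling events.

Cross-site summaries use the geometric mean (`geometric_mean()`,
`summary_table()`): deposition data are positive and right-skewed, and the
geometric mean is the natural location parameter under the multiplicative
error model used throughout. Two deliberate conventions:

* **Site pH is summarized and regressed as reported.** Converting each
  site's already-aggregated pH back to H⁺, averaging, and reconverting
  would double-transform a quantity that monitoring programmes publish on
  the pH scale. Within-site event aggregation, where the raw volumes
  exist, is a different matter: `volume_weighted_ph()` defaults to
  averaging in H⁺-activity space (chemically meaningful) and offers a
  direct-pH mode, recording which was used, because source publications
  are split on this and the choice is not always recoverable.
* **Fluxes are derived per site before any summary.** F = C·P does not
  commute with summarizing C and P separately (the geometric mean commutes
  only if P is also summarized geometrically; the arithmetic mean not at
  all). The pipeline therefore always computes per-site fluxes first; a
  regression test enforces the order.
* **Zeros are excluded from geometric means** (with a warning and reduced
  n) rather than patched with a pseudo-count — no defensible pseudo-count
  exists for equivalent concentrations spanning two orders of magnitude.

## Distances

`assign_distances()` gives each site the haversine distance to the nearest
registry city, on a sphere of radius 6371.0088 km (the mean Earth radius).
The spherical error (< 0.5 %) is far below the scatter of the deposition
data, and a closed-form metric keeps the analysis reproducible without a
geodesy stack. "Large city" is a registry property: only cities with
nonagricultural population strictly above 0.5 million enter the search.
Ties are broken by lexicographic city name; distances are floored at 1 km
because the power law diverges at x → 0 (real forest sites never sit on a
city center; the floor only guards degenerate synthetic input). Sites may
carry transcribed distances from source publications; the
`keep`/`recompute` policy decides which is authoritative, and divergences
above 10 % are flagged either way.

## The two regressions

For each medium, `fit_all()` estimates one curve per quantity:

* `fit_power_law()`: y = a·x^b for H⁺, SO₄²⁻, NO₃⁻, NH₄⁺ — concentration
  and flux (16 curves);
* `fit_log_curve()`: pH = c + d·ln x (2 curves).

The default estimator is OLS on (ln x, ln y). This is a modelling choice,
not merely a transformation trick: positive, right-skewed deposition data
with spread roughly proportional to the mean are well described by
multiplicative lognormal errors, under which log-log OLS is the maximum
likelihood estimator and its t-based inference is exact. A nonlinear
least-squares refinement on the original scale (`method = "nls"`,
initialized from the log-log fit) is provided because additive-error
fitting is also defensible; each method reports R² on its own fitting
scale and the report says which. p-values are the two-sided t-test of the
slope, per curve, with no multiple-testing correction (each curve is its
own hypothesis). The minimum n is 3 — two parameters plus one residual
degree of freedom; cells below that are recorded as unavailable rather
than aborting the table. Because H⁺ derives from pH, a medium with no pH
loses its pH, H⁺-concentration and H⁺-flux cells together.

The two forms are one model in two coordinate systems: pH = c + d·ln x is
exactly H⁺ = 10^(6−c)·x^(−d·ln 10), and a test asserts this identity
numerically through the fitting routines.

## Critical radius

The potential acid load is PAL = H⁺ + 2·NH₄⁺ (`potential_acid_load()`):
nitrification of each deposited ammonium ion releases two protons, one
"new" and one previously neutralized in the atmosphere. With both
throughfall flux fits, PAL(r) = a_H·r^(b_H) + 2·a_N·r^(b_N), strictly
decreasing when both exponents are negative (this is *checked*, not
assumed). `critical_radius()` solves PAL(r) = CL by bisection in log r on
[1, 10 000] km, contracting the bracket to relative machine precision
(load residual ≪ 10⁻⁹ keq ha⁻¹ yr⁻¹, radius resolved far below 10⁻⁶ km —
verified against the closed form (a/CL)^(−1/b) when one term vanishes).
If PAL never reaches CL the result is a flagged "no island" with radius 0,
not an error. The default CL = 2 keq ha⁻¹ yr⁻¹ is the *maximum* critical
load for acid-sensitive forest soils in the target region, so the radius
is a conservative (inner) estimate. The radius is built from throughfall
fits by default (total-deposition proxy); `radius_basis = "bulk"` exists
for sensitivity analysis.

## Island area

`buffer_union_area()` measures the union of geodesic discs around all
cities, clipped to the region, twice:

* **Monte Carlo** (`"mc"`): uniform equal-area sampling over the region —
  uniform in the Lambert cylindrical equal-area plane (x = longitude in
  radians, y = sin latitude), which is exactly uniform on the sphere —
  counting points within the radius of any city by haversine distance.
  Returns the binomial standard error. Default 10⁶ points: for a fraction
  around 0.3 of a 2.4 M km² region that is a standard error near 0.05 %.
* **Equal-area grid quadrature** (`"projected_union"`): the same indicator
  integrated deterministically over a regular grid of exactly equal-area
  cells (Δx·Δy·R² = cell_km²) in the same projection.

The two estimators share no randomness and must agree within 3 Monte Carlo
standard errors — a cross-check contract asserted on randomized city
configurations in the tests. A single unclipped disc reproduces the exact
spherical-cap area 2πR²(1 − cos(r/R)) to 0.1 % with cells of r/100.
Region polygons use one consistent convention throughout: edges are
straight segments in the equal-area plane, so the shoelace area, the
point-in-polygon test (crossing parity, supporting holes and multi-part
regions) and the sampler are mutually exact; `geosphere::areaPolygon` on a
densified ring is the independent cross-check in the tests. The GeoJSON
island export writes the per-city disc rings as-is (possibly overlapping);
the area numbers come from the estimators above, never from those rings.

## Budget arithmetic

`enrichment_ratios()` forms throughfall/bulk ratios of geometric-mean
fluxes per ion — the canopy signature; nitrogen ratios sit below sulfate's
because of foliar uptake, which also means a throughfall-based radius is,
if anything, an underestimate. `emission_acidity()` converts precursor
emissions to charge equivalents (SO₂: 2 eq per mol S, M = 32.06; NOₓ, NH₃:
1 eq per mol N, M = 14.007) and reports the SO₂/NOₓ acidification-capacity
ratio and the fraction of that acidity NH₃ could neutralize; the headline
values are insensitive to the 32 vs 32.06 molar-mass convention.

## The synthetic generator

`generate_synthetic()` emulates the study conditions with known ground
truth, for recovery and calibration tests. Defaults (chosen once to echo
the observed study):

| parameter | default | rationale |
|---|---|---|
| sites / cities | 33 / 5 | per-medium site count of the compiled network |
| per-ion n | pH 28, SO₄ 30, NO₃/NH₄ 33 | ragged availability of literature data |
| distance law | log-uniform on [2, 300] km | leverage across decades of x, matching the network's spread |
| bulk conc. truth (a, b) | SO₄ (320, −0.35), NO₃ (42, −0.25), NH₄ (125, −0.30) | geometric means near 101/19/48 μeq L⁻¹ over that distance law |
| pH truth (c, d) | 4.7 + 0.25·ln x, throughfall +0.3 | site pH near 5.5 (bulk) / 5.8 (throughfall) |
| enrichment | 1.82 / 1.56 / 1.34 | observed throughfall/bulk flux contrasts |
| precipitation | U(1200, 2200) mm | humid subtropical range |
| noise | σ_log = 0.3, σ_ph = 0.3 | reproduces the observed fit R² of 0.4–0.8 |

Sites are placed around a random city at a sampled distance and bearing
(redrawn if outside the region), but their chemistry is driven by the
distance to the *nearest* city — exactly the covariate the analysis will
reconstruct — so the ground truth is recoverable. Throughfall enrichment
multiplies the bulk amplitude *before* noise, making the enrichment-ratio
oracle exact in expectation. pH is clipped to (3, 9) to guard the H⁺
conversion domain; clips are counted in the truth sidecar (zero under
defaults). Precipitation enters fluxes as an extra bounded multiplicative
spread around the mean-precipitation flux curves recorded in the truth
record; recovery tests that need exact flux power laws fix the
precipitation range to a point.

What the generator does *not* emulate: anisotropic (wind-driven) plumes,
overlapping multi-city source contributions, spatially correlated
residuals, base-cation neutralization, and observation-period weighting.
Passing recovery tests therefore demonstrate that the estimators recover
the assumed data-generating process, not that real deposition fields obey
it.

Under these defaults the generating PAL curve crosses 2 keq ha⁻¹ yr⁻¹ at
34.0 km. That is the honest consequence of the configured geometric means —
a network-typical ammonium flux near 1 keq ha⁻¹ yr⁻¹ puts 2·NH₄⁺ near the
critical load at typical distances — and is deliberately *not* calibrated
to any particular published radius, which depends on the original site
table and city registry.

## Problem sizes and numerical choices

The test suite and the acceptance script size their simulations to run
comfortably on one CPU: 500 replicates for confidence-interval calibration
(n = 33 per replicate), 200 seeds × 99 bootstrap resamples for the
radius-recovery experiment, 10⁵–10⁶ Monte Carlo points and 1.5–2 km grid
cells for area cross-checks. Determinism is strict: every stochastic
routine takes an explicit seed, and identical configuration + seed yields
byte-identical reports.

## Known limitations

* The spherical-cap/quadrature machinery assumes a common radius for all
  cities; population- or wind-scaled per-city radii are out of scope.
* Bulk and throughfall are treated as separate media linked only through
  the enrichment ratios; canopy-exchange modelling is out of scope.
* The GeoJSON export is a visualization artifact, not a boolean union.
* Log-log OLS R² is not comparable to original-scale R²; consumers of the
  fit table must heed the `method` column.
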