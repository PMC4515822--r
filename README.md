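# acidisland

Tools for delineating urban **acid islands**: the zones around large cities
where atmospheric acid deposition is high enough to threaten soil
acidification. The package targets the situation of southern China's
forests — strong urban emission hotspots of SO₂, NOₓ and NH₃, monitored by
a sparse, literature-compiled network of precipitation-chemistry sites —
but the machinery is generic: any site table, city registry and region
polygon in the supported formats will do.

## The model

Site-level chemistry is summarized as volume-weighted mean (VWM)
concentrations (μeq L⁻¹), converted to annual deposition fluxes by
F = C·P·10⁻⁵ (keq ha⁻¹ yr⁻¹, with P the annual precipitation in mm).
Each site is assigned the great-circle distance *x* (km) to the center of
the nearest *large city* (nonagricultural population > 0.5 million).
Two empirical distance-decay forms are fitted per sampling medium (bulk
precipitation and throughfall):

* power law for ion concentrations and fluxes: **y = a·x^b** (b < 0 means
  an increase toward the city), fitted by OLS on (ln x, ln y);
* logarithmic curve for pH: **pH = c + d·ln x** (d > 0 means pH falls
  toward the city).

The **potential acid load** is the proton load after complete nitrification
of deposited ammonium, PAL = H⁺ + 2·NH₄⁺ (deposition fluxes). With the two
throughfall flux fits,

```
PAL(r) = a_H · r^b_H + 2 · a_N · r^b_N
```

and the **critical radius** r\* solves PAL(r\*) = CL for a critical acid
load CL (default 2 keq ha⁻¹ yr⁻¹), by bisection. The acid-island *area* is
the union of the geodesic discs of radius r\* around all registry cities,
clipped to the region — estimated both by equal-area Monte Carlo sampling
on the sphere and by a deterministic equal-area grid quadrature, which must
agree within Monte Carlo error. Budget helpers compute throughfall/bulk
enrichment ratios and emission-equivalent acidity arithmetic (SO₂ carries
2 eq per mol S; NOₓ and NH₃ 1 eq per mol N).

Because the study's compiled site table is not redistributable, the package
ships a seeded synthetic-data generator (`generate_synthetic()`) that
emulates the study conditions with known ground truth, plus a small
committed fixture (`packaged_fixture()`).

## Worked example

The numbered scripts under `analysis/` run the whole study on a synthetic
data set (seed 20150727) and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # generate sites/cities/region + truth
Rscript analysis/02_distances_fluxes.R
Rscript analysis/03_fits.R
Rscript analysis/04_acid_island.R
Rscript analysis/05_budget.R
```

Stage 4 prints, for that seed:

```
critical radius: 25.4 km (ground truth 34.0 km)
PAL at the radius: 2.000000000 keq/ha/yr
island union area: 10033 km2 (MC, se 141) vs 10104 km2 (grid)
coverage: 0.51% of the 1.98 million km2 region
```

i.e. the fitted throughfall H⁺ and NH₄⁺ power laws cross the 2 keq ha⁻¹
yr⁻¹ critical load 25.4 km from a city center (the generating curves cross
at 34.0 km; with n = 33 noisy sites the estimate carries sampling error of
this order), the five cities' discs cover ~10,000 km² of the region, and
the two independent area estimators agree within one Monte Carlo standard
error. The same chain in code:

```r
library(acidisland)
fx <- packaged_fixture()
sites  <- assign_distances(read_sites(fx["sites"]), read_cities(fx["cities"]))
fits   <- fit_all(sites)                      # 18 distance-decay curves
curve  <- acid_load_curve(fits$fits[["throughfall.h.flux"]],
                          fits$fits[["throughfall.nh4.flux"]])
critical_radius(curve)$radius_km              # 25.4
```

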