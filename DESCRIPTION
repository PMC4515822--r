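Package: acidisland
Title: Urban Acid Islands: Distance-Decay Gradients of Acid Deposition Around Large Cities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for delineating urban "acid islands": regions around large
    cities where the potential acid load delivered by atmospheric deposition
    exceeds the critical load for soil acidification. Provides validated I/O
    for site-level precipitation-chemistry tables and city registries,
    chemistry arithmetic (pH/hydrogen-ion conversion, volume-weighted means,
    concentration-to-flux conversion, geometric-mean summaries), great-circle
    distance assignment to the nearest large city, power-law and logarithmic
    distance-decay regressions for ion concentrations, fluxes and pH, a
    bisection solver for the critical acid-island radius, equal-area
    Monte Carlo and grid-quadrature estimates of the buffer-union area over a
    region, throughfall/bulk enrichment ratios, emission-equivalent acidity
    arithmetic, and a seeded synthetic-data generator with known ground truth
    for parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    mgcv,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
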