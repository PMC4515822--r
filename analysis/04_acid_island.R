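#!/usr/bin/env Rscript
# Stage 4: the acid-island delineation. Build the potential-acid-load curve
# from the throughfall hydrogen-ion and ammonium flux fits, solve
# PAL(r) = 2 keq/ha/yr for the critical radius, and measure the union area
# of the city discs within the region by both estimators. Writes
# results/acid_island.json and results/islands.geojson.

suppressMessages(library(acidisland))
suppressMessages(library(jsonlite))

sites <- read_sites("results/data/sites.csv")
cities <- read_cities("results/data/cities.csv")
region <- read_region("results/data/region.geojson")
sites <- assign_distances(sites, cities)
fits <- fit_all(sites)

curve <- acid_load_curve(fits$fits[["throughfall.h.flux"]],
                         fits$fits[["throughfall.nh4.flux"]],
                         critical_load = 2)
rad <- critical_radius(curve)
truth <- read_truth("results/data/truth.txt")
cat(sprintf("critical radius: %.1f km (ground truth %.1f km)\n",
            rad$radius_km, truth["critical_radius_km"]))
cat(sprintf("PAL at the radius: %.9f keq/ha/yr\n", rad$pal_at_radius))

mc <- buffer_union_area(cities, rad$radius_km, region, method = "mc",
                        n_points = 1e6, seed = 20150727)
gr <- buffer_union_area(cities, rad$radius_km, region,
                        method = "projected_union", cell_km = 2)
cat(sprintf("island union area: %.0f km2 (MC, se %.0f) vs %.0f km2 (grid)\n",
            mc$union_area_km2, mc$se_km2, gr$union_area_km2))
cat(sprintf("coverage: %.2f%% of the %.2f million km2 region\n",
            100 * mc$fraction, mc$region_area_km2 / 1e6))

islands_geojson(cities, rad$radius_km, "results/islands.geojson")
write_json(list(critical_radius_km = rad$radius_km,
                no_island = rad$no_island,
                pal_curve = list(a_h = curve$h$a, b_h = curve$h$b,
                                 a_nh4 = curve$nh4$a, b_nh4 = curve$nh4$b,
                                 critical_load = curve$critical_load),
                area_mc = mc, area_grid = gr),
           "results/acid_island.json", auto_unbox = TRUE, digits = NA)
cat("wrote results/acid_island.json and results/islands.geojson\n")
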