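#!/usr/bin/env Rscript
# Stage 3: fit the distance-decay curves -- a logarithmic curve for pH and
# power laws for ion concentrations and fluxes, per medium: 18 curves.
# Writes results/fit_table.csv.

suppressMessages(library(acidisland))

sites <- read_sites("results/data/sites.csv")
cities <- read_cities("results/data/cities.csv")
sites <- assign_distances(sites, cities)

res <- fit_all(sites)
write.csv(res$table, "results/fit_table.csv", row.names = FALSE)

cat(sprintf("%d of %d fits available; %d significant at P < 0.05\n",
            sum(res$table$available), nrow(res$table),
            sum(res$table$significant, na.rm = TRUE)))
cat("fit table (for pH rows, a = intercept c, b = slope d per ln km):\n")
print(res$table[, c("medium", "quantity", "kind", "n", "a", "b",
                    "r_squared", "p_value")],
      row.names = FALSE, digits = 3)
truth <- read_truth("results/data/truth.txt")
tf_nh4 <- res$table[res$table$medium == "throughfall" &
                      res$table$quantity == "nh4" & res$table$kind == "flux", ]
cat(sprintf("throughfall NH4+ flux: fitted b = %.3f vs ground truth %.3f\n",
            tf_nh4$b, truth["flux_nh4_b"]))
cat("wrote results/fit_table.csv\n")
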