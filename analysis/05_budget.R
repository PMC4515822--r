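#!/usr/bin/env Rscript
# Stage 5: budget arithmetic. Throughfall/bulk enrichment ratios from the
# fitted study, plus the emission-equivalent acidity arithmetic for the
# national precursor budget. Writes results/budget.json.

suppressMessages(library(acidisland))
suppressMessages(library(jsonlite))

summ <- read.csv("results/summaries.csv")
ratios <- enrichment_ratios(summ, summ)
cat("throughfall/bulk enrichment of deposition fluxes:\n")
cat(sprintf("  sulfate %.2f, nitrate %.2f, ammonium %.2f\n",
            ratios[["so4"]], ratios[["no3"]], ratios[["nh4"]]))
cat("(nitrogen enrichment below sulfate is the canopy-uptake signature)\n")

em <- emission_acidity(14.4, 5.0, 12.7)
cat(sprintf("emission equivalents: SO2 %.2f, NOx %.2f, NH3 %.2f Teq/yr\n",
            em$eq_so2, em$eq_nox, em$eq_nh3))
cat(sprintf("acidification-capacity ratio SO2/NOx: %.2f\n", em$acid_ratio))
cat(sprintf("NH3 could neutralize %.0f%% of the SO2 + NOx acidity\n",
            100 * em$neutralization_fraction))

write_json(list(enrichment = as.list(ratios), emissions = em),
           "results/budget.json", auto_unbox = TRUE, digits = NA)
cat("wrote results/budget.json\n")
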