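#!/usr/bin/env Rscript
# Step 1: generate the synthetic study region.
#
# No per-community demographic or facility records are deposited for the
# original study area, so the analysis runs on a synthetic region with the
# same structure: 49 communities with elderly (70+) populations and 32
# community care facilities with bed counts on a 4 km planar square.
# The seed fixes the region for every downstream step.

library(accessfca)

seed <- 42L
dir.create("results", showWarnings = FALSE)

cfg <- synth_config(seed = seed) # 49 communities, 32 facilities, 4000 m
reg <- generate_region(cfg)
validate_region(reg)

write_layers(reg, "results/demand.geojson", "results/supply.geojson")
write_layers(reg, "results/demand.csv", "results/supply.csv")

print(reg)
cat(sprintf("overall beds per elderly person: %.4f\n",
            sum(reg$facilities$beds) / sum(reg$demand$population)))
cat("layers written to results/{demand,supply}.{geojson,csv}\n")
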