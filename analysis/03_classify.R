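#!/usr/bin/env Rscript
# Step 3: choropleth-style level classification.
#
# Bins each run's scores into equal-width intervals from the minimum to the
# maximum value — six levels for the 2SFCA runs, five for the gravity run,
# the depths used for the study-style maps — and writes id,score,level
# tables plus a GeoJSON carrying score and level for mapping.

library(accessfca)

reg <- read_layers("results/demand.geojson", "results/supply.geojson")
runs <- list(`2sfca_500` = list(file = "results/scores_2sfca_500.csv", k = 6),
             `2sfca_600` = list(file = "results/scores_2sfca_600.csv", k = 6),
             potential = list(file = "results/scores_potential.csv", k = 5))

for (nm in names(runs)) {
  sc <- read_scores(runs[[nm]]$file)
  lv <- equal_interval_levels(sc$score, k = runs[[nm]]$k, ids = sc$id)
  out <- sprintf("results/levels_%s.csv", nm)
  write.csv(lv, out, row.names = FALSE)
  cat(sprintf("%s: %d levels used of %d, top-level communities: %s\n",
              nm, length(unique(lv$level)), runs[[nm]]$k,
              paste(lv$id[lv$level == max(lv$level)], collapse = ", ")))
}

# map-ready GeoJSON for the 600 m run
sc600 <- read_scores("results/scores_2sfca_600.csv")
res600 <- run_accessibility(reg, "2sfca", d0 = 600)
stopifnot(max(abs(res600$scores - sc600$score)) < 1e-12)
write_results(res600, "results/map_2sfca_600.geojson", reg = reg,
              levels = equal_interval_levels(res600$scores, 6, res600$ids))
cat("level tables written to results/levels_*.csv\n")
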