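#!/usr/bin/env Rscript
# Generate the synthetic study world: 20 countries pricing subsets of a
# 200-item master list, with category-structured nutrient densities and a
# synthetic DRI table for the 20 demographic groups. Writes the four CSV
# inputs consumed by the rest of the workflow.

library(conadiet)

world <- generate_world(world_spec(n_countries = 20, seed = 2024))

dir.create("results/world", recursive = TRUE, showWarnings = FALSE)
write.csv(world$foods, "results/world/foods.csv", row.names = FALSE)
write.csv(world$prices, "results/world/prices.csv", row.names = FALSE)
write.csv(world$countries, "results/world/countries.csv", row.names = FALSE)
write.csv(world$dri, "results/world/dri.csv", row.names = FALSE)

cov <- validate_category_coverage(world)
cat(sprintf("world: %d foods, %d price records, %d countries\n",
            nrow(world$foods), nrow(world$prices), nrow(world$countries)))
cat(sprintf("items priced per country: mean %.1f (range %d-%d)\n",
            mean(cov$n_items), min(cov$n_items), max(cov$n_items)))
if (any(nzchar(cov$missing_categories))) {
  print(cov[nzchar(cov$missing_categories), ])
} else {
  cat("every country prices at least one item in all six categories\n")
}
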