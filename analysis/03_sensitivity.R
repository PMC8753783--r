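#!/usr/bin/env Rscript
# Which requirements drive diet costs? Aggregates shadow-price elasticity
# magnitudes by constraint across all solved cells and ranks the most
# influential requirements, overall and by demographic group.

library(conadiet)

sens <- read.csv("results/run/sensitivity.csv", stringsAsFactors = FALSE)
sens <- sens[sens$scenario == "EAR" & is.finite(sens$magnitude), ]

overall <- aggregate(cbind(magnitude, binding) ~ constraint, sens, mean)
overall <- overall[order(-overall$magnitude), ]
cat("most influential requirements (mean |elasticity|, share binding):\n")
print(head(transform(overall, magnitude = round(magnitude, 4),
                     binding = round(binding, 3)), 10), row.names = FALSE)

top8 <- head(overall$constraint, 8)
by_group <- aggregate(magnitude ~ constraint + group_id,
                      sens[sens$constraint %in% top8, ], mean)
write.csv(by_group, "results/elasticity_by_group.csv", row.names = FALSE)
write.csv(overall, "results/elasticity_overall.csv", row.names = FALSE)
cat(sprintf("\nwrote per-group elasticities for the top %d constraints\n",
            length(top8)))
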