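#!/usr/bin/env Rscript
# Step 7 — apply the scale to the cohort: EAP scores, meal-quality levels,
# survey-weighted level prevalence with cluster-bootstrap CIs, and the top
# five foods per eating occasion within each level.

library(mesascale)

model <- read_model_json("results/model.json")
responses <- read_response_matrix("results/responses18.csv")
retained <- readLines("results/scale_items.txt")
design <- read.csv("results/design.csv")
records <- read_food_records("results/records.csv")

scores <- eap_scores(model, subset_items(responses, retained))
write.csv(scores, "results/scores.csv", row.names = FALSE)
cat(sprintf("scores span %.0f-%.0f on the reporting scale\n",
            min(scores$score), max(scores$score)))
print(table(scores$level))

d <- design[match(scores$child_id, design$child_id), ]
prev <- level_prevalence(scores$level, d, n_boot = 1000, seed = 20130815)
write.csv(prev, "results/prevalence.csv", row.names = FALSE)
print(prev, digits = 3)

kept <- records[records$child_id %in% scores$child_id, ]
tf <- top_foods(kept, scores[c("child_id", "level")])
write.csv(tf, "results/top_foods.csv", row.names = FALSE)
cat("\ntop breakfast foods by level:\n")
print(tf[tf$occasion == "breakfast", ], digits = 3)
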