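#!/usr/bin/env Rscript
# Step 2 — clean implausible reports and build the 18 binary items.
#
# Children reporting fewer than four foods, or more than three SDs above the
# mean daily count, are excluded; the remaining reports become 18 binary
# occasion-by-class consumption indicators.

library(mesascale)

records <- read_food_records("results/records.csv")
cleaned <- clean_reports(records)
write.csv(cleaned$log, "results/exclusions.csv", row.names = FALSE)
cat(sprintf("excluded %d children:\n", nrow(cleaned$log)))
print(table(cleaned$log$rule))

responses <- build_items(cleaned$records)
write_response_matrix(responses, "results/responses18.csv")
cat(sprintf("built %d x %d response matrix; endorsement rates:\n",
            nrow(responses), ncol(responses)))
print(round(colMeans(responses), 2))
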