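#!/usr/bin/env Rscript
# Step 1 — generate the working cohort.
#
# No public accession exists for the original recall data, so the analysis
# runs on a synthetic cohort generated under the study conditions: 6,399
# children, latent meal quality theta ~ N(0,1), binary consumption items
# drawn from the published 11-item unfolding model (common threshold -1),
# the remaining 7 occasion-class items as nuisance Bernoulli items, food
# rows realizing each positive item, 20 planted implausible reporters, and
# a stratified two-stage survey design (year-school strata, class clusters).

library(mesascale)

dir.create("results", showWarnings = FALSE)
seed <- 20130814 %% 1000000L  # survey-era tag, kept well below 2^31

# No occasion skipping here: the unfolding model treats a non-reported
# occasion as non-consumption, and occasion-level skipping would zero all
# three of an occasion's items at once, breaking local independence and
# contaminating the calibration. The skip knob exists for exercising the
# reporting-rate machinery, not the calibration cohort.
cfg <- simulation_config(
  n_respondents = 6399,
  seed = seed,
  implausible_spec = list(n_low = 10, n_high = 10))

sim <- simulate_food_records(cfg)
design <- simulate_survey_design(n_strata = 6, clusters_per_stratum = 24,
                                 children_per_cluster = 45, seed = seed + 1)
design <- design[seq_len(nrow(sim$responses)), ]
design$child_id <- rownames(sim$responses)

write.csv(sim$records, "results/records.csv", row.names = FALSE)
write_response_matrix(sim$responses, "results/responses_true.csv")
write.csv(data.frame(child_id = rownames(sim$responses),
                     group_sex = as.character(sim$groups),
                     theta_true = sim$theta),
          "results/cohort_truth.csv", row.names = FALSE)
write.csv(design, "results/design.csv", row.names = FALSE)

cat(sprintf("cohort: %d children, %d food rows (%d implausible reporters)\n",
            nrow(sim$responses), nrow(sim$records),
            length(sim$implausible_ids)))
cat(sprintf("occasion reporting rates:\n"))
layout <- mesa_item_layout()
for (occ in eating_occasions()) {
  its <- layout$item[layout$occasion == occ]
  cat(sprintf("  %-16s %.2f\n", occ,
              mean(rowSums(sim$responses[, its]) > 0)))
}
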