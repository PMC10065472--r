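#!/usr/bin/env Rscript
# Stage 1 -- simulate the survey.
#
# Generates the synthetic two-day 24-h recall survey the rest of the analysis
# runs on: 2,000 adult respondents across the 8 DRI age-sex groups, a second
# telephone recall for ~35% of them, 500 BRR replicate weights, and
# population/mortality tables by sex and 5-year age band. Everything is
# deterministic given the seed below; later stages regenerate the same data
# from the same seed rather than round-tripping the replicate-weight matrix
# through CSV.

library(foplimpact)

seed <- 2025L
dir.create("results", showWarnings = FALSE)

cfg <- synth_config(n_respondents = 2000, n_brr_replicates = 500,
                    rng_seed = seed)
respondents <- generate_respondents(cfg)
recalls <- generate_recalls(respondents, cfg)
tables <- generate_stratum_tables(cfg)

write_table_csv(respondents[setdiff(names(respondents), "replicate_weights")],
                "results/respondents.csv")
write_table_csv(recalls, "results/recalls.csv")
write_table_csv(tables$population, "results/population.csv")
write_table_csv(tables$deaths, "results/deaths.csv")

cat(sprintf("simulated %d respondents, %d recall items (%.1f%% with 2 days)\n",
            nrow(respondents), nrow(recalls),
            100 * mean(tapply(recalls$recall_day, recalls$respondent_id,
                              max) == 2)))
cat(sprintf("stratum tables: %d population rows, %d death rows, %d deaths\n",
            nrow(tables$population), nrow(tables$deaths),
            sum(tables$deaths$count)))
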