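#!/usr/bin/env Rscript
# Stage 5 -- report.
#
# Assembles the reporting tables: baseline vs counterfactual intakes with
# significance flags (non-overlapping 95% CIs), deaths averted by sex and by
# disease, risk-factor attribution shares, and each scenario's share of total
# diet-related NCD deaths. Also cross-checks the published arithmetic
# identities the acceptance script recomputes.

library(foplimpact)

intakes <- read_table_csv("results/intake_estimates.csv")
summ <- read_table_csv("results/cra_summary.csv")
att <- read_table_csv("results/cra_attribution.csv")

flags <- foplimpact:::significance_flags(intakes)
write_table_csv(flags, "results/significance_flags.csv")
sig <- flags[flags$significant & flags$stratum == "all adults", ]
cat("meaningful differences (all adults):\n")
print(sig[c("diet_label", "nutrient")], row.names = FALSE)

cat("\ndeaths averted by scenario:\n")
print(summ, row.names = FALSE)

att$share <- round_half_up(att$pct_of_joint)
cat("\nattribution (% of joint total):\n")
print(att[c("scenario", "factor", "averted", "share")], row.names = FALSE)

# published arithmetic identities (inputs from the published analysis)
ref <- reference_values()
cat("\npublished identities:\n")
for (sc in names(ref$reductions)) {
  r <- ref$reductions[[sc]]
  cat(sprintf("  %s: 4*%0.1f + 9*%0.2f = %0.0f kcal/day\n", sc, r$sugars_g,
              r$satfat_g, round_half_up(delta_kcal_from_macros(r$sugars_g,
                                                               r$satfat_g))))
}
cat(sprintf("  S1 share of 2019 deaths: %0.1f%%\n",
            summarize_share_of_total(ref$deaths_averted$S1,
                                     ref$total_diet_related_deaths_2019)))
cat(sprintf("  S4 share of 2019 deaths: %0.1f%%\n",
            summarize_share_of_total(ref$deaths_averted$S4,
                                     ref$total_diet_related_deaths_2019)))
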