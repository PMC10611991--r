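#!/usr/bin/env Rscript
# Effectiveness endpoints with Wilson 95% CIs, overall and stratified by
# pregnancy duration and regimen. Expects 01_build_reference_cohort.R to
# have written results/reference_cohort.csv.

suppressMessages(library(misoqba))

cohort <- read_cohort("results/reference_cohort.csv")

ep <- derive_endpoints(cohort)
write.csv(ep, "results/effectiveness_endpoints.csv", row.names = FALSE)
cat("primary endpoints (complete without procedural intervention):\n")
for (i in seq_len(nrow(ep))) {
  cat(sprintf("  %-14s %d/%d = %.1f%% (95%% CI %.1f-%.1f)\n",
              ep$timepoint[i], ep$numerator[i], ep$denominator[i],
              100 * ep$proportion[i], 100 * ep$ci_low[i], 100 * ep$ci_high[i]))
}

by_dur <- tabulate_records(cohort, "effectiveness_last", strata = "duration_weeks")
by_reg <- tabulate_records(cohort, "effectiveness_last", strata = "regimen")
write.csv(by_dur, "results/effectiveness_by_duration.csv", row.names = FALSE)
write.csv(by_reg, "results/effectiveness_by_regimen.csv", row.names = FALSE)

cat("\nlast recorded follow-up, by regimen:\n")
cnp <- by_reg[by_reg$row == "complete_no_procedure", ]
for (i in seq_len(nrow(cnp))) {
  cat(sprintf("  %-16s %d/%d = %.1f%%\n", cnp$stratum[i], cnp$count[i],
              cnp$denominator[i], cnp$pct[i]))
}
cat("\n", format_frequency_table(by_dur, "effectiveness by pregnancy duration"),
    "\n", sep = "")
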