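#!/usr/bin/env Rscript
# Safety composites, expulsion timing, and care seeking by warning-sign
# status, with the chi-square / Fisher comparison of care-seeking rates.

suppressMessages(library(misoqba))

cohort <- read_cohort("results/reference_cohort.csv")

ws_tab <- tabulate_records(cohort, "warning_sign")
ae_tab <- tabulate_records(cohort, "adverse_event")
write.csv(rbind(cbind(variable = "warning_sign", ws_tab),
                cbind(variable = "adverse_event", ae_tab)),
          "results/safety_composites.csv", row.names = FALSE)
cat(sprintf("any warning sign: %d/%d (%.1f%%)\n",
            ws_tab$count[ws_tab$row == "warning_sign"], 637,
            ws_tab$pct[ws_tab$row == "warning_sign"]))
cat(sprintf("any potential adverse event: %d/%d (%.1f%%)\n",
            ae_tab$count[ae_tab$row == "adverse_event"], 637,
            ae_tab$pct[ae_tab$row == "adverse_event"]))

exp24 <- proportion_expelled_within(cohort, 24)
cat(sprintf("expelled within 24 h of first dose: %d/%d (%.1f%%)\n",
            exp24$numerator, exp24$denominator, 100 * exp24$proportion))

ws <- composite_warning_sign(cohort)
care_tab <- xtab_from_records(cohort, "sought_care", "warning_sign")
chi <- chi2_independence(care_tab)
fis <- fisher_exact(care_tab)
cat(sprintf("care seeking: %d/%d (%.1f%%) with warning signs vs %d/%d (%.1f%%) without\n",
            sum(cohort$sought_care[ws %in% TRUE]), sum(ws %in% TRUE),
            100 * mean(cohort$sought_care[ws %in% TRUE]),
            sum(cohort$sought_care[ws %in% FALSE]), sum(ws %in% FALSE),
            100 * mean(cohort$sought_care[ws %in% FALSE])))
cat(sprintf("  chi-square: X2=%.2f, df=%d, p=%.2g; Fisher exact: p=%.2g\n",
            chi$statistic, chi$df, chi$p_value, fis$p_value))
write.csv(data.frame(method = c("chi2", "fisher_exact"),
                     statistic = c(chi$statistic, NA),
                     p_value = c(chi$p_value, fis$p_value)),
          "results/care_seeking_tests.csv", row.names = FALSE)
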