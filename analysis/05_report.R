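#!/usr/bin/env Rscript
# Step 5 — summary and interpretation tables.
#
# Builds the study-population summary (gender x age, drug-count bins,
# per-COVID-drug counts, all with half-up two-decimal percentages) and
# the interpretation groupings: unique co-medications per ATC level-1
# class (COVID-19 drugs in their own category) and signal counts per
# adverse event SOC.

suppressMessages(library(faersddi))

raw <- file.path("results", "01_raw")
sig_dir <- file.path("results", "03_signals")
out_dir <- file.path("results", "05_report")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- cohort_config(
  covid_drug_list = names(simulation_config()$covid_drugs))
cohort <- read_report_set(file.path(sig_dir, "cohort"))

summary <- summarize_cohort(cohort, cfg)
print(summary)
write.csv(cohort_summary_table(summary),
  file.path(out_dir, "cohort_summary.csv"), row.names = FALSE)

tab <- read.csv(file.path(sig_dir, "signals.csv"),
  stringsAsFactors = FALSE)
signals <- tab[tab$signal, , drop = FALSE]
grouping <- group_for_interpretation(
  signals, read_atc_map(file.path(raw, "atc_map.csv")),
  read_meddra_hierarchy(file.path(raw, "meddra.csv")), cfg)
cat("\nCo-medications per ATC level-1 class:\n")
print(grouping$comed_by_atc, row.names = FALSE)
cat("\nSignals per adverse event SOC:\n")
print(grouping$ae_by_soc, row.names = FALSE)
write.csv(grouping$comed_by_atc,
  file.path(out_dir, "comed_by_atc.csv"), row.names = FALSE)
write.csv(grouping$ae_by_soc,
  file.path(out_dir, "ae_by_soc.csv"), row.names = FALSE)
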