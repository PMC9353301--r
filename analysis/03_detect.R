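#!/usr/bin/env Rscript
# Step 3 — detect interaction signals.
#
# Selects the COVID-19 cohort through the indication SMQ, rolls adverse
# events up to HLT level with the six-SOC exclusion, enumerates
# (COVID-19 drug, co-medication, AE) triples passing the 5-EPV
# criterion, fits the Firth-penalized interaction model to each, and
# flags signals showing interaction on the additive (RERI) or
# multiplicative scale. Age/gender disparity models are fit for every
# signal triple.

suppressMessages(library(faersddi))

raw <- file.path("results", "01_raw")
out_dir <- file.path("results", "03_signals")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

reports <- read_report_set(file.path("results", "02_normalized"))
cfg <- cohort_config(
  covid_drug_list = names(simulation_config()$covid_drugs))

cohort <- select_covid_reports(reports, cfg)
cat("COVID-19 cohort:", nrow(cohort$reports), "of",
  nrow(reports$reports), "reports\n")

hier <- read_meddra_hierarchy(file.path(raw, "meddra.csv"))
cohort <- rollup_and_filter_aes(cohort, hier, cfg)
cat("AE HLTs after SOC exclusion:",
  length(unique(cohort$aes$term)), "\n")
write_report_set(cohort, file.path(out_dir, "cohort"))

triples <- enumerate_triples(cohort, cfg)
cat("Triples retained at EPV >=", cfg$epv_threshold, ":",
  length(triples), "\n")

results <- analyze_triples(triples)
tab <- results_table(results)
write.csv(tab, file.path(out_dir, "signals.csv"), row.names = FALSE)
signals <- tab[tab$signal, , drop = FALSE]
cat(nrow(signals), "signal combination(s):\n")
print(signals[, c("triple_id", "reri", "reri_ci_low", "mult_ratio",
  "mult_p")], row.names = FALSE, digits = 3)

strata <- list()
for (id in signals$triple_id) {
  for (v in c("age", "gender")) {
    strata[[paste(id, v)]] <- suppressWarnings(
      stratified_disparity(triples[[id]], v))
  }
}
if (length(strata)) {
  st <- strata_table(strata)
  write.csv(st, file.path(out_dir, "strata.csv"), row.names = FALSE)
  cat("Disparity models:", nrow(st), "(",
    sum(st$specific), "age/gender-specific )\n")
}
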