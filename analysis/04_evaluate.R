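#!/usr/bin/env Rscript
# Step 4 — evaluate detected pairs against the reference DDI table.
#
# Deduplicates signal combinations to unordered drug pairs, classifies
# each against the graded reference table (documented /
# reference-nonsignificant / not covered), and computes the Monte Carlo
# empirical p-value p = (r+1)/(n+1) for the documented overlap under
# random pair sets drawn from the cohort's candidate universe.

suppressMessages(library(faersddi))

raw <- file.path("results", "01_raw")
sig_dir <- file.path("results", "03_signals")
out_dir <- file.path("results", "04_evaluation")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

tab <- read.csv(file.path(sig_dir, "signals.csv"),
  stringsAsFactors = FALSE)
signals <- tab[tab$signal, , drop = FALSE]
pairs <- signal_pairs(signals)
cat("Unique unordered signal pairs:", nrow(pairs), "\n")

reference <- read_reference_ddi(file.path(raw, "reference_ddi.csv"))
concordance <- compare_reference(pairs, reference)
print(concordance)
write.csv(concordance$pairs, file.path(out_dir, "concordance.csv"),
  row.names = FALSE)

cohort <- read_report_set(file.path(sig_dir, "cohort"))
cfg <- cohort_config(
  covid_drug_list = names(simulation_config()$covid_drugs))
part <- partition_drugs(cohort, cfg)
ep <- monte_carlo_empirical_p(pairs, part$covid, part$comed, reference,
  n_sims = 1000, seed = 20201)
print(ep)
write_empirical_p(ep, file.path(out_dir, "empirical_p.json"))
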