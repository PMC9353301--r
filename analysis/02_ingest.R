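#!/usr/bin/env Rscript
# Step 2 — ingest the raw quarterly tables.
#
# Parses the "$"-delimited files written by step 1, removes superseded
# case versions (highest caseversion per case wins), and normalizes
# verbatim drug names to ingredients through the name map. The result
# is the one-row-per-report interchange format used by every later
# step.

suppressMessages(library(faersddi))

raw <- file.path("results", "01_raw")
out_dir <- file.path("results", "02_normalized")

cases <- read_faers_tables(
  file.path(raw, "DEMO20Q1.txt"), file.path(raw, "DRUG20Q1.txt"),
  file.path(raw, "REAC20Q1.txt"), file.path(raw, "INDI20Q1.txt"),
  file.path(raw, "OUTC20Q1.txt")
)
cat("Parsed", nrow(cases$demo), "raw report rows (",
  length(unique(cases$demo$caseid)), "cases );",
  sum(cases$orphan_rows), "orphan rows\n")

cases <- deduplicate_cases(cases)
cat("After deduplication:", nrow(cases$demo), "reports\n")

norm <- normalize_reports(cases,
  read_drug_name_map(file.path(raw, "drug_name_map.csv")))
cat(sprintf(
  "Drug-name mapping: %d of %d rows mapped (coverage %.1f%%)\n",
  norm$stats$n_mapped, norm$stats$n_names, 100 * norm$stats$coverage))
cat("Reports with unconvertible age:", norm$stats$n_age_unconvertible, "\n")

write_report_set(norm$reports, out_dir)
cat("Wrote normalized interchange files to", out_dir, "\n")
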