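#!/usr/bin/env Rscript
# Step 1 — simulate a spontaneous-report cohort.
#
# Draws the study's synthetic FAERS-like report set under the default
# conditions (4,000 reports, Table-1-style demographic marginals, two
# planted interaction effects with the strongest at beta3 = ln 2) and
# writes it out in the raw "$"-delimited quarterly dialect, together
# with the mapping fixtures (drug-name map, MedDRA hierarchy slice,
# graded reference DDI table, ATC level-1 map).

suppressMessages(library(faersddi))

out_dir <- file.path("results", "01_raw")
cfg <- simulation_config()  # seed fixed in the configuration (20201)
sim <- generate_reports(cfg)
paths <- generate_fixture_tables(sim, out_dir)

truth <- cfg$planted_effects
cat("Simulated", cfg$n_reports, "reports into", out_dir, "\n")
cat(" planted interaction effects:\n")
for (i in seq_len(nrow(truth))) {
  cat(sprintf("  %s + %s -> %s  (b1=%.3f, b2=%.3f, b3=%.3f)\n",
    truth$covid_drug[i], truth$comed[i], truth$ae_hlt[i],
    truth$b1[i], truth$b2[i], truth$b3[i]))
}
cat(" superseded case versions planted:",
  sum(sim$case_info$caseversion - 1), "\n")
write.csv(truth, file.path(out_dir, "ground_truth.csv"),
  row.names = FALSE)
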