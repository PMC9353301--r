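test_that("parsing joins long tables to one record per demographics row", {
  dir <- withr::local_tempdir()
  demo <- rbind(demo_row("101"), demo_row("102"), demo_row("103"))
  drug <- data.frame(
    primaryid = c("101", "101", "102", "102", "103", "103"),
    drugname = c("aspirin", "metformin", "aspirin", "heparin",
      "metformin", "heparin"),
    role_cod = "PS", stringsAsFactors = FALSE
  )
  paths <- write_faers_fixture(dir, demo, drug)
  cases <- read_faers_tables(paths$demo, paths$drug, paths$reac,
    paths$indi, paths$outc)
  expect_equal(nrow(cases$demo), 3)
  expect_equal(as.integer(table(cases$drugs$primaryid)), c(2L, 2L, 2L))
  expect_equal(sum(cases$orphan_rows), 0L)
})

test_that("an empty drug table yields records with empty drug rows", {
  dir <- withr::local_tempdir()
  paths <- write_faers_fixture(dir, demo_row("7"))
  cases <- read_faers_tables(paths$demo, paths$drug, paths$reac,
    paths$indi, paths$outc)
  expect_equal(nrow(cases$demo), 1)
  expect_equal(nrow(cases$drugs), 0)
})

test_that("orphan long rows are dropped with a warning, not fatal", {
  dir <- withr::local_tempdir()
  drug <- data.frame(primaryid = c("1", "999"), drugname = "aspirin",
    role_cod = "PS", stringsAsFactors = FALSE)
  paths <- write_faers_fixture(dir, demo_row("1"), drug)
  expect_warning(
    cases <- read_faers_tables(paths$demo, paths$drug, paths$reac,
      paths$indi, paths$outc),
    "orphan"
  )
  expect_equal(nrow(cases$demo), 1)
  expect_equal(nrow(cases$drugs), 1)
  expect_equal(sum(cases$orphan_rows), 1L)
})

test_that("a missing mandatory column is a parse error naming the file", {
  dir <- withr::local_tempdir()
  paths <- write_faers_fixture(dir, demo_row("1"))
  bad <- data.frame(primaryid = "1", name_of_drug = "aspirin")
  utils::write.table(bad, paths$drug, sep = "$", quote = FALSE,
    row.names = FALSE)
  expect_error(
    read_faers_tables(paths$demo, paths$drug, paths$reac, paths$indi,
      paths$outc),
    "drug.*drugname"
  )
})

test_that("deduplication keeps the highest case version, ties to highest primaryid", {
  dir <- withr::local_tempdir()
  demo <- rbind(
    demo_row("11", caseid = "X", caseversion = 1),
    demo_row("12", caseid = "X", caseversion = 2),
    demo_row("13", caseid = "X", caseversion = 3),
    # case Y: version tie, larger primaryid must win
    demo_row("24", caseid = "Y", caseversion = 1),
    demo_row("29", caseid = "Y", caseversion = 1),
    demo_row("31", caseid = "Z", caseversion = 1)
  )
  paths <- write_faers_fixture(dir, demo)
  cases <- read_faers_tables(paths$demo, paths$drug, paths$reac,
    paths$indi, paths$outc)
  dd <- deduplicate_cases(cases)
  expect_equal(dd$demo$caseid, c("X", "Y", "Z"))
  expect_equal(dd$demo$primaryid, c("13", "29", "31"))
  # idempotent
  expect_identical(deduplicate_cases(dd), dd)
})

test_that("normalization applies set semantics over messy verbatim names", {
  dir <- withr::local_tempdir()
  drug <- data.frame(
    primaryid = c("1", "1"),
    drugname = c("ASPIRIN.", "aspirin  81mg"),
    role_cod = "PS", stringsAsFactors = FALSE
  )
  paths <- write_faers_fixture(dir, demo_row("1"), drug)
  cases <- read_faers_tables(paths$demo, paths$drug, paths$reac,
    paths$indi, paths$outc)
  nm <- drug_name_map(
    c("aspirin.", "aspirin 81mg"), c("aspirin", "aspirin"))
  norm <- normalize_reports(cases, nm)
  expect_equal(norm$reports$ingredients$ingredient, "aspirin")
  expect_equal(norm$reports$reports$n_unique_ingredients, 1L)
})

test_that("mapping coverage counts name occurrences", {
  dir <- withr::local_tempdir()
  drug <- data.frame(
    primaryid = rep("1", 10),
    drugname = paste0("drug", 1:10),
    role_cod = "PS", stringsAsFactors = FALSE
  )
  paths <- write_faers_fixture(dir, demo_row("1"), drug)
  cases <- read_faers_tables(paths$demo, paths$drug, paths$reac,
    paths$indi, paths$outc)
  nm <- drug_name_map(paste0("drug", 1:6), paste0("ing", 1:6))
  norm <- normalize_reports(cases, nm)
  expect_equal(norm$stats$n_names, 10)
  expect_equal(norm$stats$n_mapped, 6)
  expect_equal(norm$stats$coverage, 0.6)
})

test_that("age units convert to years and 65.0 falls in the elderly group", {
  expect_equal(convert_age_years(780, "MON"), 65)
  expect_equal(convert_age_years(65, "YR"), 65)
  expect_equal(convert_age_years(730.5, "DY"), 2)
  expect_true(is.na(convert_age_years(12, "CENTURY")))

  dir <- withr::local_tempdir()
  demo <- rbind(
    demo_row("1", age = "780", age_cod = "MON"),
    demo_row("2", age = "64", age_cod = "YR"),
    demo_row("3", age = "5", age_cod = "XX")
  )
  paths <- write_faers_fixture(dir, demo)
  cases <- read_faers_tables(paths$demo, paths$drug, paths$reac,
    paths$indi, paths$outc)
  norm <- normalize_reports(cases, drug_name_map("a", "a"))
  rep_df <- norm$reports$reports
  expect_equal(rep_df$age_years, c(65, 64, NA))
  expect_equal(rep_df$age_group,
    c("over65_inclusive", "under65", "missing"))
  expect_equal(norm$stats$n_age_unconvertible, 1)
})

test_that("normalization preserves report count and ingredient-count invariant", {
  for (seed in c(11, 12)) {
    sim <- generate_reports(simulation_config(n_reports = 150, seed = seed))
    dir <- withr::local_tempdir()
    paths <- generate_fixture_tables(sim, dir)
    cases <- deduplicate_cases(read_faers_tables(paths$demo, paths$drug,
      paths$reac, paths$indi, paths$outc))
    norm <- normalize_reports(cases, read_drug_name_map(paths$name_map))
    rs <- norm$reports
    expect_equal(nrow(rs$reports), nrow(cases$demo))
    counts <- table(factor(rs$ingredients$report_id,
      levels = rs$reports$report_id))
    expect_equal(rs$reports$n_unique_ingredients, as.integer(counts))
  }
})

test_that("the normalized interchange format round-trips exactly", {
  sim <- generate_reports(simulation_config(n_reports = 120, seed = 5))
  dir <- withr::local_tempdir()
  write_report_set(sim$reports, dir)
  back <- read_report_set(dir)
  expect_identical(back$reports, sim$reports$reports)
  expect_identical(back$ingredients, sim$reports$ingredients)
  expect_identical(back$aes, sim$reports$aes)
  expect_identical(back$indications, sim$reports$indications)
})
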