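covid_cfg <- function(...) {
  cohort_config(covid_drug_list = c("remdesivir", "hydroxychloroquine",
    "azithromycin"), ...)
}

test_that("indication SMQ selection keeps exactly the matching reports", {
  rs <- make_report_set(3,
    ingredients_of = function(i) "remdesivir",
    aes_of = function(i) "P1",
    indications_of = function(i) switch(i, "COVID-19", "Hypertension",
      "covid-19  ")  # case/whitespace-insensitive match
  )
  out <- select_covid_reports(rs, covid_cfg())
  expect_equal(out$reports$report_id, c("r001", "r003"))
  # monotone and idempotent
  expect_identical(select_covid_reports(out, covid_cfg()), out)
})

test_that("empty SMQ term list is a configuration error", {
  expect_error(
    cohort_config(smq_indication_terms = character(0),
      covid_drug_list = "remdesivir"),
    "SMQ"
  )
})

test_that("generator-planted COVID indications are recovered exactly", {
  sim <- generate_reports(simulation_config(n_reports = 100, seed = 31,
    covid_indication_prob = 0.4))
  planted <- sum(sim$truth$covid_flag$covid)
  out <- select_covid_reports(sim$reports,
    cohort_config(covid_drug_list = names(sim$config$covid_drugs)))
  expect_equal(nrow(out$reports), planted)
})

test_that("PT rollup collapses to primary HLTs and applies the SOC exclusion", {
  hier <- meddra_hierarchy(toy_hierarchy_df())
  cfg <- cohort_config(covid_drug_list = "a", excluded_socs = "S_drop")
  rs <- make_report_set(3,
    ingredients_of = function(i) "a",
    aes_of = function(i) list(c("P1", "P2"), c("P3", "P4"), c("P5"))[[i]],
    indications_of = function(i) "COVID-19"
  )
  out <- rollup_and_filter_aes(rs, hier, cfg)
  # hand-enumerated surviving HLT sets: {H1}, {H2} (H3 under S_drop), {}
  expect_equal(out$aes$term[out$aes$report_id == "r001"], "H1")
  expect_equal(out$aes$term[out$aes$report_id == "r002"], "H2")
  expect_equal(sum(out$aes$report_id == "r003"), 0)
  expect_equal(attr(out, "unresolved_pts"), 0)
  # rerunning on already-rolled-up terms resolves nothing new
  expect_warning(rollup_and_filter_aes(out, hier, cfg), "not resolvable")
})

test_that("the six default excluded SOCs include the investigations class", {
  expect_length(default_excluded_socs(), 6)
  expect_true("Investigations" %in% default_excluded_socs())
})

test_that("drug partition excludes self-pairs and allows covid-covid pairs", {
  cfg <- covid_cfg()
  rs <- make_report_set(2,
    ingredients_of = function(i) {
      list(c("remdesivir", "metformin"),
        c("hydroxychloroquine", "azithromycin"))[[i]]
    },
    aes_of = function(i) "P1", indications_of = function(i) "COVID-19"
  )
  part <- partition_drugs(rs, cfg)
  expect_setequal(part$covid,
    c("remdesivir", "hydroxychloroquine", "azithromycin"))
  # co-medication side contains everything observed, covid drugs included
  expect_setequal(part$comed,
    c("remdesivir", "metformin", "hydroxychloroquine", "azithromycin"))

  cfg2 <- cohort_config(covid_drug_list = "remdesivir")
  rs2 <- make_report_set(1, function(i) c("remdesivir", "metformin"),
    function(i) "P1", function(i) "COVID-19")
  tr <- enumerate_triples(
    rollup_and_filter_aes(rs2, meddra_hierarchy(toy_hierarchy_df()),
      cohort_config(covid_drug_list = "remdesivir", epv_threshold = 1e-9)),
    cohort_config(covid_drug_list = "remdesivir", epv_threshold = 1e-9)
  )
  # the only candidate pair as drug A is (remdesivir, metformin)
  expect_equal(unique(vapply(tr, `[[`, "", "covid_drug")), "remdesivir")
  expect_false(any(vapply(tr, `[[`, "", "comed") == "remdesivir"))
})

test_that("a report without any covid-list drug contributes no drug-A pairs", {
  cfg <- cohort_config(covid_drug_list = "remdesivir")
  rs <- make_report_set(1, function(i) c("metformin", "heparin"),
    function(i) "P1", function(i) "COVID-19")
  part <- partition_drugs(rs, cfg)
  expect_length(part$covid, 0)
})

test_that("EPV retention is inclusive at the threshold and uses p = 7", {
  # 35 events -> EPV exactly 5 -> retained; 34 -> excluded
  hier <- meddra_hierarchy(toy_hierarchy_df())
  for (n_events in c(34, 35)) {
    n <- 200
    rs <- make_report_set(n,
      ingredients_of = function(i) {
        if (i <= 50) c("remdesivir", "metformin") else "metformin"
      },
      aes_of = function(i) if (i <= n_events) "P1" else character(0),
      indications_of = function(i) "COVID-19"
    )
    cfg <- cohort_config(covid_drug_list = "remdesivir")
    tr <- enumerate_triples(rollup_and_filter_aes(rs, hier, cfg), cfg)
    if (n_events == 35) {
      expect_length(tr, 1)
      expect_equal(tr[[1]]$epv, 5)
    } else {
      expect_length(tr, 0)
    }
  }
})

test_that("triple enumeration matches a brute-force scan on a small cohort", {
  sim <- generate_reports(simulation_config(n_reports = 600, seed = 99))
  cfg <- cohort_config(covid_drug_list = names(sim$config$covid_drugs),
    epv_threshold = 2)
  hier <- meddra_hierarchy(sim$config$meddra)
  cohort <- rollup_and_filter_aes(
    select_covid_reports(sim$reports, cfg), hier, cfg)
  triples <- enumerate_triples(cohort, cfg)

  # brute force: recount events and cells straight from the report list
  rep_df <- cohort$reports
  keep <- rep_df$age_group != "missing" & rep_df$gender != "missing"
  ids <- rep_df$report_id[keep]
  ing <- cohort$ingredients
  aes <- cohort$aes
  covid <- intersect(sort(unique(ing$ingredient)), cfg$covid_drug_list)
  comed <- sort(unique(ing$ingredient))
  expected_ids <- character(0)
  for (e in sort(unique(aes$term))) {
    ev <- intersect(aes$report_id[aes$term == e], ids)
    if (length(ev) / 7 < 2) next
    for (a in covid) for (b in setdiff(comed, a)) {
      expected_ids <- c(expected_ids, paste(a, b, e, sep = " | "))
    }
  }
  expect_setequal(names(triples), expected_ids)

  # cell counts agree with direct recounts for every triple
  for (t in triples) {
    in_a <- ids %in% ing$report_id[ing$ingredient == t$covid_drug]
    in_b <- ids %in% ing$report_id[ing$ingredient == t$comed]
    pos <- ids %in% aes$report_id[aes$term == t$ae_hlt]
    expect_equal(unname(t$counts), c(
      sum(pos & in_a & in_b), sum(pos & in_a & !in_b),
      sum(pos & !in_a & in_b), sum(pos & !in_a & !in_b)
    ))
    expect_equal(sum(t$counts), sum(t$rows$outcome))
  }
})

test_that("reports with missing age or gender are excluded from triple rows", {
  hier <- meddra_hierarchy(toy_hierarchy_df())
  rs <- make_report_set(40,
    ingredients_of = function(i) c("remdesivir", "metformin"),
    aes_of = function(i) "P1",
    indications_of = function(i) "COVID-19",
    age = c(rep(NA, 5), rep(70, 35)),
    gender = c(rep("male", 5), rep("missing", 3), rep("male", 32))
  )
  cfg <- cohort_config(covid_drug_list = "remdesivir", epv_threshold = 1e-9)
  tr <- enumerate_triples(rollup_and_filter_aes(rs, hier, cfg), cfg)
  expect_equal(nrow(tr[[1]]$rows), 32)  # 40 - 5 missing age - 3 missing gender
  expect_equal(tr[[1]]$n_excluded_missing, 8)
})
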