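# Cohort construction: indication-based report selection, MedDRA PT->HLT
# rollup with SOC exclusion, drug partition, and enumeration of analyzable
# (drug A, co-medication B, adverse event E) triples under the
# events-per-variable criterion.

#' Read a MedDRA hierarchy table
#'
#' CSV with columns `pt`, `hlt`, `hlgt`, `soc` giving each Preferred
#' Term's primary High-Level Term and the chain up to the System Organ
#' Class. Every PT must map to exactly one primary HLT.
#'
#' @param path CSV file path.
#' @return a `meddra_hierarchy` object.
#' @export
read_meddra_hierarchy <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
    colClasses = "character")
  need <- c("pt", "hlt", "hlgt", "soc")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop_faersddi("MedDRA hierarchy '", basename(path),
      "' missing column(s) ", paste(missing_cols, collapse = ", "))
  }
  meddra_hierarchy(df)
}

#' Construct a MedDRA hierarchy from a data frame
#'
#' @param df data frame with columns `pt`, `hlt`, `hlgt`, `soc`.
#' @return a `meddra_hierarchy` object with normalized-key lookups
#'   `pt -> hlt` and `hlt -> soc`.
#' @export
meddra_hierarchy <- function(df) {
  key <- normalize_term(df$pt)
  if (anyDuplicated(key)) {
    dup <- df$pt[duplicated(key)]
    stop_faersddi("PT(s) mapped to more than one primary HLT: ",
      paste(unique(dup), collapse = ", "))
  }
  pt_to_hlt <- stats::setNames(df$hlt, key)
  hlt_df <- unique(df[, c("hlt", "soc")])
  hkey <- normalize_term(hlt_df$hlt)
  if (anyDuplicated(hkey)) {
    stop_faersddi("HLT(s) assigned to more than one SOC")
  }
  structure(
    list(table = df, pt_to_hlt = pt_to_hlt,
      hlt_to_soc = stats::setNames(hlt_df$soc, hkey)),
    class = "meddra_hierarchy"
  )
}

#' The six excluded System Organ Classes
#'
#' SOCs holding nonspecific disorders, laboratory results, social issues
#' and procedures, removed from the adverse event space before signal
#' detection.
#'
#' @return character vector of six SOC names.
#' @export
default_excluded_socs <- function() {
  c(
    "Injury, poisoning and procedural complications",
    "Social circumstances",
    "Product issues",
    "Surgical and medical procedures",
    "Investigations",
    "General disorders and administration site conditions"
  )
}

#' COVID-19 narrow SMQ indication terms
#'
#' The narrow Standardized MedDRA Query term list applied to the
#' indication field to select COVID-19 reports.
#'
#' @return character vector of PT names.
#' @export
default_covid_smq_terms <- function() {
  c(
    "SARS-CoV-2 test positive", "COVID-19", "Exposure to SARS-CoV-2",
    "COVID-19 pneumonia", "Symptomatic COVID-19",
    "Occupational exposure to SARS-CoV-2", "COVID-19 treatment",
    "Coronavirus test positive", "Coronavirus infection",
    "COVID-19 immunization", "COVID-19 prophylaxis",
    "SARS-CoV-2 antibody test positive", "SARS-CoV-2 carrier",
    "SARS-CoV-2 sepsis", "SARS-CoV-2 test false negative",
    "SARS-CoV-2 viraemia"
  )
}

#' Cohort configuration
#'
#' @param smq_indication_terms PT names whose presence in the indication
#'   field selects a report into the cohort.
#' @param covid_drug_list ingredient identifiers considered COVID-19
#'   treatments (the drug-A side of every candidate pair).
#' @param excluded_socs SOC names whose HLTs are removed from the AE
#'   space; defaults to the six of [default_excluded_socs()].
#' @param epv_threshold minimum events-per-variable for a triple to be
#'   analyzable (default 5, boundary inclusive).
#' @param n_model_params number of non-intercept model parameters used as
#'   the EPV denominator; default 7 (drug A, drug B, interaction, age
#'   group, gender, two drug-count dummies).
#' @return a `cohort_config` object.
#' @export
cohort_config <- function(smq_indication_terms = default_covid_smq_terms(),
                          covid_drug_list,
                          excluded_socs = default_excluded_socs(),
                          epv_threshold = 5,
                          n_model_params = 7) {
  if (length(smq_indication_terms) == 0) {
    stop_faersddi("configuration error: empty SMQ indication term list")
  }
  if (missing(covid_drug_list) || length(covid_drug_list) == 0) {
    stop_faersddi("configuration error: empty COVID-19 drug list")
  }
  if (!is.numeric(epv_threshold) || epv_threshold <= 0) {
    stop_faersddi("configuration error: epv_threshold must be positive")
  }
  structure(
    list(
      smq_indication_terms = smq_indication_terms,
      covid_drug_list = unique(as.character(covid_drug_list)),
      excluded_socs = excluded_socs,
      epv_threshold = epv_threshold,
      n_model_params = n_model_params
    ),
    class = "cohort_config"
  )
}

#' Read a cohort configuration from YAML or JSON
#'
#' Recognized fields: `smq_indication_terms`, `covid_drug_list`,
#' `excluded_socs`, `epv_threshold`, `n_model_params`; absent fields take
#' the [cohort_config()] defaults.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return a `cohort_config` object.
#' @export
read_cohort_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  args <- raw[intersect(names(raw),
    c("smq_indication_terms", "covid_drug_list", "excluded_socs",
      "epv_threshold", "n_model_params"))]
  do.call(cohort_config, args)
}

subset_report_set <- function(rs, ids) {
  keep <- function(df) {
    out <- df[df$report_id %in% ids, , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  structure(
    list(reports = keep(rs$reports), ingredients = keep(rs$ingredients),
      aes = keep(rs$aes), indications = keep(rs$indications)),
    class = "report_set"
  )
}

#' Select reports with a cohort indication
#'
#' Retains exactly the reports whose indication terms intersect the SMQ
#' term list (case-insensitive exact match after whitespace
#' normalization).
#'
#' @param rs a `report_set`.
#' @param config a `cohort_config`.
#' @return the filtered `report_set` (a subset of the input).
#' @export
select_covid_reports <- function(rs, config) {
  stopifnot(inherits(rs, "report_set"), inherits(config, "cohort_config"))
  smq <- normalize_term(config$smq_indication_terms)
  hit <- rs$indications$report_id[
    normalize_term(rs$indications$term) %in% smq]
  subset_report_set(rs, unique(hit))
}

#' Roll adverse events up from PT to HLT and apply the SOC exclusion
#'
#' Each report's AE set of MedDRA PTs becomes a set of primary HLTs;
#' duplicate PTs under one HLT collapse. HLTs belonging to an excluded
#' SOC are removed. PTs not resolvable in the hierarchy are dropped and
#' tallied in the `unresolved_pts` attribute of the result.
#'
#' @param rs a `report_set` whose `$aes` terms are PTs.
#' @param hierarchy a `meddra_hierarchy`.
#' @param config a `cohort_config`.
#' @return a `report_set` whose `$aes` terms are HLTs, with attribute
#'   `unresolved_pts` (count of dropped PT rows).
#' @export
rollup_and_filter_aes <- function(rs, hierarchy, config) {
  stopifnot(inherits(rs, "report_set"), inherits(hierarchy, "meddra_hierarchy"))
  aes <- rs$aes
  hlt <- unname(hierarchy$pt_to_hlt[normalize_term(aes$term)])
  unresolved <- sum(is.na(hlt) & nrow(aes) > 0)
  if (unresolved > 0) {
    warning(unresolved, " AE PT row(s) not resolvable in the hierarchy; dropped",
      call. = FALSE)
  }
  out <- data.frame(report_id = aes$report_id[!is.na(hlt)],
    term = hlt[!is.na(hlt)], stringsAsFactors = FALSE)
  soc <- unname(hierarchy$hlt_to_soc[normalize_term(out$term)])
  excluded <- normalize_term(config$excluded_socs)
  out <- out[!(normalize_term(soc) %in% excluded), , drop = FALSE]
  out <- unique(out)
  out <- out[order(out$report_id, out$term), , drop = FALSE]
  rownames(out) <- NULL
  res <- rs
  res$aes <- out
  attr(res, "unresolved_pts") <- unresolved
  res
}

#' Partition observed drugs into COVID-19 drugs and co-medications
#'
#' COVID-19 drugs are the cohort-observed ingredients on the configured
#' treatment list; co-medications are all cohort-observed ingredients
#' (a COVID-19 drug can appear as the co-medication of a different
#' COVID-19 drug). A drug never pairs with itself.
#'
#' @param rs a `report_set`.
#' @param config a `cohort_config`.
#' @return list with sorted character vectors `covid` and `comed`.
#' @export
partition_drugs <- function(rs, config) {
  observed <- sort(unique(rs$ingredients$ingredient))
  list(
    covid = intersect(observed, config$covid_drug_list),
    comed = observed
  )
}

drug_count_bin <- function(n) {
  ifelse(n <= 2, "le2", ifelse(n <= 4, "b3_4", "ge5"))
}

triple_id <- function(a, b, e) paste(a, b, e, sep = " | ")

#' Construct a triple analysis dataset
#'
#' The analysis set for one (COVID-19 drug A, co-medication B, adverse
#' event E) combination: per-report exposure and outcome indicators with
#' covariates. The outcome-positive exposure cells (`n11`, `n10`, `n01`,
#' `n00`) and events-per-variable are computed from the rows.
#'
#' @param covid_drug,comed,ae_hlt identifiers of the combination.
#' @param rows data frame with columns `report_id`, `exposed_a`,
#'   `exposed_b`, `outcome`, `age65`, `male`, `bin3_4`, `bin_ge5`.
#' @param n_model_params EPV denominator (default 7).
#' @param n_excluded_missing count of reports dropped for missing
#'   age/gender before `rows` was built (bookkeeping only).
#' @return a `triple_dataset` object.
#' @export
triple_dataset <- function(covid_drug, comed, ae_hlt, rows,
                           n_model_params = 7, n_excluded_missing = 0) {
  need <- c("report_id", "exposed_a", "exposed_b", "outcome", "age65",
    "male", "bin3_4", "bin_ge5")
  missing_cols <- setdiff(need, names(rows))
  if (length(missing_cols)) {
    stop_faersddi("triple rows missing column(s) ",
      paste(missing_cols, collapse = ", "))
  }
  pos <- rows[rows$outcome == 1, , drop = FALSE]
  counts <- c(
    n11 = sum(pos$exposed_a == 1 & pos$exposed_b == 1),
    n10 = sum(pos$exposed_a == 1 & pos$exposed_b == 0),
    n01 = sum(pos$exposed_a == 0 & pos$exposed_b == 1),
    n00 = sum(pos$exposed_a == 0 & pos$exposed_b == 0)
  )
  structure(
    list(
      covid_drug = covid_drug, comed = comed, ae_hlt = ae_hlt,
      id = triple_id(covid_drug, comed, ae_hlt), rows = rows,
      counts = counts, n_events = nrow(pos),
      epv = nrow(pos) / n_model_params,
      n_excluded_missing = n_excluded_missing
    ),
    class = "triple_dataset"
  )
}

#' Enumerate analyzable (drug A, drug B, AE) triples
#'
#' For every combination of a COVID-19 drug A, a co-medication B (B
#' different from A) and an observed adverse event HLT E, builds the
#' per-report analysis rows over all complete-case cohort reports
#' (reports missing age or gender are excluded and tallied) and retains
#' the triple iff events-per-variable — outcome-positive reports divided
#' by the number of non-intercept model parameters — is at least
#' `epv_threshold` (boundary inclusive).
#'
#' @param rs a rolled-up, SOC-filtered `report_set`.
#' @param config a `cohort_config`.
#' @return list of `triple_dataset` objects, each with elements
#'   `covid_drug`, `comed`, `ae_hlt`, `id`, `rows` (columns `report_id`,
#'   `exposed_a`, `exposed_b`, `outcome`, `age65`, `male`, `bin3_4`,
#'   `bin_ge5`), `counts` (`n11`, `n10`, `n01`, `n00` among
#'   outcome-positive reports), `n_events`, `epv` and
#'   `n_excluded_missing`.
#' @export
enumerate_triples <- function(rs, config) {
  stopifnot(inherits(rs, "report_set"), inherits(config, "cohort_config"))
  rep_df <- rs$reports
  complete <- rep_df$age_group != "missing" & rep_df$gender != "missing"
  n_excluded <- sum(!complete)
  rep_df <- rep_df[complete, , drop = FALSE]
  ids <- rep_df$report_id
  if (length(ids) == 0) return(list())

  covar <- data.frame(
    report_id = ids,
    age65 = as.integer(rep_df$age_group == "over65_inclusive"),
    male = as.integer(rep_df$gender == "male"),
    stringsAsFactors = FALSE
  )
  bin <- drug_count_bin(rep_df$n_unique_ingredients)
  covar$bin3_4 <- as.integer(bin == "b3_4")
  covar$bin_ge5 <- as.integer(bin == "ge5")

  # exposure and outcome indicator lookups over the complete-case cohort
  ing <- rs$ingredients[rs$ingredients$report_id %in% ids, , drop = FALSE]
  aes <- rs$aes[rs$aes$report_id %in% ids, , drop = FALSE]
  exposed_ids <- split(ing$report_id, ing$ingredient)
  event_ids <- split(aes$report_id, aes$term)

  part <- partition_drugs(rs, config)
  min_events <- config$epv_threshold * config$n_model_params
  hlts <- names(event_ids)[lengths(event_ids) >= min_events]

  triples <- list()
  for (e in hlts) {
    outcome <- as.integer(ids %in% event_ids[[e]])
    n_events <- sum(outcome)
    for (a in part$covid) {
      xa <- as.integer(ids %in% exposed_ids[[a]])
      for (b in setdiff(part$comed, a)) {
        xb <- as.integer(ids %in% exposed_ids[[b]])
        rows <- data.frame(
          report_id = ids, exposed_a = xa, exposed_b = xb, outcome = outcome,
          age65 = covar$age65, male = covar$male, bin3_4 = covar$bin3_4,
          bin_ge5 = covar$bin_ge5, stringsAsFactors = FALSE
        )
        triples[[triple_id(a, b, e)]] <- triple_dataset(
          a, b, e, rows,
          n_model_params = config$n_model_params,
          n_excluded_missing = n_excluded
        )
      }
    }
  }
  triples
}

#' @export
print.triple_dataset <- function(x, ...) {
  cat("Triple: ", x$id, "\n  rows: ", nrow(x$rows), ", events: ", x$n_events,
    " (EPV ", format(x$epv, digits = 3), ")\n  outcome-positive cells: ",
    paste(names(x$counts), x$counts, sep = "=", collapse = ", "), "\n",
    sep = "")
  invisible(x)
}

#' Export triples as one long data frame
#'
#' @param triples list of `triple_dataset` objects.
#' @return data frame with a `triple_id` column followed by the per-report
#'   analysis rows.
#' @export
triples_to_long <- function(triples) {
  do.call(rbind, lapply(triples, function(t) {
    cbind(triple_id = t$id, t$rows, stringsAsFactors = FALSE)
  }))
}
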