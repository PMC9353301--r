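# Cohort summary tables, ATC/SOC groupings for interpretation, and the
# end-to-end pipeline driver.

#' Summarize a cohort in the style of a study population table
#'
#' Counts and percentages (of the total report count, rounded half-up to
#' two decimals) by gender within age group and drug-count bin, plus
#' per-COVID-drug report counts with a gender split. Reports with
#' missing age or gender appear in explicit `missing` rows when present.
#'
#' @param rs a `report_set` (the cohort).
#' @param config a `cohort_config` (supplies the COVID-19 drug list).
#' @return a `cohort_summary`: `total`, data frames `age_gender`,
#'   `drug_count`, `covid_drugs`.
#' @export
summarize_cohort <- function(rs, config) {
  stopifnot(inherits(rs, "report_set"), inherits(config, "cohort_config"))
  rep_df <- rs$reports
  total <- nrow(rep_df)

  cell <- function(mask) {
    f <- sum(mask & rep_df$gender == "female")
    m <- sum(mask & rep_df$gender == "male")
    t <- sum(mask)
    data.frame(
      female_n = f, female_pct = percent_of(f, total),
      male_n = m, male_pct = percent_of(m, total),
      total_n = t, total_pct = percent_of(t, total)
    )
  }

  age_levels <- c(under65 = "<65", over65_inclusive = ">=65",
    missing = "missing")
  present <- names(age_levels)[names(age_levels) %in%
    unique(rep_df$age_group) | names(age_levels) != "missing"]
  age_gender <- do.call(rbind, lapply(present, function(g) {
    cbind(group = age_levels[[g]], cell(rep_df$age_group == g))
  }))

  bins <- drug_count_bin(rep_df$n_unique_ingredients)
  bin_levels <- c(le2 = "<=2", b3_4 = "3-4", ge5 = ">=5")
  drug_count <- do.call(rbind, lapply(names(bin_levels), function(b) {
    cbind(group = bin_levels[[b]], cell(bins == b))
  }))

  covid_obs <- intersect(config$covid_drug_list,
    unique(rs$ingredients$ingredient))
  exposed <- split(rs$ingredients$report_id, rs$ingredients$ingredient)
  covid_drugs <- do.call(rbind, lapply(sort(covid_obs), function(d) {
    cbind(group = d, cell(rep_df$report_id %in% exposed[[d]]))
  }))
  rownames(age_gender) <- rownames(drug_count) <- NULL
  if (!is.null(covid_drugs)) rownames(covid_drugs) <- NULL

  structure(
    list(total = total, age_gender = age_gender, drug_count = drug_count,
      covid_drugs = covid_drugs %||% data.frame()),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary (n = ", x$total, ")\n\nAge\n", sep = "")
  print(x$age_gender, row.names = FALSE)
  cat("\nNumber of drug exposures\n")
  print(x$drug_count, row.names = FALSE)
  if (nrow(x$covid_drugs)) {
    cat("\nCOVID-19 treatments\n")
    print(x$covid_drugs, row.names = FALSE)
  }
  invisible(x)
}

#' Flatten a cohort summary to one data frame
#'
#' @param summary a `cohort_summary`.
#' @return data frame with a `section` column.
#' @export
cohort_summary_table <- function(summary) {
  out <- rbind(
    cbind(section = "age", summary$age_gender),
    cbind(section = "drug_count", summary$drug_count),
    if (nrow(summary$covid_drugs)) {
      cbind(section = "covid_drug", summary$covid_drugs)
    }
  )
  rownames(out) <- NULL
  out
}

#' Read an ATC level-1 map from CSV
#'
#' Expects columns `ingredient_id`, `atc1_code`; an ingredient may carry
#' several level-1 codes (one row each).
#'
#' @param path CSV file path.
#' @return data frame.
#' @export
read_atc_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
    colClasses = "character")
  need <- c("ingredient_id", "atc1_code")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop_faersddi("ATC map '", basename(path), "' missing column(s) ",
      paste(missing_cols, collapse = ", "))
  }
  unique(df[, need])
}

#' Group signals by ATC level-1 class and adverse event SOC
#'
#' Co-medications are counted once per ATC level-1 class they belong to
#' (an ingredient with several level-1 codes contributes to each);
#' co-medications on the COVID-19 drug list are assigned to a dedicated
#' `COVID-19` category instead of their ATC class; co-medications absent
#' from the map fall into `unmapped`. Adverse events are counted per
#' SOC over signal combinations.
#'
#' @param signals data frame of signal rows (from [results_table()],
#'   filtered to `signal == TRUE`) with columns `comed` and `ae_hlt`.
#' @param atc_map data frame `ingredient_id`, `atc1_code`.
#' @param hierarchy a `meddra_hierarchy`.
#' @param config a `cohort_config`.
#' @return list of data frames `comed_by_atc` (unique co-medications per
#'   class) and `ae_by_soc` (signal combinations per SOC).
#' @export
group_for_interpretation <- function(signals, atc_map, hierarchy, config) {
  comeds <- unique(signals$comed)
  classes_of <- function(d) {
    if (d %in% config$covid_drug_list) return("COVID-19")
    codes <- atc_map$atc1_code[atc_map$ingredient_id == d]
    if (length(codes) == 0) "unmapped" else unique(codes)
  }
  cls <- unlist(lapply(comeds, classes_of))
  comed_by_atc <- as.data.frame(table(atc1 = cls),
    stringsAsFactors = FALSE)
  names(comed_by_atc) <- c("atc1", "n_comeds")

  soc <- unname(hierarchy$hlt_to_soc[normalize_term(signals$ae_hlt)])
  soc[is.na(soc)] <- "unmapped"
  ae_by_soc <- as.data.frame(table(soc = soc), stringsAsFactors = FALSE)
  names(ae_by_soc) <- c("soc", "n_signals")

  list(comed_by_atc = comed_by_atc, ae_by_soc = ae_by_soc)
}

#' Run the full signal-detection pipeline
#'
#' Ingest (or accept pre-normalized reports) → cohort selection → AE
#' rollup and SOC exclusion → triple enumeration under the EPV rule →
#' Firth interaction fits with additive and multiplicative verdicts →
#' age/gender disparity models for signal triples → reference
#' concordance and Monte Carlo empirical p-value → summary tables. All
#' outputs are written under `out_dir` (`signals.csv`, `strata.csv`,
#' `concordance.csv`, `empirical_p.json`, `cohort_summary.csv`,
#' `run_log.txt`).
#'
#' @param faers_paths named list with elements `demo`, `drug`, `reac`,
#'   `indi`, `outc`, `name_map` (file paths), or `NULL` if `reports` is
#'   given directly.
#' @param reports optionally, a pre-normalized `report_set` (bypasses
#'   ingestion).
#' @param hierarchy_path path to the MedDRA hierarchy CSV.
#' @param reference_path path to the reference DDI CSV.
#' @param config a `cohort_config` or path to one (YAML/JSON).
#' @param out_dir output directory.
#' @param atc_map_path optional ATC map CSV for interpretation tables.
#' @param n_sims Monte Carlo simulations (default 1000).
#' @param seed seed for the Monte Carlo stream (default 1).
#' @param alpha significance level (default 0.05).
#' @param dialect a [faers_dialect()].
#' @return (invisibly) a list with every intermediate object: `cohort`,
#'   `triples`, `results`, `signals`, `pairs`, `concordance`,
#'   `empirical_p`, `summary`, `strata`, `log`.
#' @export
run_pipeline <- function(faers_paths = NULL, reports = NULL,
                         hierarchy_path, reference_path, config,
                         out_dir, atc_map_path = NULL, n_sims = 1000,
                         seed = 1, alpha = 0.05,
                         dialect = faers_dialect()) {
  if (is.character(config)) config <- read_cohort_config(config)
  stopifnot(inherits(config, "cohort_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  note("pipeline seed: ", seed, "; alpha: ", alpha)

  if (is.null(reports)) {
    if (is.null(faers_paths)) {
      stop_faersddi("ingest stage: provide faers_paths or reports")
    }
    cases <- read_faers_tables(faers_paths$demo, faers_paths$drug,
      faers_paths$reac, faers_paths$indi, faers_paths$outc, dialect)
    note("ingest: ", nrow(cases$demo), " raw report(s), ",
      sum(cases$orphan_rows), " orphan row(s)")
    cases <- deduplicate_cases(cases)
    note("deduplicate: ", nrow(cases$demo), " report(s)")
    norm <- normalize_reports(cases, read_drug_name_map(faers_paths$name_map))
    reports <- norm$reports
    note("normalize: drug-name coverage ",
      format(norm$stats$coverage, digits = 4))
  }
  note("reports: ", nrow(reports$reports))

  cohort <- select_covid_reports(reports, config)
  note("cohort (indication SMQ): ", nrow(cohort$reports), " report(s)")
  hierarchy <- read_meddra_hierarchy(hierarchy_path)
  cohort <- rollup_and_filter_aes(cohort, hierarchy, config)
  note("AE rollup: ", length(unique(cohort$aes$term)),
    " HLT(s) after SOC exclusion; ", attr(cohort, "unresolved_pts"),
    " unresolved PT row(s)")

  triples <- enumerate_triples(cohort, config)
  note("triples retained at EPV >= ", config$epv_threshold, ": ",
    length(triples))

  results <- analyze_triples(triples, alpha = alpha)
  signals_tab <- results_table(results)
  n_failed <- sum(!is.na(signals_tab$error))
  note("fits: ", nrow(signals_tab) - n_failed, " ok, ", n_failed,
    " aborted")
  signals <- signals_tab[signals_tab$signal, , drop = FALSE]
  note("signals: ", nrow(signals), " combination(s)")
  utils::write.csv(signals_tab, file.path(out_dir, "signals.csv"),
    row.names = FALSE)

  strata <- list()
  for (id in signals$triple_id) {
    for (v in c("age", "gender")) {
      s <- tryCatch(
        suppressWarnings(stratified_disparity(triples[[id]], v,
          alpha = alpha)),
        error = function(e) NULL)
      if (!is.null(s)) strata[[paste(id, v)]] <- s
    }
  }
  strata_tab <- if (length(strata)) strata_table(strata) else
    data.frame()
  utils::write.csv(strata_tab, file.path(out_dir, "strata.csv"),
    row.names = FALSE)
  note("disparity models: ", length(strata))

  reference <- read_reference_ddi(reference_path)
  pairs <- signal_pairs(signals)
  note("unique unordered signal pairs: ", nrow(pairs))
  concordance <- compare_reference(pairs, reference)
  utils::write.csv(concordance$pairs, file.path(out_dir, "concordance.csv"),
    row.names = FALSE)
  note("concordance: ", concordance$n_documented, " documented, ",
    concordance$n_reference_nonsignificant, " reference-nonsignificant, ",
    concordance$n_not_covered, " not covered")

  part <- partition_drugs(cohort, config)
  empirical_p <- if (nrow(pairs) >= 1 && length(part$covid) >= 1 &&
    length(part$comed) >= 2) {
    monte_carlo_empirical_p(pairs, part$covid, part$comed, reference,
      n_sims = n_sims, seed = seed)
  } else NULL
  if (!is.null(empirical_p)) {
    write_empirical_p(empirical_p, file.path(out_dir, "empirical_p.json"))
    note("empirical p-value: ", format(empirical_p$p, digits = 6),
      " (r = ", empirical_p$r, ", n = ", empirical_p$n, ")")
  } else {
    note("empirical p-value: skipped (no signal pairs)")
  }

  summary <- summarize_cohort(cohort, config)
  utils::write.csv(cohort_summary_table(summary),
    file.path(out_dir, "cohort_summary.csv"), row.names = FALSE)

  grouping <- if (!is.null(atc_map_path)) {
    group_for_interpretation(signals, read_atc_map(atc_map_path),
      hierarchy, config)
  } else NULL
  if (!is.null(grouping)) {
    utils::write.csv(grouping$comed_by_atc,
      file.path(out_dir, "comed_by_atc.csv"), row.names = FALSE)
    utils::write.csv(grouping$ae_by_soc,
      file.path(out_dir, "ae_by_soc.csv"), row.names = FALSE)
  }

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(
    cohort = cohort, triples = triples, results = results,
    signals_table = signals_tab, signals = signals, pairs = pairs,
    concordance = concordance, empirical_p = empirical_p,
    summary = summary, strata = strata, grouping = grouping,
    log = log_lines
  ))
}
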