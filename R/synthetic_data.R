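# Synthetic spontaneous-report generator. Reports are drawn from the same
# logistic interaction model the pipeline fits: demographics and drug
# exposures are independent Bernoulli draws, and each adverse event fires
# with probability plogis(b0 + b1*A + b2*B + b3*A*B + covariate effects).
# A fixture writer emits the generated reports back out in the
# "$"-delimited quarterly dialect — with messy verbatim drug names,
# planted duplicate case versions and unmapped junk rows — so the
# ingestion stage is testable end to end.

default_toy_meddra <- function() {
  rbind(
    data.frame(
      pt = c("Atrioventricular block", "Bundle branch block left"),
      hlt = "Cardiac conduction disorders",
      hlgt = "Cardiac arrhythmias", soc = "Cardiac disorders",
      stringsAsFactors = FALSE
    ),
    data.frame(
      pt = c("Tachycardia", "Bradycardia"),
      hlt = "Rate and rhythm disorders NEC",
      hlgt = "Cardiac arrhythmias", soc = "Cardiac disorders",
      stringsAsFactors = FALSE
    ),
    data.frame(
      pt = c("Acute kidney injury", "Renal failure"),
      hlt = "Renal failure and impairment",
      hlgt = "Nephropathies and tubular disorders",
      soc = "Renal and urinary disorders", stringsAsFactors = FALSE
    ),
    data.frame(
      pt = c("Thrombocytopenia", "Immune thrombocytopenia"),
      hlt = "Thrombocytopenias",
      hlgt = "Platelet disorders",
      soc = "Blood and lymphatic system disorders", stringsAsFactors = FALSE
    ),
    data.frame(
      pt = c("Drug ineffective", "Condition aggravated"),
      hlt = "Therapeutic and nontherapeutic effects NEC",
      hlgt = "Therapeutic and nontherapeutic responses",
      soc = "General disorders and administration site conditions",
      stringsAsFactors = FALSE
    )
  )
}

default_planted_effects <- function() {
  data.frame(
    covid_drug = c("remdesivir", "hydroxychloroquine"),
    comed = c("metformin", "azithromycin"),
    ae_hlt = c("Renal failure and impairment", "Cardiac conduction disorders"),
    b1 = c(log(1.5), log(1.4)),
    b2 = c(log(1.3), log(1.4)),
    b3 = c(log(2), log(1.8)),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration for synthetic report sets
#'
#' Defaults describe a desk-scale analogue of a COVID-19
#' spontaneous-report cohort: demographic marginals follow the published
#' cohort (52.7% male, 46.25% aged 65 or over), drug exposure
#' probabilities echo the usage shares of the most-reported COVID-19
#' treatments, adverse events are rare (baseline probability 5%), and
#' two interaction effects are planted — one strong
#' (\eqn{\beta_3 = \ln 2}) and one moderate — with everything else null.
#' The default cohort size of 10,000 reports is the operating point at
#' which a planted \eqn{\beta_3 = \ln 2} is recoverable with power of
#' at least 0.8.
#'
#' @param n_reports number of reports (default 10000).
#' @param covid_drugs named numeric vector: exposure probability per
#'   COVID-19 drug ingredient.
#' @param comeds named numeric vector: exposure probability per
#'   co-medication ingredient (names disjoint from `covid_drugs`).
#' @param meddra toy hierarchy data frame (`pt`, `hlt`, `hlgt`, `soc`);
#'   generated AEs are recorded as random PT children of the fired HLT.
#' @param ae_hlts HLT names generated as outcomes (default: all HLTs in
#'   `meddra`).
#' @param baseline_logit scalar or vector named by HLT: \eqn{\beta_0}
#'   per adverse event (default `qlogis(0.05)`).
#' @param covariate_effects numeric vector `c(age65=, male=, bin3_4=,
#'   bin_ge5=)` applied to every AE's logit.
#' @param planted_effects data frame (`covid_drug`, `comed`, `ae_hlt`,
#'   `b1`, `b2`, `b3`) of interaction effects; all unplanted drug terms
#'   are zero.
#' @param p_over65,p_male demographic probabilities.
#' @param p_missing_age,p_missing_gender probability a report lacks the
#'   field (default 0.02 each).
#' @param covid_indication_prob probability a report carries a COVID-19
#'   indication term (others get a non-COVID indication; default 0.8).
#' @param dup_case_prob probability the fixture writer emits one (or,
#'   rarely, two) superseded earlier versions of a case (default 0.1).
#' @param unmapped_row_prob probability of an extra junk drug row whose
#'   verbatim name has no ingredient mapping (default 0.05).
#' @param seed integer seed fixing the whole stream.
#' @return a `simulation_config` object.
#' @export
simulation_config <- function(n_reports = 10000,
                              covid_drugs = c(
                                hydroxychloroquine = 0.18,
                                remdesivir = 0.18, azithromycin = 0.15,
                                enoxaparin = 0.11, dexamethasone = 0.11),
                              comeds = c(
                                metformin = 0.20, atorvastatin = 0.18,
                                furosemide = 0.15, ceftriaxone = 0.12,
                                heparin = 0.10, oseltamivir = 0.08),
                              meddra = default_toy_meddra(),
                              ae_hlts = NULL,
                              baseline_logit = stats::qlogis(0.05),
                              covariate_effects = c(age65 = 0.3, male = 0.1,
                                bin3_4 = 0.15, bin_ge5 = 0.3),
                              planted_effects = default_planted_effects(),
                              p_over65 = 0.4625, p_male = 0.527,
                              p_missing_age = 0.02, p_missing_gender = 0.02,
                              covid_indication_prob = 0.8,
                              dup_case_prob = 0.1,
                              unmapped_row_prob = 0.05,
                              seed = 20201) {
  if (is.null(ae_hlts)) ae_hlts <- unique(meddra$hlt)
  probs <- c(covid_drugs, comeds, p_over65, p_male, p_missing_age,
    p_missing_gender, covid_indication_prob, dup_case_prob,
    unmapped_row_prob)
  if (any(probs < 0 | probs > 1)) {
    stop_faersddi("all probabilities must lie in [0, 1]")
  }
  if (length(covid_drugs) == 0 || length(comeds) == 0) {
    stop_faersddi("drug catalogs must be non-empty")
  }
  if (length(intersect(names(covid_drugs), names(comeds)))) {
    stop_faersddi("covid_drugs and comeds catalogs must be disjoint")
  }
  if (length(baseline_logit) == 1 && is.null(names(baseline_logit))) {
    baseline_logit <- stats::setNames(rep(baseline_logit, length(ae_hlts)),
      ae_hlts)
  }
  all_drugs <- c(names(covid_drugs), names(comeds))
  if (nrow(planted_effects)) {
    planted_drugs <- c(planted_effects$covid_drug, planted_effects$comed)
    if (!all(planted_drugs %in% all_drugs)) {
      stop_faersddi("planted effect references a drug missing from catalogs")
    }
    if (any(c(covid_drugs, comeds)[planted_drugs] == 0)) {
      stop_faersddi("planted drug has exposure probability 0")
    }
    if (!all(planted_effects$ae_hlt %in% ae_hlts)) {
      stop_faersddi("planted effect references an AE outside ae_hlts")
    }
  }
  structure(
    list(
      n_reports = n_reports, covid_drugs = covid_drugs, comeds = comeds,
      meddra = meddra, ae_hlts = ae_hlts, baseline_logit = baseline_logit,
      covariate_effects = covariate_effects,
      planted_effects = planted_effects, p_over65 = p_over65,
      p_male = p_male, p_missing_age = p_missing_age,
      p_missing_gender = p_missing_gender,
      covid_indication_prob = covid_indication_prob,
      dup_case_prob = dup_case_prob,
      unmapped_row_prob = unmapped_row_prob, seed = seed
    ),
    class = "simulation_config"
  )
}

#' Read a simulation configuration from YAML
#'
#' Scalar fields override the [simulation_config()] defaults;
#' `covid_drugs`/`comeds` are given as name: probability maps and
#' `planted_effects` as a list of records.
#'
#' @param path YAML file.
#' @return a `simulation_config`.
#' @export
read_simulation_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (fld in c("covid_drugs", "comeds", "covariate_effects",
    "baseline_logit")) {
    if (!is.null(raw[[fld]])) raw[[fld]] <- unlist(raw[[fld]])
  }
  for (fld in c("planted_effects", "meddra")) {
    if (!is.null(raw[[fld]])) {
      raw[[fld]] <- do.call(rbind, lapply(raw[[fld]], function(row) {
        as.data.frame(row, stringsAsFactors = FALSE)
      }))
    }
  }
  args <- raw[intersect(names(raw), names(formals(simulation_config)))]
  do.call(simulation_config, args)
}

covid_smq_sample_terms <- function() {
  c("COVID-19", "SARS-CoV-2 test positive", "COVID-19 pneumonia")
}

#' Generate a synthetic report set
#'
#' Draws demographics, independent Bernoulli drug exposures, a COVID-19
#' (or background) indication, and per-HLT adverse events from the
#' logistic interaction model, then returns the normalized `report_set`
#' together with a ground-truth ledger. Fully reproducible under
#' `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return a `ddi_simulation`: `reports` (a `report_set` whose AE terms
#'   are PTs), `truth` (planted effects, per-report latent COVID flag,
#'   per-report latent demographics used in the model), `case_info`
#'   (caseid/caseversion layout for the fixture writer), and `config`.
#' @export
generate_reports <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_reports

  # case layout: a fraction of cases will be written with superseded
  # earlier versions; report_id is the primaryid of the final version
  caseid <- sprintf("%07d", 1000000 + seq_len(n))
  extra <- stats::rbinom(n, 1, config$dup_case_prob) +
    stats::rbinom(n, 1, 0.2 * config$dup_case_prob)
  caseversion <- 1L + extra
  report_id <- paste0(caseid, caseversion)

  over65 <- stats::rbinom(n, 1, config$p_over65)
  male <- stats::rbinom(n, 1, config$p_male)
  age <- ifelse(over65 == 1, sample(65:95, n, replace = TRUE),
    sample(18:64, n, replace = TRUE))
  age[stats::runif(n) < config$p_missing_age] <- NA
  gender <- ifelse(male == 1, "male", "female")
  gender[stats::runif(n) < config$p_missing_gender] <- "missing"

  probs <- c(config$covid_drugs, config$comeds)
  drugs <- names(probs)
  exposure <- matrix(stats::runif(n * length(drugs)) <
    rep(probs, each = n), nrow = n,
    dimnames = list(NULL, drugs))
  n_ing <- rowSums(exposure)
  bin <- drug_count_bin(n_ing)
  cov_eff <- config$covariate_effects
  eta_cov <- cov_eff[["age65"]] * over65 + cov_eff[["male"]] * male +
    cov_eff[["bin3_4"]] * (bin == "b3_4") +
    cov_eff[["bin_ge5"]] * (bin == "ge5")

  pts_by_hlt <- split(config$meddra$pt, config$meddra$hlt)
  ae_rows <- list()
  for (e in config$ae_hlts) {
    eta <- config$baseline_logit[[e]] + eta_cov
    planted <- config$planted_effects[config$planted_effects$ae_hlt == e, ,
      drop = FALSE]
    for (j in seq_len(nrow(planted))) {
      xa <- exposure[, planted$covid_drug[j]]
      xb <- exposure[, planted$comed[j]]
      eta <- eta + planted$b1[j] * xa + planted$b2[j] * xb +
        planted$b3[j] * xa * xb
    }
    hit <- stats::runif(n) < stats::plogis(eta)
    if (any(hit)) {
      ae_rows[[e]] <- data.frame(
        report_id = report_id[hit],
        term = sample(pts_by_hlt[[e]], sum(hit), replace = TRUE),
        stringsAsFactors = FALSE
      )
    }
  }
  aes <- do.call(rbind, ae_rows) %||%
    data.frame(report_id = character(0), term = character(0))
  aes <- unique(aes)
  aes <- aes[order(aes$report_id, aes$term), , drop = FALSE]
  rownames(aes) <- NULL

  covid_flag <- stats::runif(n) < config$covid_indication_prob
  ind_term <- ifelse(covid_flag,
    sample(covid_smq_sample_terms(), n, replace = TRUE), "Hypertension")
  indications <- data.frame(report_id = report_id, term = ind_term,
    stringsAsFactors = FALSE)
  indications <- indications[order(indications$report_id, indications$term), ,
    drop = FALSE]
  rownames(indications) <- NULL

  ing_idx <- which(exposure, arr.ind = TRUE)
  ingredients <- data.frame(
    report_id = report_id[ing_idx[, 1]],
    ingredient = drugs[ing_idx[, 2]], stringsAsFactors = FALSE
  )
  ingredients <- ingredients[order(ingredients$report_id,
    ingredients$ingredient), , drop = FALSE]
  rownames(ingredients) <- NULL

  reports <- data.frame(
    report_id = report_id,
    age_years = as.numeric(age),
    age_group = age_group_of(as.numeric(age)),
    gender = gender,
    n_unique_ingredients = as.integer(n_ing),
    stringsAsFactors = FALSE
  )

  structure(
    list(
      reports = report_set(reports, ingredients, aes, indications),
      truth = list(
        planted_effects = config$planted_effects,
        covid_flag = data.frame(report_id = report_id,
          covid = covid_flag, stringsAsFactors = FALSE),
        latent = data.frame(report_id = report_id, over65 = over65,
          male = male, stringsAsFactors = FALSE)
      ),
      case_info = data.frame(caseid = caseid, caseversion = caseversion,
        report_id = report_id, stringsAsFactors = FALSE),
      config = config
    ),
    class = "ddi_simulation"
  )
}

# messy verbatim variants for one ingredient name
name_variants <- function(ingredient) {
  c(ingredient, paste0(toupper(ingredient), "."),
    paste0(ingredient, " 100MG TABLET"))
}

#' Build the toy drug-name map for a simulation
#'
#' Every catalog ingredient gets three verbatim variants (the plain
#' name, an upper-cased dotted form, and a strength-qualified form), all
#' mapping to the ingredient identifier itself.
#'
#' @param config a `simulation_config`.
#' @return data frame `verbatim_name`, `rxnorm_ingredient_id`,
#'   `ingredient_name`.
#' @export
simulation_name_map_table <- function(config) {
  ing <- c(names(config$covid_drugs), names(config$comeds))
  data.frame(
    verbatim_name = unlist(lapply(ing, name_variants)),
    rxnorm_ingredient_id = rep(ing, each = 3),
    ingredient_name = rep(ing, each = 3),
    stringsAsFactors = FALSE
  )
}

#' Build the toy reference DDI table for a simulation
#'
#' Planted interaction pairs are graded `potential` (the strongest
#' planted pair `do_not_coadminister`); the remaining candidate pairs
#' are split deterministically between `no_interaction`,
#' `potential_weak` and absent-from-reference, mimicking the skew of a
#' curated interaction database.
#'
#' @param config a `simulation_config`.
#' @return data frame `drug_a`, `drug_b`, `grade`.
#' @export
simulation_reference_table <- function(config) {
  planted <- config$planted_effects
  rows <- list()
  if (nrow(planted)) {
    strongest <- which.max(planted$b3)
    rows[[1]] <- data.frame(
      drug_a = planted$covid_drug,
      drug_b = planted$comed,
      grade = ifelse(seq_len(nrow(planted)) == strongest,
        "do_not_coadminister", "potential"),
      stringsAsFactors = FALSE
    )
  }
  covid <- names(config$covid_drugs)
  comed <- names(config$comeds)
  grid <- expand.grid(drug_a = covid, drug_b = comed,
    stringsAsFactors = FALSE)
  grid <- grid[!(pair_key(grid$drug_a, grid$drug_b) %in%
    if (nrow(planted)) pair_key(planted$covid_drug, planted$comed)
    else character(0)), , drop = FALSE]
  # deterministic split: every 3rd pair no_interaction, every 7th weak,
  # the rest uncovered
  idx <- seq_len(nrow(grid))
  keep <- idx %% 3 == 0 | idx %% 7 == 0
  grid <- grid[keep, , drop = FALSE]
  grid$grade <- ifelse(seq_len(nrow(grid)) %% 4 == 0, "potential_weak",
    "no_interaction")
  out <- rbind(do.call(rbind, rows), grid)
  rownames(out) <- NULL
  out
}

#' Build a toy ATC level-1 map for a simulation
#'
#' Ingredients from the default catalogs get their real anatomical main
#' group; anything else is assigned a level-1 code deterministically
#' from its name. A handful of co-medications are given a second
#' level-1 code so the one-count-per-class rule is exercised.
#'
#' @param config a `simulation_config`.
#' @return data frame `ingredient_id`, `atc1_code`.
#' @export
simulation_atc_map_table <- function(config) {
  known <- c(
    metformin = "A", atorvastatin = "C", furosemide = "C",
    ceftriaxone = "J", heparin = "B", oseltamivir = "J",
    hydroxychloroquine = "P", remdesivir = "J", azithromycin = "J",
    enoxaparin = "B", dexamethasone = "H"
  )
  second <- c(heparin = "C", dexamethasone = "S")
  ing <- c(names(config$covid_drugs), names(config$comeds))
  code <- ifelse(ing %in% names(known), known[ing],
    LETTERS[(vapply(ing, function(s) sum(utf8ToInt(s)), 1) %% 14) + 1])
  out <- data.frame(ingredient_id = ing, atc1_code = unname(code),
    stringsAsFactors = FALSE)
  extra <- ing[ing %in% names(second)]
  if (length(extra)) {
    out <- rbind(out, data.frame(ingredient_id = extra,
      atc1_code = unname(second[extra]), stringsAsFactors = FALSE))
  }
  out[order(out$ingredient_id, out$atc1_code), , drop = FALSE]
}

#' Write a simulation out as FAERS-dialect fixture files
#'
#' Emits the five `$`-delimited quarterly tables plus the mapping
#' fixtures (`drug_name_map.csv`, `meddra.csv`, `reference_ddi.csv`).
#' The writer plants the ingestion hazards the parser must survive:
#' messy verbatim drug names, superseded earlier case versions (dropped
#' by deduplication), unmapped junk drug rows (dropped by
#' normalization), and ages expressed in months for a subset of
#' reports. Reading the files back through
#' [read_faers_tables()] → [deduplicate_cases()] → [normalize_reports()]
#' reproduces `sim$reports` exactly.
#'
#' @param sim a `ddi_simulation` from [generate_reports()].
#' @param dir output directory.
#' @return named list of file paths, invisibly.
#' @export
generate_fixture_tables <- function(sim, dir) {
  stopifnot(inherits(sim, "ddi_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  config <- sim$config
  set.seed(config$seed + 1L)

  name_map <- simulation_name_map_table(config)
  utils::write.csv(name_map, file.path(dir, "drug_name_map.csv"),
    row.names = FALSE)
  utils::write.csv(config$meddra, file.path(dir, "meddra.csv"),
    row.names = FALSE)
  utils::write.csv(simulation_reference_table(config),
    file.path(dir, "reference_ddi.csv"), row.names = FALSE)
  utils::write.csv(simulation_atc_map_table(config),
    file.path(dir, "atc_map.csv"), row.names = FALSE)

  rs <- sim$reports
  info <- sim$case_info
  n <- nrow(info)

  # one row per (case, version); the final version is authoritative
  case_idx <- rep(seq_len(n), info$caseversion)
  version <- sequence(info$caseversion)
  is_final <- version == info$caseversion[case_idx]
  pid <- paste0(info$caseid[case_idx], version)
  rep_row <- rs$reports[case_idx, ]

  in_months <- !is.na(rep_row$age_years) &
    stats::runif(length(pid)) < 0.2
  demo <- data.frame(
    primaryid = pid,
    caseid = info$caseid[case_idx],
    caseversion = version,
    age = ifelse(is.na(rep_row$age_years), "",
      ifelse(in_months, as.character(rep_row$age_years * 12),
        as.character(rep_row$age_years))),
    age_cod = ifelse(is.na(rep_row$age_years), "",
      ifelse(in_months, "MON", "YR")),
    sex = ifelse(rep_row$gender == "female", "F",
      ifelse(rep_row$gender == "male", "M", "")),
    stringsAsFactors = FALSE
  )

  # drug rows: full ingredient list for final versions with messy
  # verbatim variants; earlier versions carry only the first ingredient
  final_pid <- stats::setNames(pid[is_final],
    info$report_id[case_idx[is_final]])
  ing <- rs$ingredients
  variant_pick <- sample.int(3, nrow(ing), replace = TRUE)
  variants <- vapply(seq_len(nrow(ing)), function(j) {
    name_variants(ing$ingredient[j])[variant_pick[j]]
  }, "")
  drug_final <- data.frame(
    primaryid = unname(final_pid[ing$report_id]),
    drugname = variants,
    role_cod = sample(c("PS", "SS", "C"), nrow(ing), replace = TRUE),
    stringsAsFactors = FALSE
  )
  first_ing <- ing[!duplicated(ing$report_id), , drop = FALSE]
  old_rows <- which(!is_final)
  old_rid <- info$report_id[case_idx[old_rows]]
  old_has_ing <- old_rid %in% first_ing$report_id
  drug_old <- data.frame(
    primaryid = pid[old_rows][old_has_ing],
    drugname = stats::setNames(first_ing$ingredient,
      first_ing$report_id)[old_rid[old_has_ing]],
    role_cod = rep("PS", sum(old_has_ing)), stringsAsFactors = FALSE
  )
  junk <- is_final & stats::runif(length(pid)) < config$unmapped_row_prob
  drug_junk <- data.frame(
    primaryid = pid[junk],
    drugname = if (any(junk)) paste("UNSPECIFIED PRODUCT", which(junk))
      else character(0),
    role_cod = rep("C", sum(junk)), stringsAsFactors = FALSE
  )
  drug <- rbind(drug_final, drug_old, drug_junk)
  drug <- drug[order(drug$primaryid), , drop = FALSE]

  # reactions and indications repeat on every version of a case
  versions_of <- split(pid, info$report_id[case_idx])
  expand_versions <- function(long_df, value_col, out_col) {
    if (nrow(long_df) == 0) {
      return(stats::setNames(
        data.frame(primaryid = character(0), value = character(0),
          stringsAsFactors = FALSE),
        c("primaryid", out_col)))
    }
    reps <- lengths(versions_of[long_df$report_id])
    data.frame(
      primaryid = unlist(versions_of[long_df$report_id], use.names = FALSE),
      value = rep(long_df[[value_col]], reps),
      stringsAsFactors = FALSE
    ) |> stats::setNames(c("primaryid", out_col))
  }
  reac <- expand_versions(rs$aes, "term", "pt")
  indi <- expand_versions(rs$indications, "term", "indi_pt")
  outc <- data.frame(primaryid = pid, outc_cod = "OT",
    stringsAsFactors = FALSE)

  wr <- function(df, file) {
    path <- file.path(dir, file)
    utils::write.table(df, path, sep = "$", quote = FALSE,
      row.names = FALSE)
    path
  }
  paths <- list(
    demo = wr(demo, "DEMO20Q1.txt"),
    drug = wr(drug, "DRUG20Q1.txt"),
    reac = wr(reac, "REAC20Q1.txt"),
    indi = wr(indi, "INDI20Q1.txt"),
    outc = wr(outc, "OUTC20Q1.txt"),
    name_map = file.path(dir, "drug_name_map.csv"),
    meddra = file.path(dir, "meddra.csv"),
    reference = file.path(dir, "reference_ddi.csv"),
    atc_map = file.path(dir, "atc_map.csv")
  )
  invisible(paths)
}
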