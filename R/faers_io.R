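# Ingestion of FAERS-style quarterly ASCII tables: parse, join by report,
# deduplicate cases, and normalize verbatim drug names to ingredients.

#' FAERS ASCII dialect description
#'
#' FAERS quarterly files are `$`-delimited text with a header row. Both
#' properties are configurable for equivalent exports.
#'
#' @param delim field delimiter (default `"$"`).
#' @param header logical; whether files carry a header row.
#' @return a `faers_dialect` list.
#' @export
faers_dialect <- function(delim = "$", header = TRUE) {
  structure(list(delim = delim, header = header), class = "faers_dialect")
}

read_faers_file <- function(path, required, dialect, label) {
  if (!file.exists(path)) {
    stop_faersddi("cannot read ", label, " file: '", path, "' does not exist")
  }
  df <- utils::read.table(path,
    sep = dialect$delim, header = dialect$header, quote = "",
    comment.char = "", colClasses = "character", stringsAsFactors = FALSE,
    strip.white = TRUE, fill = TRUE
  )
  names(df) <- tolower(names(df))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop_faersddi(
      "parse error in ", label, " file '", basename(path),
      "': missing column(s) ", paste(missing_cols, collapse = ", ")
    )
  }
  df
}

#' Read FAERS-style quarterly ASCII tables
#'
#' Parses the five per-quarter tables (demographics, drugs, reactions,
#' indications, outcomes) and joins the long tables to reports by
#' `primaryid`. One raw case record is produced per `primaryid` in the
#' demographics table; long rows referencing a `primaryid` absent from
#' demographics are dropped and tallied as orphans, never fatal.
#'
#' Expected columns (case-insensitive): demographics `primaryid, caseid,
#' caseversion, age, age_cod, sex`; drug `primaryid, drugname, role_cod`;
#' reaction `primaryid, pt`; indication `primaryid, indi_pt`; outcome
#' `primaryid, outc_cod`.
#'
#' @param demo_path,drug_path,reac_path,indi_path,outc_path file paths.
#' @param dialect a [faers_dialect()].
#' @return a `faers_cases` object: `$demo` (one row per report), long
#'   tables `$drugs`, `$reactions`, `$indications`, `$outcomes`, and
#'   `$orphan_rows`, a named count of dropped orphan rows per table.
#' @export
read_faers_tables <- function(demo_path, drug_path, reac_path, indi_path,
                              outc_path, dialect = faers_dialect()) {
  demo <- read_faers_file(
    demo_path, c("primaryid", "caseid", "caseversion", "age", "age_cod", "sex"),
    dialect, "demographics"
  )
  drugs <- read_faers_file(drug_path, c("primaryid", "drugname", "role_cod"),
    dialect, "drug")
  reac <- read_faers_file(reac_path, c("primaryid", "pt"), dialect, "reaction")
  indi <- read_faers_file(indi_path, c("primaryid", "indi_pt"),
    dialect, "indication")
  outc <- read_faers_file(outc_path, c("primaryid", "outc_cod"),
    dialect, "outcome")

  demo <- data.frame(
    primaryid = demo$primaryid,
    caseid = demo$caseid,
    caseversion = suppressWarnings(as.integer(demo$caseversion)),
    age_value = suppressWarnings(as.numeric(demo$age)),
    age_unit = toupper(demo$age_cod),
    gender = toupper(demo$sex),
    stringsAsFactors = FALSE
  )
  if (anyNA(demo$caseversion)) {
    stop_faersddi("parse error in demographics: non-integer caseversion")
  }
  if (any(demo$caseversion < 0)) {
    stop_faersddi("parse error in demographics: negative caseversion")
  }

  known <- demo$primaryid
  orphan_rows <- c(drugs = 0L, reactions = 0L, indications = 0L, outcomes = 0L)
  keep_known <- function(df, tab) {
    orphan <- !(df$primaryid %in% known)
    orphan_rows[[tab]] <<- sum(orphan)
    df[!orphan, , drop = FALSE]
  }
  drugs <- keep_known(
    data.frame(primaryid = drugs$primaryid, drugname = drugs$drugname,
      role_cod = toupper(drugs$role_cod), stringsAsFactors = FALSE),
    "drugs"
  )
  reac <- keep_known(
    data.frame(primaryid = reac$primaryid, pt = reac$pt,
      stringsAsFactors = FALSE),
    "reactions"
  )
  indi <- keep_known(
    data.frame(primaryid = indi$primaryid, pt = indi$indi_pt,
      stringsAsFactors = FALSE),
    "indications"
  )
  outc <- keep_known(
    data.frame(primaryid = outc$primaryid, outc_cod = outc$outc_cod,
      stringsAsFactors = FALSE),
    "outcomes"
  )
  if (sum(orphan_rows) > 0) {
    warning(sum(orphan_rows), " orphan row(s) referenced unknown primaryids",
      call. = FALSE)
  }

  structure(
    list(demo = demo, drugs = drugs, reactions = reac, indications = indi,
      outcomes = outc, orphan_rows = orphan_rows),
    class = "faers_cases"
  )
}

#' @export
print.faers_cases <- function(x, ...) {
  cat("FAERS case set: ", nrow(x$demo), " report(s), ",
    length(unique(x$demo$caseid)), " case(s)\n", sep = "")
  invisible(x)
}

# Rank primaryids numerically when possible, lexicographically otherwise;
# used only to break caseversion ties deterministically.
pid_rank <- function(pid) {
  num <- suppressWarnings(as.numeric(pid))
  if (anyNA(num)) rank(pid, ties.method = "first") else num
}

#' Deduplicate cases, keeping the latest version of each
#'
#' A FAERS case may be reported several times as follow-up versions. For
#' each `caseid` exactly the record with the highest `caseversion` is
#' retained; ties are broken by the highest `primaryid`. Output is sorted
#' by `caseid`, so the operation is deterministic and idempotent.
#'
#' @param cases a `faers_cases` object.
#' @return a `faers_cases` object with one report per case.
#' @export
deduplicate_cases <- function(cases) {
  stopifnot(inherits(cases, "faers_cases"))
  demo <- cases$demo
  if (nrow(demo) == 0) return(cases)
  ord <- order(demo$caseid, -demo$caseversion, -pid_rank(demo$primaryid))
  demo <- demo[ord, , drop = FALSE]
  demo <- demo[!duplicated(demo$caseid), , drop = FALSE]
  demo <- demo[order(demo$caseid), , drop = FALSE]
  rownames(demo) <- NULL
  keep <- demo$primaryid
  out <- cases
  out$demo <- demo
  for (tab in c("drugs", "reactions", "indications", "outcomes")) {
    df <- cases[[tab]]
    df <- df[df$primaryid %in% keep, , drop = FALSE]
    rownames(df) <- NULL
    out[[tab]] <- df
  }
  out
}

#' Build a verbatim-drug-name to ingredient map
#'
#' Lookup is case-insensitive and whitespace-normalized. A verbatim name
#' may map to several ingredient identifiers (combination products).
#'
#' @param verbatim_name character vector of verbatim names.
#' @param ingredient_id character vector (same length) of ingredient ids.
#' @return a `drug_name_map` object.
#' @export
drug_name_map <- function(verbatim_name, ingredient_id) {
  stopifnot(length(verbatim_name) == length(ingredient_id))
  keys <- normalize_term(verbatim_name)
  entries <- split(as.character(ingredient_id), keys)
  entries <- lapply(entries, function(v) sort(unique(v)))
  if (any(vapply(entries, length, 1L) == 0)) {
    stop_faersddi("drug name map contains an empty ingredient set")
  }
  structure(list(entries = entries), class = "drug_name_map")
}

#' Read a drug-name map from CSV
#'
#' Expects columns `verbatim_name`, `rxnorm_ingredient_id` (and optionally
#' `ingredient_name`, ignored for lookup).
#'
#' @param path CSV file path.
#' @return a `drug_name_map` object.
#' @export
read_drug_name_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
    colClasses = "character")
  need <- c("verbatim_name", "rxnorm_ingredient_id")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop_faersddi("drug name map '", basename(path), "' missing column(s) ",
      paste(missing_cols, collapse = ", "))
  }
  drug_name_map(df$verbatim_name, df$rxnorm_ingredient_id)
}

lookup_ingredients <- function(map, verbatim) {
  map$entries[[normalize_term(verbatim)]]
}

#' Convert a reported age to years
#'
#' Units: `YR` (years), `MON` (months, /12), `WK` (weeks, /52.14), `DY`
#' (days, /365.25). Unknown unit codes yield `NA`.
#'
#' @param value numeric age value(s).
#' @param unit character unit code(s).
#' @return age in years, `NA` where missing or unconvertible.
#' @export
convert_age_years <- function(value, unit) {
  divisor <- c(YR = 1, MON = 12, WK = 52.14, DY = 365.25)
  d <- divisor[toupper(as.character(unit))]
  out <- as.numeric(value) / unname(d)
  out[is.na(value) | is.na(d)] <- NA_real_
  out
}

age_group_of <- function(age_years) {
  ifelse(is.na(age_years), "missing",
    ifelse(age_years < 65, "under65", "over65_inclusive"))
}

#' Construct a normalized report set
#'
#' The normalized container holding one row per deduplicated safety
#' report plus long tables of its ingredient, adverse event (AE) and
#' indication terms. Invariants (checked): every long-table `report_id`
#' appears in `$reports`; `n_unique_ingredients` equals the size of each
#' report's ingredient set.
#'
#' @param reports data frame with columns `report_id`, `age_years`,
#'   `age_group`, `gender`, `n_unique_ingredients`.
#' @param ingredients data frame `report_id`, `ingredient`.
#' @param aes data frame `report_id`, `term` (MedDRA PTs, or HLTs after
#'   rollup).
#' @param indications data frame `report_id`, `term`.
#' @return a `report_set` object.
#' @export
report_set <- function(reports, ingredients, aes, indications) {
  rs <- structure(
    list(reports = reports, ingredients = ingredients, aes = aes,
      indications = indications),
    class = "report_set"
  )
  validate_report_set(rs)
}

validate_report_set <- function(rs) {
  ids <- rs$reports$report_id
  if (anyDuplicated(ids)) stop_faersddi("duplicate report_id in report set")
  for (tab in c("ingredients", "aes", "indications")) {
    if (!all(rs[[tab]]$report_id %in% ids)) {
      stop_faersddi("report set ", tab, " table references unknown report_id")
    }
  }
  n_ing <- table(factor(rs$ingredients$report_id, levels = ids))
  if (!all(rs$reports$n_unique_ingredients == as.integer(n_ing))) {
    stop_faersddi("n_unique_ingredients inconsistent with ingredient table")
  }
  rs
}

#' @export
print.report_set <- function(x, ...) {
  cat("Normalized report set: ", nrow(x$reports), " report(s), ",
    length(unique(x$ingredients$ingredient)), " ingredient(s), ",
    length(unique(x$aes$term)), " AE term(s)\n", sep = "")
  invisible(x)
}

#' Normalize deduplicated raw cases into reports
#'
#' Maps each verbatim drug name to ingredient identifiers through the
#' name map; names with no mapping are excluded from the report's
#' ingredient set (the report itself is kept) and tallied. Ages are
#' converted to years and grouped at the 65-year boundary (65.0 falls in
#' the elderly group). Unknown age units are treated as missing age.
#'
#' @param cases a deduplicated `faers_cases` object.
#' @param name_map a `drug_name_map`.
#' @param roles optional character vector of drug role codes to keep
#'   (e.g. `c("PS", "SS")`); `NULL` keeps all roles.
#' @return list with `reports` (a `report_set`) and `stats` (mapping
#'   statistics: `n_names`, `n_mapped`, `n_unmapped`, `coverage`,
#'   `n_age_unconvertible`).
#' @export
normalize_reports <- function(cases, name_map, roles = NULL) {
  stopifnot(inherits(cases, "faers_cases"), inherits(name_map, "drug_name_map"))
  demo <- cases$demo
  drugs <- cases$drugs
  if (!is.null(roles)) {
    drugs <- drugs[drugs$role_cod %in% toupper(roles), , drop = FALSE]
  }

  mapped <- lapply(drugs$drugname, lookup_ingredients, map = name_map)
  is_mapped <- !vapply(mapped, is.null, TRUE)
  n_names <- nrow(drugs)
  n_mapped <- sum(is_mapped)

  ing_long <- data.frame(
    report_id = as.character(rep(drugs$primaryid[is_mapped],
      lengths(mapped[is_mapped]))),
    ingredient = as.character(unlist(mapped[is_mapped], use.names = FALSE)),
    stringsAsFactors = FALSE
  )
  if (nrow(ing_long)) {
    ing_long <- unique(ing_long)
    ing_long <- ing_long[order(ing_long$report_id, ing_long$ingredient), ,
      drop = FALSE]
    rownames(ing_long) <- NULL
  }

  age_years <- convert_age_years(demo$age_value, demo$age_unit)
  n_age_unconvertible <- sum(!is.na(demo$age_value) & is.na(age_years))
  gender <- ifelse(demo$gender == "F", "female",
    ifelse(demo$gender == "M", "male", "missing"))

  ids <- demo$primaryid
  reports <- data.frame(
    report_id = ids,
    age_years = age_years,
    age_group = age_group_of(age_years),
    gender = gender,
    n_unique_ingredients =
      as.integer(table(factor(ing_long$report_id, levels = ids))),
    stringsAsFactors = FALSE
  )

  dedup_terms <- function(df, term_col) {
    out <- data.frame(report_id = df$primaryid, term = df[[term_col]],
      stringsAsFactors = FALSE)
    out <- unique(out)
    out <- out[order(out$report_id, out$term), , drop = FALSE]
    rownames(out) <- NULL
    out
  }

  rs <- report_set(
    reports = reports,
    ingredients = ing_long,
    aes = dedup_terms(cases$reactions, "pt"),
    indications = dedup_terms(cases$indications, "pt")
  )
  list(
    reports = rs,
    stats = list(
      n_names = n_names,
      n_mapped = n_mapped,
      n_unmapped = n_names - n_mapped,
      coverage = if (n_names > 0) n_mapped / n_names else NA_real_,
      n_age_unconvertible = n_age_unconvertible
    )
  )
}

#' Write a report set to the normalized interchange format
#'
#' Four CSVs in `dir`: `reports.csv` plus long-format `ingredients.csv`,
#' `aes.csv`, `indications.csv`. [read_report_set()] reproduces the
#' object exactly.
#'
#' @param rs a `report_set`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_set <- function(rs, dir) {
  stopifnot(inherits(rs, "report_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(rs$reports, file.path(dir, "reports.csv"),
    row.names = FALSE)
  utils::write.csv(rs$ingredients, file.path(dir, "ingredients.csv"),
    row.names = FALSE)
  utils::write.csv(rs$aes, file.path(dir, "aes.csv"), row.names = FALSE)
  utils::write.csv(rs$indications, file.path(dir, "indications.csv"),
    row.names = FALSE)
  invisible(dir)
}

#' Read a report set from the normalized interchange format
#'
#' @param dir directory written by [write_report_set()].
#' @return a `report_set`.
#' @export
read_report_set <- function(dir) {
  rd <- function(f, classes) {
    utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE,
      colClasses = classes)
  }
  report_set(
    reports = rd("reports.csv", c(report_id = "character",
      age_years = "numeric", age_group = "character", gender = "character",
      n_unique_ingredients = "integer")),
    ingredients = rd("ingredients.csv", c(report_id = "character",
      ingredient = "character")),
    aes = rd("aes.csv", c(report_id = "character", term = "character")),
    indications = rd("indications.csv", c(report_id = "character",
      term = "character"))
  )
}
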