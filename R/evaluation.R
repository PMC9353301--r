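# Evaluation of detected drug-pair signals against a graded reference
# DDI table, and the Monte Carlo empirical p-value for the overlap.

ddi_grades <- c("no_interaction", "potential_weak", "potential",
  "do_not_coadminister")

# canonical unordered pair key
pair_key <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  paste(pmin(a, b), pmax(a, b), sep = " || ")
}

#' Construct a graded reference DDI table
#'
#' Pairs are unordered: (a, b) and (b, a) denote the same entry. Each
#' pair carries one of the four grades `no_interaction`,
#' `potential_weak`, `potential`, `do_not_coadminister`. A pair listed
#' twice with conflicting grades is a validation error; a pair is
#' "documented" when its grade is anything but `no_interaction`.
#'
#' @param drug_a,drug_b character vectors of ingredient identifiers.
#' @param grade character vector of grades.
#' @return a `reference_ddi` object.
#' @export
reference_ddi <- function(drug_a, drug_b, grade) {
  stopifnot(length(drug_a) == length(drug_b), length(drug_a) == length(grade))
  bad <- setdiff(unique(grade), ddi_grades)
  if (length(bad)) {
    stop_faersddi("unknown DDI grade(s): ", paste(bad, collapse = ", "))
  }
  key <- pair_key(drug_a, drug_b)
  tab <- unique(data.frame(key = key, grade = as.character(grade),
    stringsAsFactors = FALSE))
  if (anyDuplicated(tab$key)) {
    dup <- unique(tab$key[duplicated(tab$key)])
    stop_faersddi("conflicting grades for pair(s): ",
      paste(dup, collapse = "; "))
  }
  structure(
    list(grades = stats::setNames(tab$grade, tab$key)),
    class = "reference_ddi"
  )
}

#' Read a reference DDI table from CSV
#'
#' Expects columns `drug_a`, `drug_b`, `grade`.
#'
#' @param path CSV file path.
#' @return a `reference_ddi` object.
#' @export
read_reference_ddi <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
    colClasses = "character")
  need <- c("drug_a", "drug_b", "grade")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop_faersddi("reference DDI table '", basename(path),
      "' missing column(s) ", paste(missing_cols, collapse = ", "))
  }
  reference_ddi(df$drug_a, df$drug_b, df$grade)
}

reference_grade <- function(reference, keys) {
  unname(reference$grades[keys])
}

# documented = present in the reference with any grade except no_interaction
documented_count <- function(reference, keys) {
  g <- reference_grade(reference, keys)
  sum(!is.na(g) & g != "no_interaction")
}

#' Deduplicate signal results to unordered drug pairs
#'
#' @param signals data frame with columns `covid_drug` and `comed` (e.g.
#'   the signal-flagged rows of [results_table()]).
#' @return data frame of distinct unordered pairs (`drug_a`, `drug_b`,
#'   and the canonical `key`).
#' @export
signal_pairs <- function(signals) {
  key <- pair_key(signals$covid_drug, signals$comed)
  keep <- !duplicated(key)
  out <- data.frame(
    drug_a = pmin(signals$covid_drug, signals$comed)[keep],
    drug_b = pmax(signals$covid_drug, signals$comed)[keep],
    key = key[keep], stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Classify detected pairs against the reference table
#'
#' Each unordered signal pair is classified as documented (grade other
#' than `no_interaction`), reference-nonsignificant (`no_interaction`),
#' or not covered (absent from the reference).
#'
#' @param pairs data frame of unordered pairs with columns `drug_a`,
#'   `drug_b` (a `key` column is recomputed if absent).
#' @param reference a `reference_ddi`.
#' @return a `concordance_summary`: counts `n_signal_pairs`,
#'   `n_documented`, `n_reference_nonsignificant`, `n_not_covered`, a
#'   `per_grade` breakdown, and the per-pair classification data frame.
#' @export
compare_reference <- function(pairs, reference) {
  stopifnot(inherits(reference, "reference_ddi"))
  keys <- pair_key(pairs$drug_a, pairs$drug_b)
  if (anyDuplicated(keys)) {
    stop_faersddi("signal pairs must be deduplicated to unordered form")
  }
  g <- reference_grade(reference, keys)
  status <- ifelse(is.na(g), "not_covered",
    ifelse(g == "no_interaction", "reference_nonsignificant", "documented"))
  detail <- data.frame(drug_a = pairs$drug_a, drug_b = pairs$drug_b,
    grade = ifelse(is.na(g), "absent", g), status = status,
    stringsAsFactors = FALSE)
  per_grade <- table(factor(g[!is.na(g)], levels = ddi_grades))
  structure(
    list(
      n_signal_pairs = nrow(pairs),
      n_documented = sum(status == "documented"),
      n_reference_nonsignificant = sum(status == "reference_nonsignificant"),
      n_not_covered = sum(status == "not_covered"),
      per_grade = as.integer(per_grade) |>
        stats::setNames(ddi_grades),
      pairs = detail
    ),
    class = "concordance_summary"
  )
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat("Concordance with reference DDI table\n",
    "  signal pairs:              ", x$n_signal_pairs, "\n",
    "  documented:                ", x$n_documented, "\n",
    "  reference non-significant: ", x$n_reference_nonsignificant, "\n",
    "  not covered:               ", x$n_not_covered, "\n", sep = "")
  invisible(x)
}

# universe of distinct unordered (covid drug, co-medication) pairs,
# self-pairs excluded
candidate_pair_universe <- function(covid_drugs, comeds) {
  grid <- expand.grid(a = covid_drugs, b = comeds, stringsAsFactors = FALSE)
  grid <- grid[grid$a != grid$b, , drop = FALSE]
  unique(pair_key(grid$a, grid$b))
}

#' Monte Carlo empirical p-value for reference overlap
#'
#' Draws `n_sims` random sets of distinct unordered (COVID-19 drug,
#' co-medication) pairs, each of the same size as the observed signal
#' pair set, uniformly without replacement from the candidate universe
#' (self-pairs excluded). `r` counts the simulations whose
#' reference-documented overlap is at least the observed overlap (ties
#' included, conservative), and the empirical p-value is
#' p = (r + 1) / (n_sims + 1), so p is never zero.
#'
#' @param observed_pairs data frame of unordered pairs (`drug_a`,
#'   `drug_b`), e.g. from [signal_pairs()].
#' @param covid_drugs character vector of candidate COVID-19 drugs.
#' @param comeds character vector of candidate co-medications.
#' @param reference a `reference_ddi`.
#' @param n_sims number of simulations (default 1000).
#' @param seed integer seed fixing the simulation stream.
#' @return an `empirical_pvalue`: `p`, `r`, `n`, `observed_overlap`,
#'   `seed`.
#' @export
monte_carlo_empirical_p <- function(observed_pairs, covid_drugs, comeds,
                                    reference, n_sims = 1000, seed = 1) {
  stopifnot(inherits(reference, "reference_ddi"), n_sims >= 1)
  if (length(covid_drugs) < 1 || length(comeds) < 2) {
    stop_faersddi("candidate universe too small: need >= 1 covid drug and ",
      ">= 2 co-medications")
  }
  universe <- candidate_pair_universe(covid_drugs, comeds)
  k <- nrow(observed_pairs)
  if (k > length(universe)) {
    stop_faersddi("configuration error: ", k, " observed pairs exceed the ",
      length(universe), "-pair candidate universe")
  }
  observed_overlap <- documented_count(
    reference, pair_key(observed_pairs$drug_a, observed_pairs$drug_b))

  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
    envir = globalenv()))
  set.seed(seed)
  sims <- vapply(seq_len(n_sims), function(i) {
    documented_count(reference, sample(universe, k, replace = FALSE))
  }, integer(1))
  r <- sum(sims >= observed_overlap)

  structure(
    list(p = (r + 1) / (n_sims + 1), r = r, n = n_sims,
      observed_overlap = observed_overlap, seed = seed),
    class = "empirical_pvalue"
  )
}

#' @export
print.empirical_pvalue <- function(x, ...) {
  cat("Empirical p-value: p = (", x$r, " + 1)/(", x$n, " + 1) = ",
    format(x$p, digits = 4), " (observed documented overlap ",
    x$observed_overlap, ", seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Write an empirical p-value report as JSON
#'
#' @param ep an `empirical_pvalue`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_empirical_p <- function(ep, path) {
  jsonlite::write_json(
    list(p = ep$p, r = ep$r, n = ep$n,
      observed_overlap = ep$observed_overlap, seed = ep$seed),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
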