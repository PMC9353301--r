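# Hand-built tiny FAERS-dialect fixtures, written from code at test time.

write_faers_fixture <- function(dir, demo, drug = NULL, reac = NULL,
                                indi = NULL, outc = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  empty <- list(
    drug = data.frame(primaryid = character(0), drugname = character(0),
      role_cod = character(0)),
    reac = data.frame(primaryid = character(0), pt = character(0)),
    indi = data.frame(primaryid = character(0), indi_pt = character(0)),
    outc = data.frame(primaryid = character(0), outc_cod = character(0))
  )
  tabs <- list(demo = demo, drug = drug %||% empty$drug,
    reac = reac %||% empty$reac, indi = indi %||% empty$indi,
    outc = outc %||% empty$outc)
  paths <- list()
  for (nm in names(tabs)) {
    paths[[nm]] <- file.path(dir, paste0(toupper(nm), "20Q1.txt"))
    utils::write.table(tabs[[nm]], paths[[nm]], sep = "$", quote = FALSE,
      row.names = FALSE)
  }
  paths
}

demo_row <- function(primaryid, caseid = primaryid, caseversion = 1,
                     age = "50", age_cod = "YR", sex = "F") {
  data.frame(primaryid = primaryid, caseid = caseid,
    caseversion = caseversion, age = age, age_cod = age_cod, sex = sex,
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# tiny hand-enumerable MedDRA hierarchy: 5 PTs, 3 HLTs, 2 SOCs
toy_hierarchy_df <- function() {
  data.frame(
    pt = c("P1", "P2", "P3", "P4", "P5"),
    hlt = c("H1", "H1", "H2", "H3", "H3"),
    hlgt = c("G1", "G1", "G1", "G2", "G2"),
    soc = c("S_keep", "S_keep", "S_keep", "S_drop", "S_drop"),
    stringsAsFactors = FALSE
  )
}

# small normalized report set built directly, bypassing ingestion
make_report_set <- function(n, ingredients_of, aes_of, indications_of,
                            age = rep(50, n), gender = rep("female", n)) {
  ids <- sprintf("r%03d", seq_len(n))
  long <- function(value_of, col) {
    vals <- lapply(seq_len(n), value_of)
    df <- data.frame(
      report_id = rep(ids, lengths(vals)),
      v = unlist(vals) %||% character(0), stringsAsFactors = FALSE
    )
    names(df)[2] <- col
    df <- unique(df)
    df <- df[order(df$report_id, df[[2]]), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  ing <- long(ingredients_of, "ingredient")
  report_set(
    reports = data.frame(
      report_id = ids, age_years = as.numeric(age),
      age_group = ifelse(is.na(age), "missing",
        ifelse(age < 65, "under65", "over65_inclusive")),
      gender = gender,
      n_unique_ingredients = as.integer(
        table(factor(ing$report_id, levels = ids))),
      stringsAsFactors = FALSE
    ),
    ingredients = ing,
    aes = long(aes_of, "term"),
    indications = long(indications_of, "term")
  )
}
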