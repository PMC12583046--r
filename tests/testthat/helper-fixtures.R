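# In-code fixtures: tiny FAERS-dialect quarters and case sets built
# programmatically, plus a small synonym/ATC pair used where the
# packaged tables would be overkill.

fixture_synonyms <- c(PROZAC = "fluoxetine", FLUOXETINE = "fluoxetine",
                      TRAMADOL = "tramadol", ULTRAM = "tramadol",
                      ZYVOX = "linezolid", LINEZOLID = "linezolid",
                      SERTRALINE = "sertraline")

fixture_atc <- c(fluoxetine = "N", tramadol = "N", linezolid = "J",
                 sertraline = "N")

# Build a faers_quarter from partial row specs; missing columns are
# filled with empty strings.
fixture_quarter <- function(quarter = "2024Q1", demo = NULL, drug = NULL,
                            reac = NULL, outc = NULL, ther = NULL) {
  fill <- function(rows, cols) {
    if (is.null(rows))
      return(as.data.frame(stats::setNames(rep(list(character(0)),
                                               length(cols)), cols),
                           stringsAsFactors = FALSE))
    rows <- as.data.frame(rows, stringsAsFactors = FALSE)
    for (cl in setdiff(cols, names(rows))) rows[[cl]] <- ""
    for (cl in cols) rows[[cl]] <- as.character(rows[[cl]])
    rows[, cols, drop = FALSE]
  }
  structure(list(
    quarter = quarter,
    demo = fill(demo, c("primaryid", "caseid", "event_dt", "age", "age_cod",
                        "sex", "occp_cod", "reporter_country", "fda_dt")),
    drug = fill(drug, c("primaryid", "caseid", "drug_seq", "role_cod",
                        "drugname", "prod_ai")),
    reac = fill(reac, c("primaryid", "caseid", "pt")),
    outc = fill(outc, c("primaryid", "caseid", "outc_cod")),
    ther = fill(ther, c("primaryid", "caseid", "dsg_drug_seq", "start_dt",
                        "end_dt")),
    skipped = c(demo = 0L, drug = 0L, reac = 0L, outc = 0L, ther = 0L)),
    class = "faers_quarter")
}

# Directly assemble a deduplicated case set for analysis-level tests.
fixture_cases <- function(demo, drugs = NULL, reactions = NULL,
                          outcomes = NULL) {
  demo <- as.data.frame(demo, stringsAsFactors = FALSE)
  if (is.null(demo$case_id)) demo$case_id <- demo$report_id
  if (is.null(demo$receipt_date))
    demo$receipt_date <- rep(as.Date("2024-03-31"), nrow(demo))
  if (is.null(demo$event_date))
    demo$event_date <- rep(as.Date(NA), nrow(demo))
  if (is.null(demo$age_years)) demo$age_years <- rep(70, nrow(demo))
  for (cl in c("sex", "country", "reporter_class"))
    if (is.null(demo[[cl]])) demo[[cl]] <- rep(NA_character_, nrow(demo))
  empty_or <- function(x, cols) {
    if (is.null(x))
      return(as.data.frame(stats::setNames(lapply(cols, function(cl)
        if (cl == "start_date") as.Date(character(0))
        else if (cl == "drug_seq") integer(0) else character(0)), cols),
        stringsAsFactors = FALSE))
    x <- as.data.frame(x, stringsAsFactors = FALSE)
    if ("drug_seq" %in% cols && is.null(x$drug_seq)) x$drug_seq <- 1L
    if ("role" %in% cols && is.null(x$role)) x$role <- "PS"
    if ("start_date" %in% cols && is.null(x$start_date))
      x$start_date <- as.Date(NA)
    x[, cols, drop = FALSE]
  }
  structure(list(
    demo = demo[, c("report_id", "case_id", "receipt_date", "event_date",
                    "age_years", "sex", "country", "reporter_class")],
    drugs = empty_or(drugs, c("report_id", "drug_seq", "role", "raw_name",
                              "start_date")),
    reactions = empty_or(reactions, c("report_id", "pt")),
    outcomes = empty_or(outcomes, c("report_id", "code"))),
    class = "faers_cases")
}

# A bare 2x2 table row with the derived E / RR / evaluable columns,
# as contingency_tables() would emit it.
finish_tables_for_test <- function(a, b, c, d) {
  tabs <- data.frame(drug = "drug", a = a, b = b, c = c, d = d,
                     stringsAsFactors = FALSE)
  tabs$N <- a + b + c + d
  tabs$E <- (a + b) * (a + c) / tabs$N
  tabs$RR <- tabs$a / tabs$E
  tabs$evaluable <- a + b > 0
  tabs
}

# Eight-report background with 2 drug+PT, 1 drug-only, 2 PT-only: the
# hand-counted (2, 1, 2, 3) contingency fixture.
fixture_background_8 <- function() {
  ids <- as.character(1:8)
  demo <- data.frame(report_id = ids, stringsAsFactors = FALSE)
  drugs <- data.frame(
    report_id = c("1", "2", "3"),
    raw_name = "TRAMADOL", role = "PS", stringsAsFactors = FALSE)
  reac <- data.frame(
    report_id = c("1", "2", "4", "5", "6", "7", "8"),
    pt = c("Serotonin syndrome", "Serotonin syndrome", "Serotonin syndrome",
           "Serotonin syndrome", "Nausea", "Nausea", "Rash"),
    stringsAsFactors = FALSE)
  fixture_cases(demo, drugs = drugs, reactions = reac)
}
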