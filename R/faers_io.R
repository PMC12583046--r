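# Ingestion of FAERS-dialect quarterly ASCII extracts and case-level
# assembly: parsing, deduplication, cohort selection.
#
# Dialect: one file per table and quarter (DEMOyyQq, DRUGyyQq, ...),
# '$'-delimited, first line is the header, dates are YYYYMMDD integers
# possibly truncated.

FAERS_TABLES <- c("DEMO", "DRUG", "REAC", "OUTC", "THER")
FAERS_OPTIONAL_TABLES <- c("RPSR", "INDI")

#' Read one FAERS-style quarter
#'
#' Reads the `$`-delimited DEMO/DRUG/REAC/OUTC/THER tables for one
#' quarter from a directory. RPSR and INDI files are read when present
#' but are not used by any downstream analysis. Rows whose field count
#' does not match the header are skipped and counted; more than 1%
#' skipped rows in a table is treated as a corrupt file.
#'
#' @param path directory containing the quarterly files.
#' @param quarter_label quarter label such as `"2024Q1"`.
#' @param quiet suppress per-table row-count messages.
#' @return an object of class `faers_quarter`: a list with one
#'   character `data.frame` per table, the quarter label, and a
#'   `skipped` count per table.
#' @export
read_quarter <- function(path, quarter_label, quiet = TRUE) {
  stopifnot(dir.exists(path), grepl("^[0-9]{4}Q[1-4]$", quarter_label))
  suffix <- paste0(substr(quarter_label, 3L, 4L), substr(quarter_label, 5L, 6L))
  out <- list(quarter = quarter_label)
  skipped <- integer(0)
  for (tab in c(FAERS_TABLES, FAERS_OPTIONAL_TABLES)) {
    file <- file.path(path, paste0(tab, suffix, ".txt"))
    if (!file.exists(file)) file <- file.path(path, paste0(tab, suffix))
    if (!file.exists(file)) {
      if (tab %in% FAERS_OPTIONAL_TABLES) next
      stop("missing mandatory FAERS file for ", tab, " ", quarter_label,
           " (expected ", paste0(tab, suffix, ".txt"), " under ", path, ")")
    }
    parsed <- read_faers_table(file)
    out[[tolower(tab)]] <- parsed
    skipped[tolower(tab)] <- attr(parsed, "skipped")
    if (!quiet)
      message(tab, " ", quarter_label, ": ", nrow(parsed), " rows (",
              attr(parsed, "skipped"), " skipped)")
  }
  out$skipped <- skipped
  structure(out, class = "faers_quarter")
}

# Parse one '$'-delimited table. A sentinel field is appended before
# splitting so trailing empty fields survive strsplit().
read_faers_table <- function(file) {
  lines <- readLines(file, warn = FALSE)
  if (length(lines) == 0L) stop("empty file (no header): ", file)
  split1 <- strsplit(paste0(lines, "$\x01"), "$", fixed = TRUE)
  header <- split1[[1L]]
  header <- header[-length(header)]
  body <- split1[-1L]
  nf <- length(header)
  ok <- lengths(body) == nf + 1L
  n_skipped <- sum(!ok)
  if (length(body) > 0L && n_skipped / length(body) > 0.01)
    stop("more than 1% malformed rows (", n_skipped, "/", length(body),
         ") in ", file)
  rows <- body[ok]
  if (length(rows) == 0L) {
    df <- as.data.frame(matrix(character(0), ncol = nf,
                               dimnames = list(NULL, header)),
                        stringsAsFactors = FALSE)
  } else {
    m <- matrix(unlist(rows, use.names = FALSE), ncol = nf + 1L, byrow = TRUE)
    df <- as.data.frame(m[, seq_len(nf), drop = FALSE],
                        stringsAsFactors = FALSE)
    names(df) <- header
  }
  attr(df, "skipped") <- n_skipped
  df
}

#' Convert a FAERS age field to years
#'
#' Unit codes: YR (years), DEC (decades), MON (months), WK (weeks),
#' DY (days), HR (hours). A value with a missing or unknown unit is
#' taken as years (the dominant FAERS unit); negative values and ages
#' above 125 years are treated as erroneous and returned as `NA`.
#'
#' @param value numeric or character vector of age values.
#' @param unit character vector of unit codes (recycled if length 1).
#' @return numeric vector of ages in years.
#' @export
parse_age_to_years <- function(value, unit) {
  value <- suppressWarnings(as.numeric(value))
  unit <- toupper(trimws(as.character(unit)))
  if (length(unit) == 1L) unit <- rep(unit, length(value))
  mult <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 1 / 52.1775,
            DY = 1 / 365.25, HR = 1 / 8766)
  m <- unname(mult[unit])
  m[is.na(m)] <- 1  # blank/unknown unit: assume years
  years <- value * m
  years[!is.finite(years) | years < 0 | years > 125] <- NA_real_
  years
}

#' Classify a reporter occupation code
#'
#' MD, PH, HP and OT (physician, pharmacist, other health professional)
#' are healthcare professionals; CN and LW (consumer, lawyer) are
#' non-professional reporters; anything else is missing.
#'
#' @param occupation_code character vector of FAERS `occp_cod` values.
#' @return character vector: `"healthcare"`, `"non-healthcare"` or `NA`.
#' @export
classify_reporter <- function(occupation_code) {
  code <- toupper(trimws(as.character(occupation_code)))
  out <- rep(NA_character_, length(code))
  out[code %in% c("MD", "PH", "HP", "OT")] <- "healthcare"
  out[code %in% c("CN", "LW")] <- "non-healthcare"
  out
}

#' Deduplicate report versions into one case set
#'
#' FAERS cases accrue new versions across quarters. Per `caseid` the
#' retained version is the one with the latest receipt date (`fda_dt`;
#' a partial receipt date falls back to the end of its quarter), ties
#' broken by the largest numeric `primaryid`. Drug, reaction, outcome
#' and therapy rows are joined for the retained report only; therapy
#' start dates attach to drug mentions by drug sequence, keeping the
#' earliest full start date per mention.
#'
#' @param quarters a list of `faers_quarter` objects (or a single one).
#' @return an object of class `faers_cases`: a list of data.frames
#'   `demo` (one row per case), `drugs`, `reactions`, `outcomes`.
#' @export
deduplicate_cases <- function(quarters) {
  if (inherits(quarters, "faers_quarter")) quarters <- list(quarters)
  if (length(quarters) == 0L) return(empty_cases())

  demo <- do.call(rbind, lapply(quarters, function(q) {
    d <- q$demo
    if (nrow(d) == 0L) return(NULL)
    data.frame(
      report_id = trimws(d$primaryid),
      case_id = trimws(d$caseid),
      receipt_date = parse_receipt_date(d$fda_dt, q$quarter),
      event_date = parse_faers_date(d$event_dt),
      age_years = parse_age_to_years(d$age, d$age_cod),
      sex = unname(c(F = "female", M = "male")[toupper(trimws(d$sex))]),
      country = ifelse(trimws(d$reporter_country) == "", NA_character_,
                       trimws(d$reporter_country)),
      reporter_class = classify_reporter(d$occp_cod),
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(demo) || nrow(demo) == 0L) return(empty_cases())

  ord <- order(demo$case_id, demo$receipt_date,
               suppressWarnings(as.numeric(demo$report_id)))
  demo <- demo[ord, , drop = FALSE]
  keep <- !duplicated(demo$case_id, fromLast = TRUE)  # last = latest
  demo <- demo[keep, , drop = FALSE]
  rownames(demo) <- NULL

  bind <- function(tab_name, build) {
    parts <- lapply(quarters, function(q) {
      t <- q[[tab_name]]
      if (is.null(t) || nrow(t) == 0L) NULL else build(t)
    })
    parts <- parts[!vapply(parts, is.null, logical(1))]
    if (length(parts) == 0L) return(NULL)
    res <- do.call(rbind, parts)
    res[res$report_id %in% demo$report_id, , drop = FALSE]
  }

  drugs <- bind("drug", function(t) data.frame(
    report_id = trimws(t$primaryid),
    drug_seq = suppressWarnings(as.integer(t$drug_seq)),
    role = toupper(trimws(t$role_cod)),
    raw_name = trimws(t$drugname),
    stringsAsFactors = FALSE))
  ther <- bind("ther", function(t) data.frame(
    report_id = trimws(t$primaryid),
    drug_seq = suppressWarnings(as.integer(t$dsg_drug_seq)),
    start_date = parse_faers_date(t$start_dt),
    stringsAsFactors = FALSE))
  reac <- bind("reac", function(t) data.frame(
    report_id = trimws(t$primaryid),
    pt = trimws(t$pt),
    stringsAsFactors = FALSE))
  outc <- bind("outc", function(t) data.frame(
    report_id = trimws(t$primaryid),
    code = toupper(trimws(t$outc_cod)),
    stringsAsFactors = FALSE))

  if (is.null(drugs)) {
    drugs <- data.frame(report_id = character(0), drug_seq = integer(0),
                        role = character(0), raw_name = character(0),
                        start_date = as.Date(character(0)),
                        stringsAsFactors = FALSE)
  } else {
    # earliest full therapy start date per (report, drug sequence)
    if (!is.null(ther) && nrow(ther) > 0L) {
      ther <- ther[!is.na(ther$start_date), , drop = FALSE]
      if (nrow(ther) > 0L) {
        key <- paste(ther$report_id, ther$drug_seq, sep = "\r")
        first <- tapply(as.numeric(ther$start_date), key, min)
        dkey <- paste(drugs$report_id, drugs$drug_seq, sep = "\r")
        drugs$start_date <- as.Date(unname(first[dkey]),
                                    origin = "1970-01-01")
      } else drugs$start_date <- as.Date(NA)
    } else drugs$start_date <- as.Date(NA)
    rownames(drugs) <- NULL
  }
  if (is.null(reac)) reac <- data.frame(report_id = character(0),
                                        pt = character(0),
                                        stringsAsFactors = FALSE)
  if (is.null(outc)) outc <- data.frame(report_id = character(0),
                                        code = character(0),
                                        stringsAsFactors = FALSE)
  rownames(reac) <- rownames(outc) <- NULL

  structure(list(demo = demo, drugs = drugs, reactions = reac,
                 outcomes = outc),
            class = "faers_cases")
}

empty_cases <- function() {
  structure(list(
    demo = data.frame(report_id = character(0), case_id = character(0),
                      receipt_date = as.Date(character(0)),
                      event_date = as.Date(character(0)),
                      age_years = numeric(0), sex = character(0),
                      country = character(0), reporter_class = character(0),
                      stringsAsFactors = FALSE),
    drugs = data.frame(report_id = character(0), drug_seq = integer(0),
                       role = character(0), raw_name = character(0),
                       start_date = as.Date(character(0)),
                       stringsAsFactors = FALSE),
    reactions = data.frame(report_id = character(0), pt = character(0),
                           stringsAsFactors = FALSE),
    outcomes = data.frame(report_id = character(0), code = character(0),
                          stringsAsFactors = FALSE)),
    class = "faers_cases")
}

#' Subset a case set by report id
#'
#' @param cases a `faers_cases` object.
#' @param report_ids character vector of report ids to keep.
#' @return a `faers_cases` object restricted to those reports.
#' @export
subset_cases <- function(cases, report_ids) {
  stopifnot(inherits(cases, "faers_cases"))
  out <- lapply(cases, function(t) {
    r <- t[t$report_id %in% report_ids, , drop = FALSE]
    rownames(r) <- NULL
    r
  })
  structure(out, class = "faers_cases")
}

#' @export
print.faers_cases <- function(x, ...) {
  cat("<faers_cases> ", nrow(x$demo), " cases, ", nrow(x$drugs),
      " drug mentions, ", nrow(x$reactions), " reactions\n", sep = "")
  invisible(x)
}

#' Select the elderly target-event cohort and its background
#'
#' The background population is every deduplicated report with age
#' >= `age_min` years (inclusive); the cohort is the subset of the
#' background whose reactions contain the target preferred term
#' (case-insensitive exact match after trimming).
#'
#' @param cases deduplicated `faers_cases`.
#' @param target_pt MedDRA preferred term, default `"Serotonin syndrome"`.
#' @param age_min minimum age in years, default 65.
#' @return list with elements `cohort` and `background` (both
#'   `faers_cases`).
#' @export
select_cohort <- function(cases, target_pt = "Serotonin syndrome",
                          age_min = 65) {
  stopifnot(inherits(cases, "faers_cases"))
  bg_ids <- cases$demo$report_id[!is.na(cases$demo$age_years) &
                                   cases$demo$age_years >= age_min]
  if (length(bg_ids) == 0L) stop("no elderly reports (age >= ", age_min, ")")
  background <- subset_cases(cases, bg_ids)
  pt_norm <- casefold(trimws(target_pt))
  hit <- background$reactions$report_id[
    casefold(trimws(background$reactions$pt)) == pt_norm]
  cohort <- subset_cases(background, unique(hit))
  list(cohort = cohort, background = background)
}
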