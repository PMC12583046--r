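# Table-1 style cohort characterization: sex, elderly age bands, top
# reporting countries, mutually exclusive outcome classes, reporter
# type, and yearly report counts.

OUTCOME_CLASSES <- c("Death", "Life-Threatening", "Hospitalization",
                     "Disability", "Other")

#' Map outcome codes to one mutually exclusive class
#'
#' FAERS reports can carry several outcome codes; for a partition of
#' the cohort one class is assigned by severity precedence:
#' Death (DE) > Life-Threatening (LT) > Hospitalization (HO) >
#' Disability (DS) > Other (CA, RI, OT, or no code).
#'
#' @param codes character vector of outcome codes for one report.
#' @param precedence class order, highest severity first; the default
#'   is the conventional ordering.
#' @return a single class label.
#' @export
map_outcome <- function(codes,
                        precedence = c(DE = "Death", LT = "Life-Threatening",
                                       HO = "Hospitalization",
                                       DS = "Disability")) {
  codes <- toupper(trimws(as.character(codes)))
  for (code in names(precedence))
    if (code %in% codes) return(unname(precedence[code]))
  "Other"
}

#' Summarize a cohort Table-1 style
#'
#' Counts and percentages (against the full cohort size, rounded half
#' up to one decimal) for sex, elderly age band, top reporting
#' countries, mutually exclusive outcome class, reporter type, and
#' receipt year. Missing sex/country/reporter values are reported as
#' explicit "Missing" rows.
#'
#' @param cohort a nonempty `faers_cases`.
#' @param top_countries how many countries to keep, default 10.
#' @return data.frame `characteristic, category, count, percent`.
#' @export
summarize_cohort <- function(cohort, top_countries = 10L) {
  stopifnot(inherits(cohort, "faers_cases"))
  demo <- cohort$demo
  n <- nrow(demo)
  if (n == 0L) stop("empty cohort")
  pct <- function(k) round_half_up(100 * k / n, 1L)

  rows <- list()
  add <- function(characteristic, categories, counts) {
    rows[[length(rows) + 1L]] <<- data.frame(
      characteristic = characteristic, category = categories,
      count = as.integer(counts), percent = pct(counts),
      stringsAsFactors = FALSE)
  }

  sex <- ifelse(is.na(demo$sex), "Missing",
                ifelse(demo$sex == "female", "Female", "Male"))
  tab <- table(factor(sex, levels = c("Female", "Male", "Missing")))
  add("Sex", names(tab), as.integer(tab))

  band <- age_band(demo$age_years)
  tab <- table(factor(band, levels = c("65-74", "75-84", "85-94", ">=95")))
  add("Age (years)", names(tab), as.integer(tab))

  country <- ifelse(is.na(demo$country), "Missing", demo$country)
  tab <- sort(table(country), decreasing = TRUE)
  tab <- utils::head(tab, top_countries)
  add(sprintf("Reported countries (Top %d)", top_countries),
      names(tab), as.integer(tab))

  out_by_report <- split(cohort$outcomes$code, cohort$outcomes$report_id)
  cls <- vapply(demo$report_id, function(id)
    map_outcome(out_by_report[[id]] %||% character(0)), character(1))
  tab <- table(factor(cls, levels = OUTCOME_CLASSES))
  add("Outcome", names(tab), as.integer(tab))

  rep_cls <- ifelse(is.na(demo$reporter_class), "Missing",
                    ifelse(demo$reporter_class == "healthcare",
                           "Healthcare professionals",
                           "Non-healthcare professionals"))
  tab <- table(factor(rep_cls, levels = c("Healthcare professionals",
                                          "Non-healthcare professionals",
                                          "Missing")))
  add("Reporter type", names(tab), as.integer(tab))

  year <- format(demo$receipt_date, "%Y")
  tab <- table(year)
  add("Received year", names(tab), as.integer(tab))

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
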