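# Shared helpers: FAERS date handling, rounding, age bands.

#' Parse FAERS 8-digit dates
#'
#' FAERS dates are YYYYMMDD integers; truncated (YYYYMM or YYYY) or
#' malformed values carry partial information only and are returned as
#' `NA` here. Onset-interval computations require full dates.
#'
#' @param x character or numeric vector of raw date fields.
#' @return a `Date` vector; non-8-digit inputs are `NA`.
#' @export
parse_faers_date <- function(x) {
  x <- trimws(as.character(x))
  x[is.na(x) | !grepl("^[0-9]{8}$", x)] <- NA_character_
  as.Date(x, format = "%Y%m%d")
}

# Receipt-date parse with quarter-end fallback for partial/missing values,
# so every report version carries a usable date for deduplication.
parse_receipt_date <- function(x, quarter_label) {
  d <- parse_faers_date(x)
  d[is.na(d)] <- quarter_end(quarter_label)
  d
}

# "2024Q1" -> first/last day of the quarter
quarter_start <- function(label) {
  y <- as.integer(substr(label, 1L, 4L))
  q <- as.integer(substr(label, 6L, 6L))
  as.Date(sprintf("%04d-%02d-01", y, (q - 1L) * 3L + 1L))
}

quarter_end <- function(label) {
  y <- as.integer(substr(label, 1L, 4L))
  q <- as.integer(substr(label, 6L, 6L))
  if (q == 4L) as.Date(sprintf("%04d-12-31", y))
  else quarter_start(sprintf("%04dQ%d", y, q + 1L)) - 1L
}

# Round half away from zero (presentation convention for percentages;
# base round() uses round-half-even).
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Assign elderly age bands
#'
#' Bands are 65-74, 75-84, 85-94 and >=95 years with inclusive lower
#' bounds; ages below 65 or missing map to `NA`.
#'
#' @param age_years numeric vector of ages in years.
#' @return character vector of band labels.
#' @export
age_band <- function(age_years) {
  out <- rep(NA_character_, length(age_years))
  ok <- !is.na(age_years) & age_years >= 65
  out[ok & age_years < 75] <- "65-74"
  out[ok & age_years >= 75 & age_years < 85] <- "75-84"
  out[ok & age_years >= 85 & age_years < 95] <- "85-94"
  out[ok & age_years >= 95] <- ">=95"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
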