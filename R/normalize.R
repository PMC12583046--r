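# Drug-name normalization (trade name -> generic) and ATC first-level
# classification. Both mappings are plain two-column CSV tables so a
# user can swap in their own cross-reference without code changes.

# Fixed salt/dosage suffix tokens stripped before lookup. A fixed list
# (rather than a greedy regex) keeps the mapping deterministic and
# auditable.
SALT_SUFFIXES <- c("HCL", "HYDROCHLORIDE", "SULFATE", "TARTRATE",
                   "MALEATE", "SUCCINATE")

ATC_LABELS <- c(
  A = "alimentary tract and metabolism",
  B = "blood and blood forming organs",
  C = "cardiovascular system",
  D = "dermatologicals",
  G = "genito urinary system and sex hormones",
  H = "systemic hormonal preparations",
  J = "antiinfectives for systemic use",
  L = "antineoplastic and immunomodulating agents",
  M = "musculo-skeletal system",
  N = "nervous system",
  P = "antiparasitic products",
  R = "respiratory system",
  S = "sensory organs",
  V = "various"
)

#' Load a drug synonym table
#'
#' A two-column CSV (`raw,generic`) mapping canonicalized raw name
#' strings (trade names, salts, generic spellings) to generic names.
#' The packaged default covers the synthetic generator's drug roster.
#'
#' @param path CSV path; `NULL` uses the packaged table.
#' @return named character vector: canonical raw string -> generic name.
#' @export
load_synonyms <- function(path = NULL) {
  path <- path %||% system.file("extdata", "drug_synonyms.csv",
                                package = "ssfaers", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("raw", "generic") %in% names(tab)))
  keys <- canonicalize_drug_name(tab$raw, strip_salts = FALSE)
  stats::setNames(tolower(trimws(tab$generic)), keys)
}

#' Load an ATC first-level classification table
#'
#' A two-column CSV (`generic,atc_code`) assigning each generic name a
#' single ATC first-level letter.
#'
#' @param path CSV path; `NULL` uses the packaged table.
#' @return named character vector: generic name -> ATC letter.
#' @export
load_atc <- function(path = NULL) {
  path <- path %||% system.file("extdata", "atc_classes.csv",
                                package = "ssfaers", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("generic", "atc_code") %in% names(tab)))
  stats::setNames(toupper(trimws(tab$atc_code)), tolower(trimws(tab$generic)))
}

# Uppercase, trim, collapse whitespace/punctuation runs, optionally
# strip trailing salt/dosage tokens.
canonicalize_drug_name <- function(raw, strip_salts = TRUE) {
  x <- toupper(trimws(as.character(raw)))
  x <- gsub("[[:space:].,;:]+", " ", x)
  x <- trimws(x)
  if (strip_salts) {
    pat <- paste0(" (", paste(SALT_SUFFIXES, collapse = "|"), ")$")
    repeat {
      stripped <- sub(pat, "", x)
      if (identical(stripped, x)) break
      x <- stripped
    }
  }
  x
}

#' Normalize raw drug names to generics
#'
#' Canonicalizes each raw string (uppercase, trim, collapse internal
#' whitespace, strip trailing salt/dosage tokens from a fixed list) and
#' looks it up in the synonym table. Unmapped names pass through
#' unchanged and are flagged. Multi-ingredient strings (containing "/"
#' or "+") are only mapped on an exact synonym entry, since combination
#' products are ambiguous with respect to the suspect ingredient.
#'
#' @param raw character vector of raw drug name strings.
#' @param synonyms named vector from [load_synonyms()].
#' @return character vector of generic names (unmapped inputs returned
#'   canonicalized but otherwise as-is), with a logical attribute
#'   `mapped`.
#' @export
normalize_drug_name <- function(raw, synonyms = load_synonyms()) {
  key <- canonicalize_drug_name(raw, strip_salts = TRUE)
  exact_key <- canonicalize_drug_name(raw, strip_salts = FALSE)
  multi <- grepl("[/+]", exact_key)
  hit <- unname(synonyms[key])
  hit_exact <- unname(synonyms[exact_key])
  # combination products: exact entry only, no salt stripping applied
  hit[multi] <- hit_exact[multi]
  mapped <- !is.na(hit)
  out <- ifelse(mapped, hit, key)
  attr(out, "mapped") <- mapped
  out
}

#' Assign an ATC first-level class
#'
#' Exact lookup of a generic name in the ATC table; misses are
#' reported as `"unclassified"`.
#'
#' @param generic character vector of generic names.
#' @param atc named vector from [load_atc()].
#' @return character vector of single-letter ATC codes or
#'   `"unclassified"`.
#' @export
assign_atc_class <- function(generic, atc = load_atc()) {
  hit <- unname(atc[tolower(trimws(generic))])
  ifelse(is.na(hit), "unclassified", hit)
}

#' Human-readable ATC first-level label
#'
#' @param code character vector of ATC letters (or `"unclassified"`).
#' @return character vector of labels.
#' @export
atc_class_label <- function(code) {
  lab <- unname(ATC_LABELS[toupper(code)])
  ifelse(is.na(lab), "unclassified", lab)
}
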