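# Synthetic FAERS-dialect report generator with planted ground truth.
#
# Emulates the structures the analysis pipeline must survive: age
# units, sex/country/reporter/outcome mixtures, trade-name and salt
# variants of drug names, duplicate case versions, missing and partial
# dates, and per-drug reporting-rate elevations for the target event
# with class-specific onset-time distributions. Defaults mirror the
# published cohort mixtures so descriptive output resembles real
# elderly serotonin-syndrome reporting at a glance.

OTHER_PTS <- c("Nausea", "Dizziness", "Fall", "Rash", "Headache", "Tremor",
               "Confusional state", "Vomiting", "Fatigue", "Dyspnoea",
               "Pruritus", "Diarrhoea")

#' Default synthetic drug roster
#'
#' Fifty generics spanning the ATC classes that dominate serotonin
#' syndrome reporting. Five drugs (one per major class) carry a
#' planted reporting-rate ratio `lambda = 10` for the target event;
#' the other 45 report at the background rate (`lambda = 1`). Onset
#' distributions are log-normal with class medians of 16.5 days
#' (nervous system), 1.5 (antiinfectives, alimentary tract), 2.5
#' (musculo-skeletal), 0.5 (dermatologicals, various) and 5 days for
#' the small remaining classes.
#'
#' @return data.frame `generic, trade, atc, lambda, onset_median,
#'   onset_sdlog`.
#' @export
default_drug_roster <- function() {
  synonyms <- utils::read.csv(system.file("extdata", "drug_synonyms.csv",
                                          package = "ssfaers",
                                          mustWork = TRUE),
                              stringsAsFactors = FALSE)
  atc_tab <- utils::read.csv(system.file("extdata", "atc_classes.csv",
                                         package = "ssfaers",
                                         mustWork = TRUE),
                             stringsAsFactors = FALSE)
  roster <- data.frame(generic = atc_tab$generic, atc = atc_tab$atc_code,
                       stringsAsFactors = FALSE)
  # first synonym entry per generic that is not the identity row
  trade <- vapply(roster$generic, function(g) {
    hits <- synonyms$raw[synonyms$generic == g &
                           toupper(synonyms$raw) != toupper(g)]
    if (length(hits)) hits[[1L]] else NA_character_
  }, character(1))
  roster$trade <- unname(trade)
  planted <- c("fluoxetine", "tramadol", "linezolid", "ondansetron",
               "cyclobenzaprine")
  roster$lambda <- ifelse(roster$generic %in% planted, 10, 1)
  med <- c(N = 16.5, J = 1.5, A = 1.5, M = 2.5, D = 0.5, V = 0.5,
           R = 5, B = 5)
  sdl <- c(N = 1.6, J = 1.0, A = 1.0, M = 0.6, D = 0.5, V = 0.5,
           R = 1.0, B = 1.0)
  roster$onset_median <- unname(med[roster$atc])
  roster$onset_sdlog <- unname(sdl[roster$atc])
  roster
}

#' Build a synthetic-study configuration
#'
#' Defaults are the study conditions used throughout the package's
#' validation: demographic mixtures mirroring the published elderly
#' serotonin-syndrome cohort, a 5% base target-event reporting rate,
#' 10% duplicate case versions, 30% trade-name substitution, and the
#' planted roster of [default_drug_roster()].
#'
#' @param n_reports reports per quarter.
#' @param quarters character vector of quarter labels.
#' @param roster drug roster data.frame.
#' @param base_pt_rate target-event probability for a lambda = 1 drug.
#' @param signal_lambda_threshold planted lambda above which a roster
#'   drug counts as a true signal.
#' @param duplicate_rate fraction of cases emitted twice with a later
#'   receipt date.
#' @param trade_name_rate fraction of primary-suspect mentions using
#'   the trade name.
#' @param salt_suffix_rate fraction of mentions with a trailing salt
#'   token appended.
#' @param p_elderly fraction of reports aged 65+.
#' @param age_band_probs mixture over elderly age bands.
#' @param sex_probs mixture over female/male/missing.
#' @param reporter_probs mixture over healthcare/non-healthcare/missing.
#' @param outcome_probs mixture over outcome codes DE/DS/HO/LT/OT.
#' @param country_probs named country-code weights.
#' @param missing_event_date_rate,missing_start_date_rate,partial_date_rate,missing_age_rate
#'   missingness rates for the corresponding fields.
#' @param seed integer RNG seed; all generator randomness flows from
#'   it (quarter i uses stream seed `seed + i - 1`).
#' @return a validated `ss_config` list.
#' @export
synthetic_config <- function(n_reports = 2000L,
                             quarters = "2024Q1",
                             roster = default_drug_roster(),
                             base_pt_rate = 0.05,
                             signal_lambda_threshold = 2,
                             duplicate_rate = 0.10,
                             trade_name_rate = 0.30,
                             salt_suffix_rate = 0.05,
                             p_elderly = 0.75,
                             age_band_probs = c("65-74" = 0.607,
                                                "75-84" = 0.293,
                                                "85-94" = 0.086,
                                                ">=95" = 0.014),
                             sex_probs = c(female = 0.615, male = 0.376,
                                           missing = 0.009),
                             reporter_probs = c(healthcare = 0.842,
                                                `non-healthcare` = 0.099,
                                                missing = 0.059),
                             outcome_probs = c(DE = 0.074, DS = 0.007,
                                               HO = 0.464, LT = 0.184,
                                               OT = 0.271),
                             country_probs = c(US = 0.344, ES = 0.090,
                                               GB = 0.080, FR = 0.050,
                                               JP = 0.045, CA = 0.034,
                                               IT = 0.026, DE = 0.020,
                                               NL = 0.020, PT = 0.017,
                                               AU = 0.08, BR = 0.08,
                                               SE = 0.06, CH = 0.054),
                             missing_event_date_rate = 0.30,
                             missing_start_date_rate = 0.15,
                             partial_date_rate = 0.05,
                             missing_age_rate = 0.02,
                             seed = 101L) {
  config <- list(n_reports = as.integer(n_reports), quarters = quarters,
                 roster = roster, base_pt_rate = base_pt_rate,
                 signal_lambda_threshold = signal_lambda_threshold,
                 duplicate_rate = duplicate_rate,
                 trade_name_rate = trade_name_rate,
                 salt_suffix_rate = salt_suffix_rate,
                 p_elderly = p_elderly, age_band_probs = age_band_probs,
                 sex_probs = sex_probs, reporter_probs = reporter_probs,
                 outcome_probs = outcome_probs,
                 country_probs = country_probs,
                 missing_event_date_rate = missing_event_date_rate,
                 missing_start_date_rate = missing_start_date_rate,
                 partial_date_rate = partial_date_rate,
                 missing_age_rate = missing_age_rate,
                 seed = as.integer(seed))
  validate_config(config)
  structure(config, class = "ss_config")
}

validate_config <- function(config) {
  for (nm in c("age_band_probs", "sex_probs", "reporter_probs",
               "outcome_probs")) {
    p <- config[[nm]]
    if (any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-6)
      stop(nm, " must be probabilities summing to 1")
  }
  if (any(config$country_probs < 0))
    stop("country_probs must be non-negative")
  for (nm in c("duplicate_rate", "trade_name_rate", "salt_suffix_rate",
               "p_elderly", "base_pt_rate", "missing_event_date_rate",
               "missing_start_date_rate", "partial_date_rate",
               "missing_age_rate")) {
    p <- config[[nm]]
    if (p < 0 || p > 1) stop(nm, " must lie in [0, 1]")
  }
  stopifnot(config$n_reports >= 0L,
            all(grepl("^[0-9]{4}Q[1-4]$", config$quarters)),
            all(config$roster$lambda > 0),
            all(config$roster$onset_median > 0))
  invisible(config)
}

#' Read a generator configuration from YAML
#'
#' Scalar fields and probability mixtures override the defaults of
#' [synthetic_config()]; a `roster` section (list of records with
#' `generic, trade, atc, lambda, onset_median, onset_sdlog`) replaces
#' the default roster.
#'
#' @param path YAML file path.
#' @return an `ss_config`.
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- list()
  for (nm in c("n_reports", "quarters", "base_pt_rate",
               "signal_lambda_threshold", "duplicate_rate",
               "trade_name_rate", "salt_suffix_rate", "p_elderly",
               "missing_event_date_rate", "missing_start_date_rate",
               "partial_date_rate", "missing_age_rate", "seed"))
    if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
  for (nm in c("age_band_probs", "sex_probs", "reporter_probs",
               "outcome_probs", "country_probs"))
    if (!is.null(raw[[nm]])) args[[nm]] <- unlist(raw[[nm]])
  if (!is.null(raw$roster))
    args$roster <- do.call(rbind, lapply(raw$roster, as.data.frame))
  do.call(synthetic_config, args)
}

#' Generate synthetic quarterly reports with known truth
#'
#' Each report draws one primary-suspect roster drug; the target
#' preferred term is assigned with probability
#' `min(1, base_pt_rate * lambda_drug)`; onset days are drawn from the
#' drug's log-normal class distribution and anchored to the event and
#' therapy start dates. A configured fraction of cases is emitted
#' twice with a later receipt date (to exercise deduplication), and
#' trade names / salt suffixes replace generic names at configured
#' rates (to exercise normalization).
#'
#' @param config an `ss_config` from [synthetic_config()].
#' @param target_pt preferred term planted for elevated drugs.
#' @return list with `quarters` (list of `faers_quarter`) and `truth`
#'   (data.frame `generic, atc, lambda, onset_median, is_signal`).
#' @export
generate_reports <- function(config = synthetic_config(),
                             target_pt = "Serotonin syndrome") {
  validate_config(config)
  roster <- config$roster
  quarters <- vector("list", length(config$quarters))
  case_counter <- 0L
  for (qi in seq_along(config$quarters)) {
    set.seed(config$seed + qi - 1L)
    quarters[[qi]] <- generate_one_quarter(config, config$quarters[qi],
                                           case_counter, target_pt)
    case_counter <- case_counter + config$n_reports
  }
  truth <- data.frame(generic = roster$generic, atc = roster$atc,
                      lambda = roster$lambda,
                      onset_median = roster$onset_median,
                      is_signal = roster$lambda >= config$signal_lambda_threshold,
                      stringsAsFactors = FALSE)
  list(quarters = quarters, truth = truth)
}

generate_one_quarter <- function(config, quarter_label, case_counter,
                                 target_pt) {
  n <- config$n_reports
  roster <- config$roster
  fmt_date <- function(d) ifelse(is.na(d), "", format(d, "%Y%m%d"))
  qs <- quarter_start(quarter_label)
  qdays <- as.integer(quarter_end(quarter_label) - qs) + 1L

  if (n == 0L) {
    empty <- function(...) as.data.frame(stats::setNames(
      rep(list(character(0)), length(c(...))), c(...)),
      stringsAsFactors = FALSE)
    return(structure(list(
      quarter = quarter_label,
      demo = empty("primaryid", "caseid", "event_dt", "age", "age_cod",
                   "sex", "occp_cod", "reporter_country", "fda_dt"),
      drug = empty("primaryid", "caseid", "drug_seq", "role_cod",
                   "drugname", "prod_ai"),
      reac = empty("primaryid", "caseid", "pt"),
      outc = empty("primaryid", "caseid", "outc_cod"),
      ther = empty("primaryid", "caseid", "dsg_drug_seq", "start_dt",
                   "end_dt"),
      skipped = integer(0)), class = "faers_quarter"))
  }

  caseid <- as.character(10000000L + case_counter + seq_len(n))
  primaryid <- paste0(caseid, "1")

  # demographics ------------------------------------------------------
  elderly <- stats::runif(n) < config$p_elderly
  band <- sample(names(config$age_band_probs), n, replace = TRUE,
                 prob = config$age_band_probs)
  lo <- unname(c("65-74" = 65, "75-84" = 75, "85-94" = 85, ">=95" = 95)[band])
  wid <- unname(c("65-74" = 10, "75-84" = 10, "85-94" = 10, ">=95" = 5)[band])
  age <- ifelse(elderly, floor(lo + stats::runif(n) * wid),
                floor(30 + stats::runif(n) * 35))
  unit_pick <- stats::runif(n)
  age_val <- ifelse(unit_pick < 0.90, as.character(age),
                    ifelse(unit_pick < 0.95, as.character(age * 12L),
                           sprintf("%.1f", age / 10)))
  age_cod <- ifelse(unit_pick < 0.90, "YR",
                    ifelse(unit_pick < 0.95, "MON", "DEC"))
  drop_age <- stats::runif(n) < config$missing_age_rate
  age_val[drop_age] <- ""
  age_cod[drop_age] <- ""

  sex_cls <- sample(names(config$sex_probs), n, replace = TRUE,
                    prob = config$sex_probs)
  sex <- unname(c(female = "F", male = "M", missing = "")[sex_cls])
  country <- sample(names(config$country_probs), n, replace = TRUE,
                    prob = config$country_probs)
  rep_cls <- sample(names(config$reporter_probs), n, replace = TRUE,
                    prob = config$reporter_probs)
  occp <- character(n)
  occp[rep_cls == "healthcare"] <-
    sample(c("MD", "PH", "HP", "OT"), sum(rep_cls == "healthcare"),
           replace = TRUE, prob = c(0.5, 0.25, 0.15, 0.10))
  occp[rep_cls == "non-healthcare"] <-
    sample(c("CN", "LW"), sum(rep_cls == "non-healthcare"),
           replace = TRUE, prob = c(0.9, 0.1))

  # drugs and events --------------------------------------------------
  ps_idx <- sample(nrow(roster), n, replace = TRUE)
  has_pt <- stats::runif(n) < pmin(1, config$base_pt_rate *
                                     roster$lambda[ps_idx])
  onset <- floor(stats::rlnorm(n, log(roster$onset_median[ps_idx]),
                               roster$onset_sdlog[ps_idx]))
  fda <- qs + floor(stats::runif(n) * qdays)
  event <- fda - sample(0:45, n, replace = TRUE)
  start <- event - onset

  event_str <- fmt_date(event)
  start_str <- fmt_date(start)
  partial <- stats::runif(n) < config$partial_date_rate
  event_str[partial] <- substr(event_str[partial], 1L, 6L)
  start_partial <- stats::runif(n) < config$partial_date_rate
  start_str[start_partial] <- substr(start_str[start_partial], 1L, 6L)
  event_str[stats::runif(n) < config$missing_event_date_rate] <- ""
  start_str[stats::runif(n) < config$missing_start_date_rate] <- ""

  generic <- roster$generic[ps_idx]
  use_trade <- stats::runif(n) < config$trade_name_rate &
    !is.na(roster$trade[ps_idx])
  drugname <- ifelse(use_trade, toupper(roster$trade[ps_idx]),
                     toupper(generic))
  add_salt <- !use_trade & stats::runif(n) < config$salt_suffix_rate
  drugname[add_salt] <- paste(drugname[add_salt], "HCL")

  demo <- data.frame(primaryid = primaryid, caseid = caseid,
                     event_dt = event_str, age = age_val,
                     age_cod = age_cod, sex = sex, occp_cod = occp,
                     reporter_country = country,
                     fda_dt = fmt_date(fda), stringsAsFactors = FALSE)

  drug <- data.frame(primaryid = primaryid, caseid = caseid,
                     drug_seq = "1", role_cod = "PS",
                     drugname = drugname,
                     prod_ai = toupper(generic), stringsAsFactors = FALSE)
  ther <- data.frame(primaryid = primaryid, caseid = caseid,
                     dsg_drug_seq = "1", start_dt = start_str,
                     end_dt = "", stringsAsFactors = FALSE)
  n_con <- stats::rbinom(n, 2L, 0.4)
  if (sum(n_con) > 0L) {
    rep_i <- rep(seq_len(n), n_con)
    seq_no <- unlist(lapply(n_con[n_con > 0L], function(k) 1L + seq_len(k)))
    con_idx <- sample(nrow(roster), length(rep_i), replace = TRUE)
    drug <- rbind(drug, data.frame(
      primaryid = primaryid[rep_i], caseid = caseid[rep_i],
      drug_seq = as.character(seq_no), role_cod = "C",
      drugname = toupper(roster$generic[con_idx]),
      prod_ai = toupper(roster$generic[con_idx]),
      stringsAsFactors = FALSE))
  }

  n_other <- 1L + stats::rbinom(n, 1L, 0.5)
  rep_i <- rep(seq_len(n), n_other)
  other_pt <- sample(OTHER_PTS, length(rep_i), replace = TRUE)
  reac <- data.frame(primaryid = primaryid[rep_i], caseid = caseid[rep_i],
                     pt = other_pt, stringsAsFactors = FALSE)
  if (any(has_pt))
    reac <- rbind(data.frame(primaryid = primaryid[has_pt],
                             caseid = caseid[has_pt], pt = target_pt,
                             stringsAsFactors = FALSE), reac)
  reac <- reac[order(as.numeric(reac$primaryid)), , drop = FALSE]

  outc_code <- sample(names(config$outcome_probs), n, replace = TRUE,
                      prob = config$outcome_probs)
  outc <- data.frame(primaryid = primaryid, caseid = caseid,
                     outc_cod = outc_code, stringsAsFactors = FALSE)
  extra <- stats::runif(n) < 0.10
  if (any(extra))
    outc <- rbind(outc, data.frame(primaryid = primaryid[extra],
                                   caseid = caseid[extra],
                                   outc_cod = sample(c("HO", "OT", "CA", "RI"),
                                                     sum(extra),
                                                     replace = TRUE),
                                   stringsAsFactors = FALSE))
  outc <- outc[order(as.numeric(outc$primaryid)), , drop = FALSE]

  # duplicate case versions ------------------------------------------
  dup <- stats::runif(n) < config$duplicate_rate
  if (any(dup)) {
    dup_map <- function(tab) {
      keep <- tab$caseid %in% caseid[dup]
      t2 <- tab[keep, , drop = FALSE]
      t2$primaryid <- paste0(t2$caseid, "2")
      t2
    }
    demo2 <- dup_map(demo)
    demo2$fda_dt <- fmt_date(fda[dup] + 30L + floor(stats::runif(sum(dup)) *
                                                      150))
    demo <- rbind(demo, demo2)
    drug <- rbind(drug, dup_map(drug))
    reac <- rbind(reac, dup_map(reac))
    outc <- rbind(outc, dup_map(outc))
    ther <- rbind(ther, dup_map(ther))
  }
  rownames(demo) <- rownames(drug) <- rownames(reac) <- rownames(outc) <-
    rownames(ther) <- NULL

  structure(list(quarter = quarter_label, demo = demo, drug = drug,
                 reac = reac, outc = outc, ther = ther,
                 skipped = c(demo = 0L, drug = 0L, reac = 0L, outc = 0L,
                             ther = 0L)),
            class = "faers_quarter")
}

#' Write quarters as FAERS-dialect ASCII files
#'
#' One `$`-delimited file per table and quarter (`DEMOyyQq.txt`, ...),
#' first line the header, dates as YYYYMMDD, missing fields empty.
#' Output is readable by [read_quarter()] field-for-field.
#'
#' @param quarters list of `faers_quarter` objects (or one).
#' @param out_dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_faers_ascii <- function(quarters, out_dir) {
  if (inherits(quarters, "faers_quarter")) quarters <- list(quarters)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  paths <- character(0)
  for (q in quarters) {
    suffix <- paste0(substr(q$quarter, 3L, 4L), substr(q$quarter, 5L, 6L))
    for (tab in FAERS_TABLES) {
      df <- q[[tolower(tab)]]
      file <- file.path(out_dir, paste0(tab, suffix, ".txt"))
      lines <- paste(names(df), collapse = "$")
      if (nrow(df) > 0L)
        lines <- c(lines, do.call(paste, c(df, sep = "$")))
      writeLines(lines, file)
      paths <- c(paths, file)
    }
  }
  invisible(paths)
}
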