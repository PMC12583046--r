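# Full-study orchestration: read -> deduplicate -> cohort -> normalize
# -> disproportionality (main + healthcare-professional sensitivity
# run) -> volcano -> time-to-onset -> descriptive, with all plot-ready
# tables and a run manifest written to disk.

#' Run the complete serotonin-syndrome analysis pipeline
#'
#' Executes every stage of the analysis on a directory of
#' FAERS-dialect quarterly files and writes `signals.csv`,
#' `signals_professional.csv`, `volcano.csv`, `table1.csv`,
#' `tto_summary.csv`, `tto_tests.csv`, `ecdf.csv` and a JSON
#' `manifest.json` (configuration echo, input-file hashes, and report
#' counts at each stage) to `out_dir`. The sensitivity analysis is the
#' same disproportionality stage re-run on the cohort restricted to
#' healthcare-professional reporters.
#'
#' @param data_dir directory of quarterly FAERS-dialect files.
#' @param out_dir output directory, created if needed; `NULL` skips
#'   writing and only returns the tables.
#' @param quarters quarter labels to read; `NULL` autodetects from the
#'   DEMO file names.
#' @param target_pt MedDRA preferred term of the target event.
#' @param age_min elderly age threshold in years (inclusive).
#' @param synonyms,atc mapping tables (packaged defaults).
#' @param background_scope `"elderly"` restricts the
#'   disproportionality background to reports aged `age_min`+;
#'   `"all"` uses every deduplicated report.
#' @param strict_ebgm also require EB05 > 2 in the signal rule.
#' @param fit_prior fit the MGPS prior to the run's tables when at
#'   least 50 are usable (otherwise, or when `FALSE`, the conventional
#'   default prior is used).
#' @param professional_only if `TRUE` the *main* run itself is
#'   restricted to healthcare-professional reporters.
#' @return invisibly, a list of all result tables plus the manifest.
#' @export
run_pipeline <- function(data_dir, out_dir = NULL, quarters = NULL,
                         target_pt = "Serotonin syndrome", age_min = 65,
                         synonyms = load_synonyms(), atc = load_atc(),
                         background_scope = c("elderly", "all"),
                         strict_ebgm = FALSE, fit_prior = TRUE,
                         professional_only = FALSE) {
  background_scope <- match.arg(background_scope)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if (is.null(quarters)) {
    demo_files <- list.files(data_dir, pattern = "^DEMO[0-9]{2}Q[1-4]")
    if (length(demo_files) == 0L)
      stop("pipeline stage 'read' failed: no DEMO files under ", data_dir,
           "; check --data-dir", call. = FALSE)
    suffix <- sub("^DEMO([0-9]{2}Q[1-4]).*$", "\\1", demo_files)
    century <- ifelse(as.integer(substr(suffix, 1L, 2L)) < 50L, "20", "19")
    quarters <- sort(unique(paste0(century, substr(suffix, 1L, 2L),
                                   substr(suffix, 3L, 4L))))
  }
  raw <- stage("read", lapply(quarters, function(q)
    read_quarter(data_dir, q)))
  n_raw <- sum(vapply(raw, function(q) nrow(q$demo), integer(1)))

  cases <- stage("deduplicate", deduplicate_cases(raw))
  sel <- stage("cohort", select_cohort(cases, target_pt = target_pt,
                                       age_min = age_min))
  cohort <- sel$cohort
  background <- if (background_scope == "elderly") sel$background else cases
  if (professional_only) {
    keep <- cohort$demo$report_id[!is.na(cohort$demo$reporter_class) &
                                    cohort$demo$reporter_class == "healthcare"]
    if (length(keep) == 0L)
      stop("pipeline stage 'reporter-filter' failed: empty cohort after ",
           "reporter filter", call. = FALSE)
    cohort <- subset_cases(cohort, keep)
  }

  run_signals <- function(coh, bg) {
    tabs <- contingency_tables(coh, bg, synonyms = synonyms)
    prior <- default_gps_prior()
    usable <- sum(is.finite(tabs$E) & tabs$E > 0 & tabs$evaluable)
    if (isTRUE(fit_prior) && usable >= 50L)
      prior <- tryCatch(fit_gps_prior(tabs$a[tabs$evaluable],
                                      tabs$E[tabs$evaluable]),
                        error = function(e) default_gps_prior(),
                        warning = function(w) default_gps_prior())
    met <- signal_metrics(tabs, prior = prior, strict_ebgm = strict_ebgm)
    met$atc_class <- assign_atc_class(met$drug, atc)
    met[order(-met$a, met$drug),
        c("drug", "atc_class", "a", "b", "c", "d", "E", "RR", "ror",
          "ror_lo", "ror_hi", "prr", "chi2", "ic", "ic_lo", "ebgm",
          "eb05", "fisher_p", "p_adj", "is_signal")]
  }

  signals <- stage("disproportionality", run_signals(cohort, background))

  # sensitivity: healthcare-professional reporters only
  prof_ids <- cohort$demo$report_id[!is.na(cohort$demo$reporter_class) &
                                      cohort$demo$reporter_class ==
                                      "healthcare"]
  bg_prof_ids <- background$demo$report_id[
    !is.na(background$demo$reporter_class) &
      background$demo$reporter_class == "healthcare"]
  signals_prof <- stage("sensitivity", {
    if (length(prof_ids) == 0L)
      stop("empty cohort after reporter filter")
    run_signals(subset_cases(cohort, prof_ids),
                subset_cases(background, bg_prof_ids))
  })

  volcano <- stage("volcano", {
    ev <- signals[signals$a + signals$b > 0, , drop = FALSE]
    data.frame(drug = ev$drug, log_ror = log(ev$ror),
               neg_log10_p_adj = -log10(pmax(ev$p_adj, 1e-300)),
               n_reports = ev$a, stringsAsFactors = FALSE)
  })

  tto <- stage("tto", tto_records(cohort, synonyms = synonyms, atc = atc))
  tto_summary <- stage("tto-summary", {
    rbind(cbind(stratum = "overall", summarize_tto(tto)),
          cbind(stratum = "atc_class", summarize_tto(tto, "atc_class")),
          cbind(stratum = "sex",
                summarize_tto(tto[!is.na(tto$sex), , drop = FALSE], "sex")),
          cbind(stratum = "age_band",
                summarize_tto(tto[!is.na(tto$age_band), , drop = FALSE],
                              "age_band")),
          cbind(stratum = "drug", summarize_tto(tto, "drug")))
  })
  tto_tests <- stage("tto-tests", tto_strata_tests(tto))
  ecdf_tab <- stage("ecdf", {
    rbind(ecdf_points(tto),
          ecdf_points(tto, "atc_class"),
          ecdf_points(tto[!is.na(tto$sex), , drop = FALSE], "sex"))
  })

  table1 <- stage("descriptive", summarize_cohort(cohort))

  manifest <- list(
    target_pt = target_pt, age_min = age_min,
    background_scope = background_scope, strict_ebgm = strict_ebgm,
    quarters = quarters,
    input_md5 = as.list(tools::md5sum(list.files(data_dir,
                                                 full.names = TRUE))),
    counts = list(raw_reports = n_raw,
                  deduplicated_cases = nrow(cases$demo),
                  background = nrow(sel$background$demo),
                  cohort = nrow(cohort$demo),
                  cohort_professional = length(prof_ids),
                  tto_records = nrow(tto),
                  tto_excluded = as.list(attr(tto, "exclusions"))))

  results <- list(signals = signals, signals_professional = signals_prof,
                  volcano = volcano, table1 = table1,
                  tto_records = tto, tto_summary = tto_summary,
                  tto_tests = tto_tests, ecdf = ecdf_tab,
                  manifest = manifest)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir))
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name)
      utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
    wr(signals, "signals.csv")
    wr(signals_prof, "signals_professional.csv")
    wr(volcano, "volcano.csv")
    wr(table1, "table1.csv")
    wr(tto_summary, "tto_summary.csv")
    wr(tto_tests, "tto_tests.csv")
    wr(ecdf_tab, "ecdf.csv")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(results)
}

# Rank tests across the standard strata; groups with fewer than two
# records are dropped inside the test helpers.
tto_strata_tests <- function(tto) {
  rows <- list()
  add <- function(comparison, statistic, p, p_adj = NA_real_)
    rows[[length(rows) + 1L]] <<- data.frame(
      comparison = comparison, statistic = statistic, p = p, p_adj = p_adj,
      stringsAsFactors = FALSE)

  sx <- tto[!is.na(tto$sex), , drop = FALSE]
  if (length(unique(sx$sex)) == 2L &&
      all(table(sx$sex) >= 2L)) {
    mw <- mann_whitney_u(sx$tto_days[sx$sex == "female"],
                         sx$tto_days[sx$sex == "male"])
    add("sex: female vs male (Mann-Whitney U)", mw$U, mw$p)
  }
  for (strat in c("atc_class", "age_band")) {
    st <- tto[!is.na(tto[[strat]]), , drop = FALSE]
    enough <- names(which(table(st[[strat]]) >= 2L))
    if (length(enough) >= 2L) {
      kw <- kruskal_wallis_pairwise(st$tto_days, st[[strat]])
      add(paste0(strat, " (Kruskal-Wallis H)"), kw$H, kw$p)
      for (i in seq_len(nrow(kw$pairwise)))
        add(paste0(strat, ": ", kw$pairwise$group1[i], " vs ",
                   kw$pairwise$group2[i], " (Mann-Whitney U)"),
            kw$pairwise$U[i], kw$pairwise$p[i], kw$pairwise$p_adj[i])
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(comparison = character(0), statistic = numeric(0),
                      p = numeric(0), p_adj = numeric(0),
                      stringsAsFactors = FALSE)
  out
}
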