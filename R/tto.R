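# Time-to-onset analysis: per-report onset intervals, quartile
# summaries, cumulative-distribution points, and rank-based group
# comparisons (Mann-Whitney, Kruskal-Wallis with BH-adjusted pairwise
# tests).

#' Compute onset intervals in days
#'
#' Onset is the event date minus the therapy start date in whole days.
#' Same-day onset is recorded as 0.5 days so that sub-day onsets carry
#' a positive value (clusters of day-0 events then yield medians of
#' exactly 0.5 days). Negative intervals and missing/partial dates are
#' excluded with a reason code.
#'
#' @param event_date `Date` vector of adverse-event onset dates.
#' @param start_date `Date` vector of therapy start dates.
#' @param same_day_value value recorded for day-0 onsets, default 0.5.
#' @return data.frame with `tto_days` (NA when excluded) and
#'   `excluded_reason` (`NA`, `"missing_date"` or `"negative"`).
#' @export
compute_tto <- function(event_date, start_date, same_day_value = 0.5) {
  n <- max(length(event_date), length(start_date))
  event_date <- rep_len(as.Date(event_date), n)
  start_date <- rep_len(as.Date(start_date), n)
  days <- as.numeric(event_date - start_date)
  reason <- rep(NA_character_, n)
  reason[is.na(days)] <- "missing_date"
  reason[!is.na(days) & days < 0] <- "negative"
  days[!is.na(reason)] <- NA_real_
  days[!is.na(days) & days == 0] <- same_day_value
  data.frame(tto_days = days, excluded_reason = reason,
             stringsAsFactors = FALSE)
}

#' Assemble time-to-onset records for a cohort
#'
#' One record per (report, primary-suspect drug): the onset interval
#' from the drug's earliest therapy start date to the event date, with
#' the stratification keys used downstream (ATC class, sex, age band).
#' Reports with excluded intervals are dropped; exclusion counts are
#' attached as attribute `exclusions`.
#'
#' @param cohort target-event reports (`faers_cases`).
#' @param synonyms synonym table for drug-name normalization.
#' @param atc ATC table for class assignment.
#' @param same_day_value passed to [compute_tto()].
#' @return data.frame `report_id, drug, atc_class, sex, age_band,
#'   tto_days`.
#' @export
tto_records <- function(cohort, synonyms = load_synonyms(),
                        atc = load_atc(), same_day_value = 0.5) {
  stopifnot(inherits(cohort, "faers_cases"))
  ps <- cohort$drugs[cohort$drugs$role == "PS", , drop = FALSE]
  if (nrow(ps) == 0L)
    return(structure(data.frame(report_id = character(0), drug = character(0),
                                atc_class = character(0), sex = character(0),
                                age_band = character(0), tto_days = numeric(0),
                                stringsAsFactors = FALSE),
                     exclusions = c(missing_date = 0L, negative = 0L)))
  ps$drug <- as.character(normalize_drug_name(ps$raw_name, synonyms))
  # earliest start per (report, generic drug)
  key <- paste(ps$report_id, ps$drug, sep = "\r")
  start_num <- ifelse(is.na(ps$start_date), Inf, as.numeric(ps$start_date))
  first <- tapply(start_num, key, min)
  uniq <- !duplicated(key)
  rec <- ps[uniq, c("report_id", "drug"), drop = FALSE]
  rec$start_date <- as.Date(ifelse(is.finite(first[key[uniq]]),
                                   first[key[uniq]], NA),
                            origin = "1970-01-01")
  demo <- cohort$demo
  idx <- match(rec$report_id, demo$report_id)
  rec$event_date <- demo$event_date[idx]
  tto <- compute_tto(rec$event_date, rec$start_date,
                     same_day_value = same_day_value)
  excl <- c(missing_date = sum(tto$excluded_reason == "missing_date",
                               na.rm = TRUE),
            negative = sum(tto$excluded_reason == "negative", na.rm = TRUE))
  keep <- !is.na(tto$tto_days)
  out <- data.frame(report_id = rec$report_id[keep],
                    drug = rec$drug[keep],
                    atc_class = assign_atc_class(rec$drug[keep], atc),
                    sex = demo$sex[idx][keep],
                    age_band = age_band(demo$age_years[idx][keep]),
                    tto_days = tto$tto_days[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, exclusions = excl)
}

#' Quartile summaries of onset intervals by group
#'
#' Quartiles follow the linear-interpolation convention on `p (n - 1)`
#' positions (`stats::quantile` type 7). Groups with fewer than two
#' valid records are dropped (and reported via attribute `dropped`).
#'
#' @param records data.frame from [tto_records()] (needs `tto_days`).
#' @param group_by column name(s) to stratify on, or `NULL` for one
#'   overall summary.
#' @return data.frame `group, n, q1, median, q3`.
#' @export
summarize_tto <- function(records, group_by = NULL) {
  v <- records$tto_days
  key <- if (is.null(group_by)) rep("overall", length(v))
  else do.call(paste, c(records[, group_by, drop = FALSE], sep = "/"))
  groups <- split(v, key)
  ns <- vapply(groups, length, integer(1))
  dropped <- names(groups)[ns < 2L]
  groups <- groups[ns >= 2L]
  out <- data.frame(
    group = names(groups),
    n = vapply(groups, length, integer(1)),
    q1 = vapply(groups, function(x) unname(stats::quantile(x, 0.25, type = 7)),
                numeric(1)),
    median = vapply(groups, function(x) unname(stats::quantile(x, 0.5,
                                                               type = 7)),
                    numeric(1)),
    q3 = vapply(groups, function(x) unname(stats::quantile(x, 0.75, type = 7)),
                numeric(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, dropped = dropped)
}

#' Empirical cumulative distribution points by group
#'
#' @param records data.frame with `tto_days`.
#' @param group_by column name(s) to stratify on, or `NULL` for one
#'   overall curve.
#' @return data.frame `group, t, fraction` of sorted step points; each
#'   group's final ordinate is exactly 1.
#' @export
ecdf_points <- function(records, group_by = NULL) {
  v <- records$tto_days
  key <- if (is.null(group_by)) rep("overall", length(v))
  else do.call(paste, c(records[, group_by, drop = FALSE], sep = "/"))
  groups <- split(v, key)
  groups <- groups[lengths(groups) > 0L]
  parts <- lapply(names(groups), function(g) {
    x <- sort(groups[[g]])
    t <- unique(x)
    frac <- vapply(t, function(ti) mean(x <= ti), numeric(1))
    data.frame(group = g, t = t, fraction = frac, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Mann-Whitney U test
#'
#' Midrank U statistic. For pooled sample sizes of at most 10 the
#' two-sided p-value is computed by exhaustive enumeration of all
#' group assignments (symmetric tail convention, valid under ties);
#' otherwise a normal approximation with tie-corrected variance and a
#' 0.5 continuity correction is used. When every pooled value is tied
#' the test degenerates to `U = n1 n2 / 2`, `p = 1`.
#'
#' @param x,y numeric samples (each nonempty).
#' @param method `"auto"` (enumeration when `n1+n2 <= 10`), `"exact"`,
#'   or `"normal"`.
#' @return list with `U`, `p`, and the `method` used.
#' @export
mann_whitney_u <- function(x, y, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (method == "auto") method <- if (n <= 10L) "exact" else "normal"

  if (method == "exact") {
    idx <- utils::combn(n, n1)
    Us <- apply(idx, 2L, function(id) sum(r[id]) - n1 * (n1 + 1) / 2)
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
  } else {
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- U - mu
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  list(U = U, p = p, method = method)
}

#' Kruskal-Wallis test with BH-adjusted pairwise comparisons
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square reference on k - 1
#' degrees of freedom, followed by pairwise Mann-Whitney tests across
#' all group pairs with Benjamini-Hochberg adjustment.
#'
#' @param values numeric vector.
#' @param groups grouping vector, same length.
#' @param min_n minimum records per group, default 2; smaller groups
#'   are dropped first.
#' @return list with `H`, `p`, `n_groups`, and a `pairwise` data.frame
#'   (`group1, group2, U, p, p_adj`).
#' @export
kruskal_wallis_pairwise <- function(values, groups, min_n = 2L) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- as.character(groups[keep])
  sizes <- table(groups)
  eligible <- names(sizes)[sizes >= min_n]
  if (length(eligible) < 2L)
    stop("need at least two groups with >= ", min_n, " records")
  keep <- groups %in% eligible
  values <- values[keep]; groups <- groups[keep]
  kw <- stats::kruskal.test(values, factor(groups))
  gl <- sort(unique(groups))
  pairs <- utils::combn(gl, 2L)
  pw <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                   U = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    res <- mann_whitney_u(values[groups == pairs[1L, i]],
                          values[groups == pairs[2L, i]])
    pw$U[i] <- res$U
    pw$p[i] <- res$p
  }
  pw$p_adj <- stats::p.adjust(pw$p, method = "BH")
  list(H = unname(kw$statistic), p = kw$p.value,
       n_groups = length(gl), pairwise = pw)
}
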