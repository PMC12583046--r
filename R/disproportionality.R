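# Four-algorithm disproportionality analysis on per-drug 2x2 tables:
#   ROR   with Woolf (log-normal) 95% interval,
#   PRR   with Pearson chi-square (no Yates correction),
#   BCPNN information component with its credible-bound approximation,
#   MGPS  empirical-Bayes geometric mean under a two-gamma mixture
#         prior (DuMouchel-type gamma-Poisson shrinker),
# plus Fisher/Bonferroni volcano statistics and the combined
# five-criterion signal rule.
#
# All cell-level computations are vectorized over tables.

#' Build a drug x event 2x2 contingency table
#'
#' Cell `a` counts background reports carrying the drug as primary
#' suspect (role PS) and the target event; `b` drug without event; `c`
#' event without drug; `d` neither. A report mentioning the drug
#' several times counts once. `E = (a+b)(a+c)/N` is the expected count
#' under independence and `RR = a/E` the observed rate ratio.
#'
#' @param cohort target-event reports (`faers_cases`), a subset of
#'   `background`.
#' @param background the full comparison population (`faers_cases`).
#' @param drug generic drug name (already normalized).
#' @param synonyms synonym table used to normalize primary-suspect
#'   mentions before matching.
#' @return one-row data.frame with `drug, a, b, c, d, N, E, RR,
#'   evaluable`.
#' @export
build_contingency <- function(cohort, background, drug,
                              synonyms = load_synonyms()) {
  tabs <- contingency_tables(cohort, background, synonyms = synonyms,
                             drugs = drug)
  if (nrow(tabs) == 0L) {
    n_pt <- length(unique(cohort$demo$report_id))
    N <- nrow(background$demo)
    tabs <- data.frame(drug = drug, a = 0L, b = 0L, c = n_pt,
                       d = N - n_pt, stringsAsFactors = FALSE)
    tabs <- finish_tables(tabs)
  }
  tabs
}

#' Build 2x2 tables for every primary-suspect drug in a population
#'
#' @inheritParams build_contingency
#' @param drugs optional character vector restricting which generic
#'   names to tabulate; default is every PS drug observed.
#' @return data.frame, one row per drug, columns `drug, a, b, c, d, N,
#'   E, RR, evaluable`.
#' @export
contingency_tables <- function(cohort, background,
                               synonyms = load_synonyms(), drugs = NULL) {
  stopifnot(inherits(cohort, "faers_cases"),
            inherits(background, "faers_cases"))
  ps <- background$drugs[background$drugs$role == "PS", , drop = FALSE]
  gen <- normalize_drug_name(ps$raw_name, synonyms)
  pairs <- unique(data.frame(report_id = ps$report_id,
                             drug = as.character(gen),
                             stringsAsFactors = FALSE))
  if (!is.null(drugs))
    pairs <- pairs[pairs$drug %in% drugs, , drop = FALSE]
  N <- nrow(background$demo)
  pt_ids <- unique(cohort$demo$report_id)
  n_pt <- length(pt_ids)
  if (nrow(pairs) == 0L)
    return(finish_tables(data.frame(drug = character(0), a = integer(0),
                                    b = integer(0), c = integer(0),
                                    d = integer(0))))
  has_pt <- pairs$report_id %in% pt_ids
  a <- tapply(has_pt, pairs$drug, sum)
  n_drug <- tapply(has_pt, pairs$drug, length)
  tabs <- data.frame(drug = names(a),
                     a = as.integer(a),
                     b = as.integer(n_drug - a),
                     stringsAsFactors = FALSE)
  tabs$c <- n_pt - tabs$a
  tabs$d <- N - tabs$a - tabs$b - tabs$c
  rownames(tabs) <- NULL
  finish_tables(tabs)
}

finish_tables <- function(tabs) {
  tabs$N <- tabs$a + tabs$b + tabs$c + tabs$d
  tabs$E <- ifelse(tabs$N > 0, (tabs$a + tabs$b) * (tabs$a + tabs$c) / tabs$N,
                   NA_real_)
  tabs$RR <- ifelse(!is.na(tabs$E) & tabs$E > 0, tabs$a / tabs$E, NA_real_)
  tabs$evaluable <- tabs$a + tabs$b > 0
  tabs
}

#' Reporting odds ratio with Woolf 95% interval
#'
#' `ROR = ad/(bc)` with bounds `exp(log ROR -/+ 1.96 * sqrt(1/a + 1/b +
#' 1/c + 1/d))`. If any cell is zero the Haldane-Anscombe correction
#' (+0.5 to all four cells) is applied first and flagged. Tables with
#' `a = 0` return missing metrics (they can never signal, since the
#' combined rule requires at least 3 cases).
#'
#' @param a,b,c,d integer vectors of cell counts (recycled).
#' @return data.frame with `ror, ror_lo, ror_hi, corrected`.
#' @export
compute_ror <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  corrected <- a == 0 | b == 0 | c == 0 | d == 0
  aa <- ifelse(corrected, a + 0.5, a); bb <- ifelse(corrected, b + 0.5, b)
  cc <- ifelse(corrected, c + 0.5, c); dd <- ifelse(corrected, d + 0.5, d)
  ror <- (aa * dd) / (bb * cc)
  se <- sqrt(1 / aa + 1 / bb + 1 / cc + 1 / dd)
  lo <- exp(log(ror) - 1.96 * se)
  hi <- exp(log(ror) + 1.96 * se)
  miss <- a == 0
  ror[miss] <- lo[miss] <- hi[miss] <- NA_real_
  data.frame(ror = ror, ror_lo = lo, ror_hi = hi, corrected = corrected)
}

#' Proportional reporting ratio and Pearson chi-square
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`; chi-square is Pearson's statistic on
#' the 2x2 table without continuity correction,
#' `N(ad-bc)^2 / [(a+b)(c+d)(a+c)(b+d)]`. Zero denominators yield
#' missing values.
#'
#' @inheritParams compute_ror
#' @return data.frame with `prr, chi2`.
#' @export
compute_prr_chi2 <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  N <- a + b + c + d
  prr <- ifelse(a + b > 0 & c > 0 & c + d > 0,
                (a / (a + b)) / (c / (c + d)), NA_real_)
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  chi2 <- ifelse(den > 0, N * (a * d - b * c)^2 / den, NA_real_)
  data.frame(prr = prr, chi2 = chi2)
}

#' BCPNN information component
#'
#' `IC = log2((a + 0.5) / (E + 0.5))` with the lower 95% credibility
#' bound approximation `IC025 = IC - 3.3 (a+0.5)^{-1/2} -
#' 2 (a+0.5)^{-3/2}` (gamma approximation to the posterior of the
#' shrunken observed/expected ratio).
#'
#' @param a observed count vector.
#' @param E expected count vector under independence (`> 0`).
#' @return data.frame with `ic, ic_lo`.
#' @export
compute_ic <- function(a, E) {
  n <- max(length(a), length(E))
  a <- rep_len(as.numeric(a), n); E <- rep_len(as.numeric(E), n)
  ic <- ifelse(E > 0, log2((a + 0.5) / (E + 0.5)), NA_real_)
  ic_lo <- ic - 3.3 * (a + 0.5)^(-0.5) - 2.0 * (a + 0.5)^(-1.5)
  data.frame(ic = ic, ic_lo = ic_lo)
}

#' Default MGPS prior
#'
#' The conventional two-gamma mixture starting prior: gamma(0.2, 0.1)
#' and gamma(2, 4) components (shape, rate) with mixture weight 1/3 on
#' the first.
#'
#' @return a `gps_prior` list with `w, alpha1, beta1, alpha2, beta2`.
#' @export
default_gps_prior <- function() {
  structure(list(w = 1 / 3, alpha1 = 0.2, beta1 = 0.1,
                 alpha2 = 2.0, beta2 = 4.0),
            class = "gps_prior")
}

validate_gps_prior <- function(prior) {
  stopifnot(is.list(prior),
            all(c("w", "alpha1", "beta1", "alpha2", "beta2") %in% names(prior)))
  # w in [0, 1]: the closed ends give the single-component shrinker
  with(prior, stopifnot(w >= 0, w <= 1, alpha1 > 0, beta1 > 0,
                        alpha2 > 0, beta2 > 0))
  invisible(prior)
}

# negative-binomial marginal P(a | alpha, beta, E) for one mixture
# component: a ~ NB(size = alpha, prob = beta/(beta+E))
nb_marginal <- function(a, alpha, beta, E) {
  stats::dnbinom(a, size = alpha, prob = beta / (beta + E))
}

#' MGPS empirical-Bayes geometric mean and EB05
#'
#' Under the two-gamma mixture prior, the posterior of the reporting
#' rate ratio given `(a, E)` is again a two-gamma mixture with
#' component `i` gamma(alpha_i + a, beta_i + E) and posterior weight
#' `Q` proportional to the prior weight times the negative-binomial
#' marginal of `a`. `EBGM = 2^{E[log2 lambda]}` via the digamma closed
#' form per component; `EB05` is the posterior 5th percentile found by
#' bisection on the mixture CDF to relative tolerance 1e-8.
#'
#' @param a observed count vector (non-negative integers).
#' @param E expected count vector (`> 0`).
#' @param prior a `gps_prior` list.
#' @return data.frame with `ebgm, eb05`.
#' @export
compute_ebgm <- function(a, E, prior = default_gps_prior()) {
  validate_gps_prior(prior)
  n <- max(length(a), length(E))
  a <- rep_len(as.numeric(a), n); E <- rep_len(as.numeric(E), n)
  if (any(E <= 0)) stop("compute_ebgm requires E > 0 for every table")
  s1 <- prior$alpha1 + a; r1 <- prior$beta1 + E
  s2 <- prior$alpha2 + a; r2 <- prior$beta2 + E
  if (prior$w >= 1) {
    Q <- rep(1, n)
  } else if (prior$w <= 0) {
    Q <- rep(0, n)
  } else {
    m1 <- nb_marginal(a, prior$alpha1, prior$beta1, E)
    m2 <- nb_marginal(a, prior$alpha2, prior$beta2, E)
    Q <- prior$w * m1 / (prior$w * m1 + (1 - prior$w) * m2)
  }
  elog <- Q * (digamma(s1) - log(r1)) + (1 - Q) * (digamma(s2) - log(r2))
  ebgm <- exp(elog)

  # posterior 5th percentile by vectorized bisection on the mixture CDF
  mix_cdf <- function(x) Q * stats::pgamma(x, s1, rate = r1) +
    (1 - Q) * stats::pgamma(x, s2, rate = r2)
  lo <- rep(0, n)
  hi <- pmax(stats::qgamma(0.9999, s1, rate = r1),
             stats::qgamma(0.9999, s2, rate = r2)) + 1
  for (iter in 1:200) {
    mid <- (lo + hi) / 2
    below <- mix_cdf(mid) < 0.05
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
    if (max((hi - lo) / pmax(mid, 1e-12)) < 1e-8) break
  }
  eb05 <- (lo + hi) / 2
  if (any(!is.finite(eb05)))
    stop("EB05 bisection failed for table(s) ",
         paste(which(!is.finite(eb05)), collapse = ", "))
  data.frame(ebgm = ebgm, eb05 = eb05)
}

#' Fit the MGPS two-gamma mixture prior by marginal maximum likelihood
#'
#' Maximizes the summed log negative-binomial mixture marginal
#' likelihood of the observed counts over `(alpha1, beta1, alpha2,
#' beta2, w)` with shapes/rates log-transformed and the weight
#' logit-transformed, using five documented Nelder-Mead starts around
#' the conventional default prior. Falls back to the default prior
#' with a warning if every start fails or the fit is degenerate.
#'
#' @param a vector of observed counts, one per table.
#' @param E vector of expected counts (`> 0`), same length.
#' @param min_tables minimum number of usable tables, default 50.
#' @return a `gps_prior` with attributes `logLik` and `converged`.
#' @export
fit_gps_prior <- function(a, E, min_tables = 50L) {
  keep <- is.finite(a) & is.finite(E) & E > 0
  a <- as.numeric(a[keep]); E <- as.numeric(E[keep])
  if (length(a) < min_tables)
    stop("fewer than ", min_tables, " tables with E > 0; ",
         "use default_gps_prior() instead")
  if (all(a == 0)) {
    warning("all observed counts are zero; returning the default prior")
    p <- default_gps_prior()
    attr(p, "converged") <- FALSE
    return(p)
  }
  negll <- function(theta) {
    al1 <- exp(theta[1]); be1 <- exp(theta[2])
    al2 <- exp(theta[3]); be2 <- exp(theta[4])
    w <- stats::plogis(theta[5])
    lik <- w * nb_marginal(a, al1, be1, E) +
      (1 - w) * nb_marginal(a, al2, be2, E)
    -sum(log(pmax(lik, 1e-300)))
  }
  base <- c(log(0.2), log(0.1), log(2), log(4), stats::qlogis(1 / 3))
  starts <- list(
    base,
    base + c(1, 1, 0, 0, 0),
    base + c(-1, -1, 1, 1, 1),
    c(log(1), log(1), log(1), log(0.5), 0),
    base + c(0.5, -0.5, -0.5, 0.5, -1)
  )
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, negll, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    warning("MGPS prior optimization failed; returning the default prior")
    p <- default_gps_prior()
    attr(p, "converged") <- FALSE
    return(p)
  }
  th <- best$par
  p <- structure(list(w = stats::plogis(th[5]),
                      alpha1 = exp(th[1]), beta1 = exp(th[2]),
                      alpha2 = exp(th[3]), beta2 = exp(th[4])),
                 class = "gps_prior")
  attr(p, "logLik") <- -best$value
  attr(p, "converged") <- TRUE
  p
}

#' Log marginal likelihood of counts under a GPS prior
#'
#' @param prior a `gps_prior`.
#' @param a,E count and expectation vectors.
#' @return summed log mixture marginal likelihood.
#' @export
gps_marginal_loglik <- function(prior, a, E) {
  validate_gps_prior(prior)
  lik <- prior$w * nb_marginal(a, prior$alpha1, prior$beta1, E) +
    (1 - prior$w) * nb_marginal(a, prior$alpha2, prior$beta2, E)
  sum(log(pmax(lik, 1e-300)))
}

#' Combined disproportionality metrics for a set of tables
#'
#' @param tables data.frame from [contingency_tables()].
#' @param prior MGPS prior; `NULL` uses the default.
#' @param strict_ebgm also require `EB05 > 2` in the signal rule.
#' @return `tables` augmented with all metric columns, Fisher/Bonferroni
#'   volcano statistics and `is_signal`.
#' @export
signal_metrics <- function(tables, prior = NULL, strict_ebgm = FALSE) {
  prior <- prior %||% default_gps_prior()
  out <- cbind(tables, compute_ror(tables$a, tables$b, tables$c, tables$d))
  out <- cbind(out, compute_prr_chi2(tables$a, tables$b, tables$c, tables$d))
  out <- cbind(out, compute_ic(tables$a, tables$E))
  eb <- data.frame(ebgm = rep(NA_real_, nrow(tables)),
                   eb05 = rep(NA_real_, nrow(tables)))
  ok <- is.finite(tables$E) & tables$E > 0
  if (any(ok)) eb[ok, ] <- compute_ebgm(tables$a[ok], tables$E[ok], prior)
  out <- cbind(out, eb)
  out <- cbind(out, volcano_stats(tables))
  out$n_reports <- out$a
  out$is_signal <- evaluate_signal(out, strict_ebgm = strict_ebgm)
  out
}

#' Apply the combined signal rule
#'
#' A drug is a signal when all five predefined criteria hold: lower
#' 95% bound of ROR > 1, PRR >= 2, chi-square >= 4, lower 95% credible
#' bound of IC > 0, and at least 3 target-event reports with the drug
#' as primary suspect. With `strict_ebgm = TRUE`, `EB05 > 2` is
#' additionally required. Missing metrics fail the rule.
#'
#' @param metrics data.frame with columns `a` (or `n_reports`),
#'   `ror_lo, prr, chi2, ic_lo` and (strict mode) `eb05`.
#' @param strict_ebgm require `EB05 > 2` as well.
#' @return logical vector.
#' @export
evaluate_signal <- function(metrics, strict_ebgm = FALSE) {
  a <- metrics$a %||% metrics$n_reports
  crit <- !is.na(a) & a >= 3 &
    !is.na(metrics$ror_lo) & metrics$ror_lo > 1 &
    !is.na(metrics$prr) & metrics$prr >= 2 &
    !is.na(metrics$chi2) & metrics$chi2 >= 4 &
    !is.na(metrics$ic_lo) & metrics$ic_lo > 0
  if (strict_ebgm)
    crit <- crit & !is.na(metrics$eb05) & metrics$eb05 > 2
  crit
}

#' Volcano-plot statistics: Fisher exact p with Bonferroni correction
#'
#' Two-sided Fisher exact p-value per table (sum of hypergeometric
#' probabilities no larger than that of the observed cell), Bonferroni
#' adjusted across the evaluable drugs, and the natural log of the
#' (possibly Haldane-Anscombe corrected) ROR.
#'
#' @param tables data.frame with cells `a, b, c, d` and an `evaluable`
#'   column (defaults to `a + b > 0` when absent).
#' @return data.frame with `fisher_p, p_adj, log_ror`.
#' @export
volcano_stats <- function(tables) {
  n <- nrow(tables)
  evaluable <- tables$evaluable %||% (tables$a + tables$b > 0)
  fisher_p <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!evaluable[i]) next
    m <- matrix(c(tables$a[i], tables$b[i], tables$c[i], tables$d[i]),
                nrow = 2, byrow = TRUE)
    fisher_p[i] <- stats::fisher.test(m)$p.value
  }
  m_tests <- sum(evaluable)
  p_adj <- pmin(1, m_tests * fisher_p)
  cor_ror <- compute_ror(tables$a, tables$b, tables$c, tables$d)
  data.frame(fisher_p = fisher_p, p_adj = p_adj,
             log_ror = log(cor_ror$ror))
}
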