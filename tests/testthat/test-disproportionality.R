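# 2x2 table construction and the four disproportionality algorithms,
# their hand-computable oracle values, invariances, and the combined
# signal rule.

test_that("contingency tables count primary-suspect reports once each", {
  bg <- fixture_background_8()
  sel <- select_cohort(bg)
  tab <- build_contingency(sel$cohort, sel$background, "tramadol",
                           synonyms = fixture_synonyms)
  expect_equal(unlist(tab[, c("a", "b", "c", "d")], use.names = FALSE),
               c(2L, 1L, 2L, 3L))
  expect_equal(tab$N, 8L)
  expect_true(tab$evaluable)

  # a report mentioning the drug twice counts once
  bg2 <- bg
  bg2$drugs <- rbind(bg2$drugs,
                     data.frame(report_id = "1", drug_seq = 2L, role = "PS",
                                raw_name = "ULTRAM",
                                start_date = as.Date(NA)))
  sel2 <- select_cohort(bg2)
  tab2 <- build_contingency(sel2$cohort, sel2$background, "tramadol",
                            synonyms = fixture_synonyms)
  expect_equal(tab2$a, 2L)

  # absent drug: non-evaluable zero-margin table
  tab0 <- build_contingency(sel$cohort, sel$background, "linezolid",
                            synonyms = fixture_synonyms)
  expect_equal(c(tab0$a, tab0$b), c(0L, 0L))
  expect_false(tab0$evaluable)

  # concomitant (non-PS) mentions never enter the table
  bg3 <- bg
  bg3$drugs$role <- "C"
  sel3 <- select_cohort(bg3)
  tab3 <- build_contingency(sel3$cohort, sel3$background, "tramadol",
                            synonyms = fixture_synonyms)
  expect_equal(c(tab3$a, tab3$b), c(0L, 0L))
})

test_that("ROR and Woolf interval match hand arithmetic", {
  r <- compute_ror(5, 50, 10, 100)
  expect_equal(r$ror, 1.0)
  r2 <- compute_ror(8, 92, 192, 9708)
  expect_lt(abs(r2$ror - 4.3967), 1e-3)
  expect_lt(abs(r2$ror_lo - 2.105), 1e-3)
  expect_equal(compute_ror(10, 90, 100, 9900)$ror, 11.0)

  # antisymmetry: swapping rows gives the reciprocal
  set.seed(7)
  for (i in 1:20) {
    cells <- rpois(4, 20) + 1
    fwd <- compute_ror(cells[1], cells[2], cells[3], cells[4])
    rev <- compute_ror(cells[2], cells[1], cells[4], cells[3])
    expect_equal(fwd$ror, 1 / rev$ror, tolerance = 1e-12)
    expect_equal(fwd$ror_lo, 1 / rev$ror_hi, tolerance = 1e-12)
  }

  # zero cell: Haldane-Anscombe correction applied and flagged
  z <- compute_ror(3, 0, 10, 100)
  expect_true(z$corrected)
  expect_equal(z$ror, (3.5 * 100.5) / (0.5 * 10.5))
  # a = 0 can never signal: metrics missing
  expect_true(is.na(compute_ror(0, 10, 10, 100)$ror))
})

test_that("PRR and Pearson chi-square match hand arithmetic", {
  p <- compute_prr_chi2(8, 92, 192, 9708)
  expect_lt(abs(p$prr - 4.125), 1e-3)
  expect_lt(abs(p$chi2 - 18.553), 1e-3)
  p2 <- compute_prr_chi2(5, 5, 5, 85)
  expect_equal(p2$prr, 9.0)
  expect_lt(abs(p2$chi2 - 19.753), 1e-3)
  p3 <- compute_prr_chi2(5, 50, 10, 100)
  expect_equal(p3$prr, 1.0)
  expect_equal(p3$chi2, 0)

  # chi-square is invariant under transposing the 2x2 table
  set.seed(11)
  for (i in 1:20) {
    cells <- rpois(4, 15) + 1
    expect_equal(compute_prr_chi2(cells[1], cells[2], cells[3],
                                  cells[4])$chi2,
                 compute_prr_chi2(cells[1], cells[3], cells[2],
                                  cells[4])$chi2,
                 tolerance = 1e-12)
  }
})

test_that("information component matches its closed form and limits", {
  # E = a gives IC = 0 exactly
  expect_equal(compute_ic(4, 4)$ic, 0)
  i2 <- compute_ic(8, 2)
  expect_lt(abs(i2$ic - 1.7655), 1e-3)
  expect_lt(abs(i2$ic_lo - 0.5529), 1e-3)
  expect_equal(compute_ic(0, 1)$ic, log2(0.5 / 1.5))

  # strictly increasing in a at fixed E
  ic_seq <- compute_ic(0:50, 5)$ic
  expect_true(all(diff(ic_seq) > 0))

  # IC -> log2(RR) as counts grow at fixed RR
  rr <- 3
  big <- compute_ic(3 * 10^(1:5), 10^(1:5))
  errs <- abs(big$ic - log2(rr))
  expect_lt(errs[5], 1e-4)
  expect_true(all(diff(errs) < 0))
})

test_that("EBGM matches the single-component closed form and a quadrature oracle", {
  # degenerate prior w = 1, gamma(2, 4), a = 6, E = 2: posterior gamma(8, 6)
  prior1 <- structure(list(w = 1, alpha1 = 2, beta1 = 4,
                           alpha2 = 1, beta2 = 1), class = "gps_prior")
  eb <- compute_ebgm(6, 2, prior1)
  expect_equal(eb$ebgm, exp(digamma(8) - log(6)), tolerance = 1e-10)
  expect_lt(abs(eb$ebgm - 1.2509), 1e-3)
  # geometric mean below the arithmetic posterior mean 8/6
  expect_lt(eb$ebgm, 8 / 6)
  # EB05 agrees with the gamma quantile to the bisection tolerance
  expect_equal(eb$eb05, qgamma(0.05, 8, rate = 6), tolerance = 1e-6)

  # default two-component prior, a = 5, E = 1: brute-force quadrature
  # oracle over the unnormalized posterior mixture density
  prior <- default_gps_prior()
  grid <- seq(1e-9, 60, length.out = 1e6)
  dens <- (prior$w * dgamma(grid, prior$alpha1, rate = prior$beta1) +
             (1 - prior$w) * dgamma(grid, prior$alpha2, rate = prior$beta2)) *
    dpois(5, grid * 1)
  w <- diff(grid)[1]
  dens <- dens / sum(dens * w)
  oracle_ebgm <- exp(sum(log(grid) * dens * w))
  oracle_cdf <- cumsum(dens * w)
  oracle_eb05 <- grid[which.max(oracle_cdf >= 0.05)]
  eb2 <- compute_ebgm(5, 1, prior)
  expect_lt(abs(eb2$ebgm - oracle_ebgm), 1e-4)
  expect_lt(abs(eb2$eb05 - oracle_eb05), 1e-3)
})

test_that("EBGM shrinks the observed rate ratio toward the prior", {
  set.seed(23)
  prior <- default_gps_prior()
  for (i in 1:50) {
    E <- runif(1, 1, 10)
    rr <- runif(1, 3, 20)
    a <- round(rr * E)
    res <- compute_ebgm(a, E, prior)
    rr_obs <- a / E
    expect_gt(res$ebgm, 1)
    expect_lt(res$ebgm, rr_obs)
    # geometric mean never exceeds the posterior arithmetic mean
    m1 <- dnbinom(a, size = prior$alpha1,
                  prob = prior$beta1 / (prior$beta1 + E))
    m2 <- dnbinom(a, size = prior$alpha2,
                  prob = prior$beta2 / (prior$beta2 + E))
    Q <- prior$w * m1 / (prior$w * m1 + (1 - prior$w) * m2)
    post_mean <- Q * (prior$alpha1 + a) / (prior$beta1 + E) +
      (1 - Q) * (prior$alpha2 + a) / (prior$beta2 + E)
    expect_lte(res$ebgm, post_mean)
    expect_lte(res$eb05, res$ebgm)
  }
})

test_that("the MGPS prior is recoverable from data it generated", {
  set.seed(31)
  prior <- default_gps_prior()
  sim <- function(n) {
    E <- exp(runif(n, log(0.5), log(20)))
    comp <- runif(n) < prior$w
    lam <- ifelse(comp, rgamma(n, prior$alpha1, rate = prior$beta1),
                  rgamma(n, prior$alpha2, rate = prior$beta2))
    list(a = rpois(n, lam * E), E = E)
  }
  train <- sim(5000)
  heldout <- sim(5000)
  fit <- fit_gps_prior(train$a, train$E)
  ll_fit <- gps_marginal_loglik(fit, heldout$a, heldout$E) / 5000
  ll_gen <- gps_marginal_loglik(prior, heldout$a, heldout$E) / 5000
  expect_lt(abs(ll_fit - ll_gen), 0.01 * abs(ll_gen))

  # degenerate all-zero counts fall back to the default prior
  expect_warning(p0 <- fit_gps_prior(rep(0, 100), rep(1, 100)), "default")
  expect_equal(p0$alpha1, default_gps_prior()$alpha1)

  # too few tables is an error
  expect_error(fit_gps_prior(1:10, rep(1, 10)), "50")
})

test_that("near single-component data concentrates the fitted mixture", {
  set.seed(37)
  n <- 2000
  E <- exp(runif(n, log(0.5), log(10)))
  lam <- rgamma(n, 2, rate = 4)   # only the second default component
  a <- rpois(n, lam * E)
  fit <- fit_gps_prior(a, E)
  # effectively one component: the fit may hang a sliver of weight on
  # a near-zero spike that absorbs excess zeros, so require dominant
  # weight and that the dominant component sits near the truth
  w_dom <- max(fit$w, 1 - fit$w)
  expect_gte(w_dom, 0.95)
  dom <- if (fit$w >= 0.5) c(fit$alpha1, fit$beta1)
  else c(fit$alpha2, fit$beta2)
  expect_lt(abs(log(dom[1] / 2)), log(1.5))
  expect_lt(abs(log(dom[2] / 4)), log(1.5))
})

test_that("the five-criterion signal rule behaves as specified", {
  m <- signal_metrics(finish_tables_for_test(8, 92, 192, 9708))
  expect_true(m$is_signal)
  expect_gt(m$ror_lo, 1); expect_gte(m$prr, 2)
  expect_gte(m$chi2, 4); expect_gt(m$ic_lo, 0); expect_gte(m$a, 3)

  # a < 3 vetoes regardless of the other metrics
  strong <- data.frame(a = 2, ror_lo = 50, prr = 50, chi2 = 100, ic_lo = 3)
  expect_false(evaluate_signal(strong))
  # property: any metrics row with a < 3 is refused
  set.seed(41)
  rnd <- data.frame(a = sample(0:2, 50, TRUE),
                    ror_lo = runif(50, 0, 60), prr = runif(50, 0, 60),
                    chi2 = runif(50, 0, 200), ic_lo = runif(50, -2, 5))
  expect_false(any(evaluate_signal(rnd)))

  # independence never signals
  m0 <- signal_metrics(finish_tables_for_test(5, 50, 10, 100))
  expect_false(m0$is_signal)
  expect_equal(m0$prr, 1)

  # strict mode additionally requires EB05 > 2
  met <- data.frame(a = 10, ror_lo = 3, prr = 5, chi2 = 40, ic_lo = 1,
                    eb05 = 1.5)
  expect_true(evaluate_signal(met))
  expect_false(evaluate_signal(met, strict_ebgm = TRUE))
  met$eb05 <- 2.5
  expect_true(evaluate_signal(met, strict_ebgm = TRUE))
})

test_that("null tables rarely clear the ROR lower bound", {
  # Poisson sampling under a true rate ratio of 1
  set.seed(43)
  n <- 10000
  a <- rpois(n, 2)
  b <- rpois(n, 98)
  c <- rpois(n, 198)
  d <- rpois(n, 9702)
  r <- compute_ror(a, b, c, d)
  frac <- mean(r$ror_lo > 1, na.rm = TRUE)
  expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / n))
})

test_that("volcano statistics follow the Fisher/Bonferroni recipe", {
  # (1,9,9,81): the observed cell is the hypergeometric mode, p = 1.
  # Independent oracle: exhaustive enumeration of the hypergeometric.
  probs <- dhyper(0:10, 10, 90, 10)
  p_oracle <- sum(probs[probs <= probs[2] + 1e-12])
  tab <- finish_tables_for_test(1, 9, 9, 81)
  v <- volcano_stats(tab)
  expect_equal(v$fisher_p, 1.0, tolerance = 1e-12)
  expect_equal(v$fisher_p, p_oracle, tolerance = 1e-9)

  # Fisher p on a sharper table agrees with the enumeration oracle
  tab2 <- finish_tables_for_test(8, 92, 192, 9708)
  probs2 <- dhyper(0:100, 100, 9900, 200)
  p2_oracle <- sum(probs2[probs2 <= probs2[9] + 1e-12])
  expect_equal(volcano_stats(tab2)$fisher_p, p2_oracle, tolerance = 1e-9)

  # Bonferroni with m = number of evaluable drugs, capped at 1
  many <- do.call(rbind, replicate(236, tab2, simplify = FALSE))
  v2 <- volcano_stats(many)
  expect_equal(v2$p_adj, pmin(1, 236 * v2$fisher_p))
  expect_equal(v2$log_ror[1], log(8 * 9708 / (92 * 192)))
})
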