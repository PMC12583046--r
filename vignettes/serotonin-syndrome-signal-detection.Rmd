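---
title: "Methods: disproportionality signal detection for serotonin syndrome in elderly spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality signal detection for serotonin syndrome in elderly spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssfaers)
```

## The problem and the data model

Spontaneous adverse-event databases contain reports, not incidence
data: there is no denominator of exposed patients, reporting is
voluntary and biased, and the same clinical case can appear several
times as updated versions. Disproportionality analysis sidesteps the
missing denominator by asking whether a drug–event pair is reported
*more often than expected given the rest of the database*. `ssfaers`
applies this machinery to one question: which drugs, taken as primary
suspect, are disproportionately reported with the MedDRA preferred
term "Serotonin syndrome" in patients aged 65 years and over.

The ingestion layer models the FAERS quarterly ASCII dialect: one
`$`-delimited file per table (DEMO, DRUG, REAC, OUTC, THER; RPSR and
INDI are read when present but unused), first line a header, dates as
`YYYYMMDD` integers that may be truncated to month or year. Rows with
the wrong field count are skipped and counted; a table with more than
1% such rows is treated as corrupt and refused, on the view that
silent large-scale row loss is worse than a hard stop.

### Deduplication and cohort selection

Cases are deduplicated by `caseid`: the retained version is the one
with the **latest receipt date**, ties broken by the **largest numeric
report id**. This is the convention FAERS itself documents for
identifying the current version of a case; the operation is idempotent
and all child tables (drugs, reactions, outcomes, therapy dates) join
to the retained version only. A truncated receipt date falls back to
the end of its quarter — receipt dates only order versions, so a
quarter-resolution bound is sufficient — whereas truncated event or
therapy dates are treated as missing, because onset intervals computed
from them would be spurious.

Ages are converted to years from the FAERS unit codes (YR, DEC, MON,
WK, DY, HR). A value with a missing or unknown unit is taken as years,
the dominant unit in practice; negative ages and ages above 125 years
are rejected as data errors. The elderly background is every
deduplicated report with age ≥ 65 (inclusive), and the cohort is the
subset whose reactions contain the target preferred term, matched by
case-insensitive exact string equality after trimming. No MedDRA
hierarchy traversal is attempted: the analysis is defined at a single
preferred term, and term expansion would require licensed dictionary
content.

The comparison population for disproportionality defaults to the
**elderly-only background** rather than all ages, because the study
frame is elderly patients: the question is "which drugs stand out
among elderly reports", not "does elderly reporting differ from
younger reporting". `run_pipeline(background_scope = "all")` exposes
the alternative.

### Drug normalization

Raw drug strings mix trade names, salts and spelling variants.
Normalization canonicalizes (uppercase, trim, collapse whitespace and
punctuation runs), strips trailing salt/dosage tokens from a fixed
list (HCL, HYDROCHLORIDE, SULFATE, TARTRATE, MALEATE, SUCCINATE), then
performs an exact lookup in a two-column synonym table. The fixed
suffix list is deliberate: a greedy regex would silently mangle names,
and an auditable mapping matters more than a marginally higher hit
rate. Multi-ingredient strings (containing `/` or `+`) are only mapped
on an exact entry because a combination product is ambiguous with
respect to the suspect ingredient. Unmapped names pass through
flagged, never dropped. Generic names then map to a single ATC
first-level letter (N = nervous system, J = antiinfectives for
systemic use, ...), with misses reported as `"unclassified"`.

## The four disproportionality statistics

All four operate on the per-drug 2×2 table: `a` reports with the drug
as primary suspect and the target event, `b` drug without event, `c`
event without drug, `d` neither; `N = a+b+c+d`,
`E = (a+b)(a+c)/N`, observed rate ratio `RR = a/E`. A report
mentioning the drug several times counts once; non-primary-suspect
roles (SS, C, I) never enter the table, matching the primary-suspect
framing of the cohort.

* **ROR** `= ad/bc` with the Woolf (log-normal) 95% interval. When any
  cell is zero the Haldane–Anscombe correction adds 0.5 to all four
  cells and flags the row. Tables with `a = 0` return missing metrics:
  they can never satisfy the case-count criterion anyway.
* **PRR** `= [a/(a+b)]/[c/(c+d)]` with Pearson's χ² on the 2×2 table.
  No Yates correction is applied: the continuity-corrected variant is
  the more conservative of the two conventions in circulation and the
  signal rule already demands χ² ≥ 4 alongside four other criteria;
  the choice is documented here precisely because the two variants
  disagree near the threshold.
* **IC** `= log2((a+0.5)/(E+0.5))` with the lower 95% credible bound
  `IC − 3.3(a+0.5)^{−1/2} − 2(a+0.5)^{−3/2}`, the standard
  gamma-approximation form of the BCPNN information component. The
  +0.5 offsets shrink small-count cells toward independence.
* **EBGM** (gamma-Poisson shrinker). The prior on the rate ratio λ is
  a two-component gamma mixture; given `(a, E)` the posterior is again
  a two-gamma mixture with components gamma(αᵢ + a, βᵢ + E) and
  posterior weight proportional to the prior weight times the
  negative-binomial marginal of `a`. `EBGM = exp(E[ln λ])` uses the
  digamma closed form per component; `EB05` is found by bisection on
  the mixture CDF to relative tolerance 1e−8 (a monotone CDF makes
  bisection the reliable choice; failures are errors, never silent).

The conventional starting prior is gamma(0.2, 0.1) and gamma(2, 4)
with weight 1/3 on the first component. `fit_gps_prior()` fits the
prior to the run's tables by marginal maximum likelihood: shapes and
rates are log-transformed, the weight logit-transformed, and
Nelder-Mead is run from five fixed documented starts, keeping the best
optimum. Mixture likelihoods are multimodal and can legitimately
collapse toward near-point-mass components when the empirical rate
ratios cluster; the fit falls back to the default prior, with a
warning, when optimization fails or every count is zero, and refuses
to fit on fewer than 50 tables.

### The signal rule

A drug is a signal when **all five** predefined criteria hold:
ROR025 > 1, PRR ≥ 2, χ² ≥ 4, IC025 > 0, and a ≥ 3. Missing metrics
fail the rule. Note the rule itself involves no EBGM threshold even
though four algorithms are computed; `strict_ebgm = TRUE` additionally
requires EB05 > 2 for users who want the shrinker to gate the verdict
rather than only rank it.

### Volcano statistics

Per drug, a two-sided Fisher exact p-value (sum of hypergeometric
probabilities no larger than the observed cell's — stated explicitly
because two-sided Fisher conventions differ) is Bonferroni-adjusted
with m = the number of *evaluable* drugs in the run, not the number of
signals: the correction is for the family of comparisons actually
made. The volcano table pairs `ln ROR` with `−log10` of the adjusted
p.

## Time-to-onset

Onset is `EVENT_DT − START_DT` in whole days, using the **earliest**
full therapy start date of the primary-suspect drug (onset is measured
from first exposure). Same-day onset is recorded as **0.5 days**: a
positive value is needed for log-scale displays and lets clusters of
day-0 events produce medians of exactly 0.5 days rather than
degenerate zeros; the value is configurable. Negative intervals and
missing or partial dates are excluded with reason codes that surface
in the run manifest.

Summaries use quartiles with the linear-interpolation convention on
`p(n−1)` positions (`quantile` type 7, R's default) — a convention
choice that must be fixed for fixtures to be exact — and groups with
fewer than two valid intervals are dropped. Group comparisons use a
midrank Mann-Whitney U (exact enumeration over all assignments when
the pooled sample is ≤ 10, valid under ties; otherwise the normal
approximation with tie-corrected variance and 0.5 continuity
correction) and tie-corrected Kruskal-Wallis across ≥ 3 groups with
Benjamini-Hochberg-adjusted pairwise Mann-Whitney tests. The exact and
approximate Mann-Whitney p-values agree to about 0.04 in the worst
(most unbalanced) splits of a pooled sample of 10, and much closer
near balance — the approximation's known small-sample coarseness,
which is why the exact path is the default there.

## The synthetic generator: what it does and does not emulate

`synthetic_config()` defines the study conditions used throughout the
package's validation. Each report draws one primary-suspect drug from
a 50-drug roster spanning the ATC classes that dominate serotonergic
reporting; the target term is assigned with probability
`min(1, base_rate × λ_drug)` with a base rate of 0.05, and five drugs
(fluoxetine, tramadol, linezolid, ondansetron, cyclobenzaprine — one
per major class) are planted at λ = 10. Onset days are log-normal with
class medians of 16.5 (N), 1.5 (J, A), 2.5 (M), 0.5 (D, V) and 5 days
for the small remaining classes — long-tailed for nervous-system
drugs (σ_log = 1.6), tight for the sub-day classes. Demographic
mixtures (61.5% female; 60.7/29.3/8.6/1.4% across the elderly bands;
84.2% healthcare reporters; 46.4% hospitalized; US-led country
weights) mirror published elderly serotonin-syndrome cohort
proportions so descriptive output looks right at a glance. 25% of
reports are under 65 to exercise the age filter; 10% of cases are
emitted twice with a later receipt date to exercise deduplication;
trade names replace generics 30% of the time and salt suffixes are
appended 5% of the time to exercise normalization; event/start dates
are missing at 30%/15% and truncated at 5%.

All randomness flows from one seed (quarter *i* uses stream seed
`seed + i − 1`), so a fixed configuration is byte-reproducible.

What the generator does **not** emulate — and therefore what passing
tests do *not* show about real data: FAERS-scale cardinality (millions
of reports, thousands of drugs), real co-reporting correlation
(concomitants here are drawn independently), reporting-rate secular
trends, country- or reporter-specific coding habits, true duplicate
records with *conflicting* field values, and free-text name noise
beyond trade/salt variants. Recovery of planted signals demonstrates
that the pipeline is correct, not that FAERS signals are causal.

## Validation design and problem sizes

The package's validation suite runs at sizes chosen to make each check
informative yet quick to rerun routinely:

* hand-computable 2×2 oracles (e.g. (8, 92, 192, 9708)) checked to
  1e−3, the EBGM path against a 10⁶-node quadrature of the posterior
  mixture to 1e−4 and against the single-component digamma closed
  form to 1e−10;
* prior-fit recovery on 5,000 simulated pairs scored by held-out
  marginal likelihood within 1% of the generating prior;
* null calibration on a 10,000-report unelevated dataset (flagged
  fraction bounded by 5% plus 3 Monte-Carlo σ) and a 10,000-replicate
  check that the Woolf lower bound exceeds 1 in ≤ 5% of null tables;
* planted-recovery across 100 seeded 2,000-report studies (the signal
  set must equal the planted set in ≥ 95 runs) and Woolf coverage over
  1,000 tables at a planted odds ratio of 2.5 (93–97% band);
* exhaustive Mann-Whitney exact-vs-approximate comparison over all
  splits of a 10-value fixture, and 100 seeded onset-ordering
  recoveries.

`scripts/acceptance.R` replays the full pipeline on a seeded 8,000
report study and reports only quantities it computes at run time.

## Known limitations

* Signal detection here is hypothesis generation: disproportionality
  cannot establish causality, and the elderly-only background bakes in
  a specific comparison frame.
* The IC credible bound uses the standard closed-form approximation,
  not the original neural-network formulation; stratified (age/sex)
  shrinkage is not implemented.
* Which χ² variant, IC variant and prior-fitting policy other
  published analyses used is often unstated; the defaults here are the
  standard published set, and the alternatives that matter
  (strict EBGM gating, all-ages background, same-day onset value,
  quantile convention) are configuration flags rather than forks.
* PT matching is exact; misspelled or differently-coded reaction terms
  are invisible to the cohort selector.
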