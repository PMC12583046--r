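# ssfaers

Pharmacovigilance signal detection for **drug-associated serotonin
syndrome in elderly patients**, built on FAERS-style spontaneous
adverse-event reports.

Serotonin syndrome is a toxic state caused by excess serotonergic
activity — altered mental status, autonomic hyperactivity and
neuromuscular dysfunction — and is disproportionately dangerous in
older patients exposed to polypharmacy. Spontaneous-report databases
such as the FDA Adverse Event Reporting System (FAERS) let us ask
which drugs are reported with this event *more often than expected*.
`ssfaers` implements that analysis end to end for anyone working with
FAERS-dialect quarterly ASCII extracts: epidemiologists and clinical
pharmacists running disproportionality studies, and methodologists who
need a fully synthetic, ground-truthed testbed for such pipelines.

## What it computes

For each drug *D* taken as primary suspect, reports aged 65+ are
cross-classified against the MedDRA preferred term "Serotonin
syndrome" into the 2×2 table (a, b, c, d) with N = a+b+c+d and
expected count E = (a+b)(a+c)/N. Four standard disproportionality
statistics are computed:

- **ROR** = ad/bc, with Woolf 95% interval
  exp(ln ROR ∓ 1.96·√(1/a+1/b+1/c+1/d)) (Haldane–Anscombe +0.5 on zero
  cells);
- **PRR** = [a/(a+b)] / [c/(c+d)] with Pearson χ² (no Yates
  correction);
- **BCPNN IC** = log₂((a+0.5)/(E+0.5)), lower credible bound
  IC − 3.3(a+0.5)^−½ − 2(a+0.5)^−3/2;
- **MGPS EBGM** = 2^E[log₂ λ] under a two-component gamma-mixture
  posterior for the reporting-rate ratio λ, with EB05 its posterior
  5th percentile; the mixture prior can be fitted to the data by
  marginal maximum likelihood.

A drug is a **signal** when all five predefined criteria hold:
ROR025 > 1, PRR ≥ 2, χ² ≥ 4, IC025 > 0, and a ≥ 3. Around this core
the package provides case deduplication (latest receipt date per case,
ties to the largest report id), trade-name → generic normalization
with ATC first-level classes, Fisher/Bonferroni volcano statistics, a
healthcare-professional-only sensitivity rerun, time-to-onset
quartiles/ECDFs with Mann-Whitney and Kruskal-Wallis (BH-adjusted)
comparisons, and Table-1 style descriptive summaries.

A bundled synthetic generator emits FAERS-dialect files with planted
per-drug rate elevations, class-specific onset distributions,
duplicate case versions and name variants, so the entire pipeline is
testable with known truth and no external database.

## Worked example

```r
library(ssfaers)

cfg <- synthetic_config(n_reports = 1500, quarters = c("2024Q1", "2024Q2"),
                        seed = 42)
gen <- generate_reports(cfg)                    # planted truth included
write_faers_ascii(gen$quarters, "faers-synth")

res <- run_pipeline("faers-synth", out_dir = "results")
subset(res$signals, is_signal,
       select = c(drug, atc_class, a, ror, ror_lo, prr, chi2, ic_lo))
```

```
            drug atc_class  a   ror ror_lo  prr   chi2 ic_lo
        tramadol         N 31 14.57   8.32 6.78 144.53  1.86
     ondansetron         A 22  9.06   5.01 5.29  75.90  1.44
       linezolid         J 20 11.36   5.91 5.91  81.77  1.55
      fluoxetine         N 19  9.65   5.06 5.44  69.36  1.42
 cyclobenzaprine         M 13  5.82   2.89 4.03  30.76  0.86
```

The run read 3,290 raw report versions, deduplicated them to 3,000
cases, kept 2,204 elderly reports as the background and 213 as the
serotonin-syndrome cohort. The five flagged drugs are exactly the five
the generator planted at a rate ratio of 10 (`gen$truth`); every one
clears all five signal thresholds, e.g. tramadol with 31 cohort
reports and ROR 14.6 (95% lower bound 8.3). Onset summaries recover
the planted class difference — nervous-system drugs onset late (median
14 days here, planted 16.5) while antiinfectives onset within a day or
two:

```r
subset(res$tto_summary, stratum == "atc_class")
#>    stratum group  n    q1 median     q3
#>  atc_class     A 26 0.500   1.00  2.000
#>  atc_class     J 16 1.000   1.00  6.000
#>  atc_class     N 54 4.000  14.00 27.750
#>  ...
```

`run_pipeline()` also writes `signals.csv`,
`signals_professional.csv` (the sensitivity rerun restricted to
healthcare-professional reporters), `volcano.csv`, `table1.csv`,
`tto_summary.csv`, `tto_tests.csv`, `ecdf.csv` and a `manifest.json`
with stage-by-stage counts.

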