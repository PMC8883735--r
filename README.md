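# codeshift

Stability analysis for chronic-disease surveillance trends derived from
coded administrative health claims.

## The problem

Population-level disease surveillance often counts cases by applying a
*case-definition algorithm* — e.g. "1 or more hospital separations or 2 or
more physician visits with a diabetes diagnosis code within 2 years" — to
administrative claims. Over decades, the coding of those claims changes:
ICD versions switch (ICDA-8 → ICD-9-CM → ICD-10-CA), coding precision
changes, practice patterns drift. A kink in an incidence or prevalence
trend can therefore be a coding artifact rather than a change in population
health. This package implements, for juvenile (age 0–17) diabetes
surveillance, a pipeline that makes such artifacts visible and lets you ask
whether some algorithms are more robust to them than others.

## What it does

For each of 18 validated claims-based juvenile diabetes algorithms
(`juvenile_diabetes_algorithms()`), over a 1975–2016 study span:

1. **Ascertain** incident and prevalent cases from a person registry plus
   coded claims (rolling observation windows, a 30-day visit-spacing rule
   for physician-only definitions, a 3-year diagnosis-free lookback for
   incidence), aggregated by year × age group (0–9, 10–17) × sex, with
   privacy suppression of small cells (1–5) handled by seeded uniform
   imputation or exclusion (> 10% suppressed).
2. **Model** the trend: negative binomial regression for incidence
   (independent years), Poisson estimating equations with AR(1) working
   correlation within age-sex series for prevalence; year enters either
   linearly or as a restricted cubic spline (3–5 knots at Harrell's
   quantiles), selected by AIC/QIC plus a likelihood-ratio or robust Wald
   test against the linear model; log cohort size is the offset.
3. **Chart**: observed yearly totals against model-expected totals with
   control limits at `expected ± k · pooled SD` (pooled over strata as the
   SD of a sum of independent cells), `k = 0.8` by default and `k = 2` as a
   relaxed sensitivity setting; years strictly outside the limits are
   out-of-control (OOC).
4. **Compare**: OOC proportions per algorithm; McNemar tests (exact, with
   fewer than 10 discordant years, else continuity-corrected) of each
   algorithm against the reference `"2: 1 + H or 1 + P"`, Holm-Bonferroni
   adjusted within period families (all years, three ICD periods, two
   ICD-implementation periods); agreement-by-year across algorithms;
   crude-rate period summaries.

Real provincial claims are access-restricted, so the package includes a
first-class synthetic-data generator (`sim_config()`, `simulate_study()`)
with known ground truth: era-specific ICD coding by care setting,
configurable care-seeking and coding-sensitivity parameters, background
(non-disease) claims, and injectable coding-disruption events at chosen
years. See the vignette (`vignettes/surveillance-stability.Rmd`) for the
model details, generator assumptions, and design choices.

## Worked example

```r
library(codeshift)

cfg <- study_config(
  sim = sim_config(seed = 42),          # 60,000 persons, 1965-2016
  algorithms = c("1: 1 + P", "2: 1 + H or 1 + P", "2: 1 + P", "2: 2 + P"),
  reference = "2: 1 + H or 1 + P",
  seed = 42
)
res <- run_study(cfg)
res
#> <study_result> 4 algorithms; 8 modelled algorithm-outcomes; 0 excluded

res$charts[["2: 1 + H or 1 + P | incidence | 0.8"]]
#> <control_chart> incidence for 2: 1 + H or 1 + P - k = 0.8 ; 18 of 42 years out-of-control
head(as.data.frame(res$charts[["2: 1 + H or 1 + P | incidence | 0.8"]]), 4)
#>   year observed expected sd_pooled    lower    upper   ooc
#> 1 1975       25 29.78988  5.458010 25.42347 34.15629  TRUE
#> 2 1976       32 30.60083  5.531802 26.17539 35.02627 FALSE
#> 3 1977       31 31.34783  5.598913 26.86870 35.82696 FALSE
#> 4 1978       40 32.20336  5.674801 27.66352 36.74320  TRUE
```

18 of 42 years fall outside the tight ±0.8·SD limits for the reference
algorithm — by construction these limits flag roughly the largest 40% of
deviations even for a well-specified model, so the interesting question is
comparative, not absolute:

```r
res$stability[["incidence | k=0.8"]]$ooc_proportions
#>                           algorithm ooc_count ooc_proportion
#> 1: 1 + P                   1: 1 + P        15      0.3571429
#> 2: 1 + H or 1 + P 2: 1 + H or 1 + P        18      0.4285714
#> 2: 1 + P                   2: 1 + P        16      0.3809524
#> 2: 2 + P                   2: 2 + P        19      0.4523810

subset(res$stability[["incidence | k=0.8"]]$comparisons, family == "All years")
#>      family algorithm b c method statistic p_value identical p_adjusted
#> 1 All years  1: 1 + P 4 1  exact        NA   0.375     FALSE          1
#> 2 All years  2: 1 + P 2 0  exact        NA   0.500     FALSE          1
#> 3 All years  2: 2 + P 3 4  exact        NA   1.000     FALSE          1
```

No algorithm differs significantly from the reference in OOC frequency
(all Holm-adjusted p = 1) — under stable coding, trend stability is
comparable across algorithms. Crude rates land in the range typical of
claims-based juvenile diabetes ascertainment:

```r
rate_summary(res$counts[["2: 1 + H or 1 + P | incidence"]])$periods
#>                 period average_rate average_annual_change
#> 1   ICDA-8 (1975-1979)     224.3068              4.788729
#> 2    ICD-9 (1980-2004)     330.4573              6.085820
#> 3 ICD-9/10 (2005-2016)     428.3961              6.404757
```

To see a coding artifact, inject one and look at cross-algorithm agreement:

```r
cfg_d <- study_config(
  sim = sim_config(seed = 42, disruptions = list(
    disruption_event(c(1990, 1991), "coding_sensitivity", 0.5)
  )),
  seed = 42
)
res_d <- run_study(cfg_d)
series <- lapply(names(res_d$fits), function(key)
  ooc_series(res_d$charts[[paste(key, 0.8, sep = " | ")]]))
round(agreement_by_year(series)[as.character(1988:1993)], 2)
```

`plot()` on any `control_chart` draws the observed-expected chart with the
ICD-change years marked.

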