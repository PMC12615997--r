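# fatalinc

Decomposition of racial disparities in the incidence of fatal cancer.

## The problem

Black men in the United States experience both higher prostate-cancer
incidence and worse survival than White men, and the *relative*
disparity in the most lethal disease is largest at young ages. Raw
incidence is a misleading basis for such comparisons when screening
intensity differs between groups, because screening inflates incidence
with overdiagnosed cases. A more comparable burden measure is the
incidence of **fatal cancer**: diagnoses that lead to cancer-specific
death within a fixed window of k years (10 by default),

    F = I × (1 − S_k)

where `I` is the incidence rate per 100,000 person-years and `S_k` the
k-year net cause-specific survival (other-cause deaths treated as
censorings). The Black-to-White ratio of `F` factorises exactly,

    RR_F = RR_I × RR_p        (p = 1 − S_k),

so its age pattern deconstructs into an incidence component and a
fatality component. `fatalinc` implements that deconstruction as a
tested pipeline for registry-style data stratified by race, 5-year age
band (45–84) and calendar era (pre-screening 1980–1989 vs established
screening 2000–2009 by default):

* per-stratum incidence (Poisson variance) and net survival
  (product-limit with Greenwood variance; annual actuarial option);
* delta-method Black/White rate ratios on the log scale with log-normal
  95% CIs, for all three metrics;
* inverse-variance weighted linear regressions of each ratio on the age
  band, with an era main effect and age × era interaction
  (`RR = β0 + β1·age + β2·era + β3·age·era`);
* a synthetic SEER-like registry simulator with known ground truth, so
  calibration, coverage and parameter-recovery studies run without any
  registry download.

## Worked example

```r
library(fatalinc)
res <- run_pipeline(pipeline_config(mode = "synthetic", seed = 7))
res
#> Disparity decomposition pipeline (synthetic mode, 10-year window)
#>   48 ratio rows (0 degenerate)
#>   incidence  intercept 2.180, age slope -0.110
#>   death_prob intercept 1.521, age slope -0.018
#>   fatal      intercept 3.256, age slope -0.184
```

The 48 rows are 3 metrics × 8 age bands × 2 eras. The fitted trend for
the fatal-incidence ratio:

```r
res$trends$fatal
#> Weighted linear age trend (ratio scale) for metric 'fatal'
#>   16 observations, reference era 'pre_psa', weights: invvar
#>                     Coefficient           95% CI       P
#> intercept                 3.256   3.087 to 3.424 2.1e-14
#> age_slope                -0.184 -0.213 to -0.155 1.2e-08
#> era_shift                -0.160  -0.416 to 0.096 2.0e-01
#> age_era_interaction       0.039  -0.007 to 0.084 8.7e-02
```

Read: in the reference (pre-screening) era the fatal-incidence ratio is
about 3.3 at ages 45–49 and falls by about 0.18 per consecutive 5-year
band, while the era shift and interaction are compatible with zero —
the age pattern of the disparity is stable across eras. Comparing the
three fits shows the decline is driven almost entirely by the incidence
component (slope −0.110) rather than the fatality component (slope
−0.018): young Black men's excess burden of fatal disease reflects
excess incidence more than excess fatality, the substantive motivation
for starting screening earlier in Black men. Per-era lines for plotting
come from `trend_lines(res$trends$incidence)`.

The same pipeline runs on real extractions: `mode = "micro_csv"` takes
a case listing and person-year table, `mode = "aggregate_csv"` takes
pre-computed per-stratum incidence counts and survival estimates (the
shape of a SEER*Stat export after header renaming; column schemas in
`?read_case_listing`, `?read_population`, `?read_aggregate`). The fatal
window is configurable (`window_years = 17` for a sensitivity
analysis), as are the eras, the survival estimator and the weighting
scheme. A thin command-line wrapper with subcommands `simulate`,
`estimate`, `decompose`, `trend` and `run` is installed at
`inst/cli/fatalinc`.

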