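---
title: "Decomposing age-specific racial disparities in fatal cancer incidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing age-specific racial disparities in fatal cancer incidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fatalinc)
```

## The problem and the composite metric

Raw cancer incidence is a poor basis for comparing disease burden across
populations when screening intensity differs, because screening inflates
incidence with overdiagnosed cases — tumours that would never have
surfaced clinically. A composite that conditions on a lethal outcome is
more comparable: the incidence of *fatal* cancer, defined as diagnoses
that lead to cancer-specific death within a fixed window of $k$ years
(10 by default). For a stratum (race $\times$ 5-year age band $\times$
calendar era),

$$F = I \times (1 - S_k),$$

where $I$ is the incidence rate per 100{,}000 person-years and $S_k$ the
$k$-year net cause-specific survival — the survival that would be seen if
the cancer of interest were the only cause of death, estimated by
treating deaths from other causes as censorings. Because every included
case dies of the cancer within the same window, the case mix is
comparable across age bands in a way that a mortality ratio (which mixes
very different diagnosis-to-death lags across ages) is not.

The racial disparity in any of the three metrics — incidence $I$, window
death probability $p = 1 - S_k$, or fatal incidence $F$ — is the
Black-to-White ratio within a stratum. Since

$$\mathrm{RR}_F = \mathrm{RR}_I \times \mathrm{RR}_p$$

exactly, the age pattern of the fatal-incidence disparity decomposes
multiplicatively into an incidence part and a fatality part; the
scientific question the pipeline addresses is which part drives the
elevated disparity at young ages, and whether the pattern changed
between the pre-screening era (diagnoses 1980–1989) and the established
screening era (2000–2009). The dissemination decade 1990–1999 is
deliberately excluded so each era reflects stable diagnostic practice.

## Estimators and uncertainty

**Incidence.** Within an era, cases and person-years are pooled over the
era's calendar years before dividing: $\hat I = 10^5 D / \mathrm{PY}$
with Poisson variance $10^{10} D / \mathrm{PY}^2$. Zero-count strata are
flagged degenerate and excluded from ratio construction rather than
continuity-corrected; at era-level aggregation over 5-year bands this
should essentially never occur in practice, and a silent correction
would bias the log-scale ratios it feeds.

**Net survival.** The default estimator is the continuous-time
product-limit (Kaplan–Meier) curve with events = cancer deaths and
censorings = other-cause deaths and administrative follow-up ends,
evaluated at $t = k$, with Greenwood variance. Ties between a death and
a censoring at the same time are resolved deaths-first, the standard
product-limit convention. An annual-interval actuarial estimator with
half-interval withdrawal adjustment is exposed
(`survival_method = "actuarial"`) for users matching registry software
that tabulates survival on yearly intervals; the two target the same
quantity and differ only by interval discretisation. If the risk set
empties before $k$ with survival still positive, the last value is
carried forward and the stratum is flagged in the pipeline log. When the
estimate reaches zero the Greenwood sum diverges; the variance is
reported as 0 and the stratum flagged — such strata are degenerate for
ratio purposes anyway. Era membership follows the year of diagnosis;
follow-up may run past the era's end.

**Ratios.** The delta method is applied on the log scale assuming
independence between the race groups and between the incidence and
survival components (they derive from different data dimensions):

$$\mathrm{se}\big(\log \mathrm{RR}\big)^2 =
  \frac{\mathrm{Var}(\hat v_B)}{\hat v_B^2} +
  \frac{\mathrm{Var}(\hat v_W)}{\hat v_W^2},$$

which for incidence reduces to $1/D_B + 1/D_W$. Confidence intervals are
log-normal, $\mathrm{RR}\cdot\exp(\pm z_{0.975}\,\mathrm{se})$, the
standard construction for ratio estimates and the reason the intervals
are asymmetric around the point estimate. The variance of the composite
uses the first-order delta method only,
$\mathrm{Var}(\hat F) = (1-S)^2\mathrm{Var}(\hat I) + I^2\mathrm{Var}(\hat S)$;
the neglected second-order term is $\mathrm{Var}(\hat I)\mathrm{Var}(\hat S)$,
which is orders of magnitude smaller at realistic stratum sizes (the
test suite bounds the gap against a Monte-Carlo propagation oracle).

## The trend model

The age pattern of each metric's ratio is summarised by weighted least
squares on the natural ratio scale:

$$\mathrm{RR}_{k,e} = \beta_0 + \beta_1 k + \beta_2 e + \beta_3 k e +
  \varepsilon_{k,e},$$

with $k = 0,\dots,7$ the age-band index (45–49 reference) and $e$ an
indicator for the later era. Choices worth stating explicitly, since
each was genuinely open:

* **Response scale.** The ratio scale, not the log, so that $\beta_0$ is
  the fitted young-age ratio itself and $\beta_1$ the change in the
  ratio per 5-year band — the scale on which such trend tables are
  reported. A log-scale option (`response = "log"`) is exposed for
  sensitivity; on synthetic data the qualitative conclusions are
  unchanged.
* **Weights.** Inverse estimated variance of each ratio,
  $w = 1/\widehat{\mathrm{Var}}(\mathrm{RR}) =
  1/(\mathrm{RR}^2\,\mathrm{se}_{\log}^2)$, the standard choice when
  per-point standard errors exist; `weights = "equal"` is exposed.
  Rescaling all weights by a constant leaves everything invariant, so
  only relative precision matters.
* **Inference.** t-based Wald tests with the residual-scaled covariance
  $\hat\sigma^2 (X^\top W X)^{-1}$ and $n - p$ degrees of freedom — the
  default behaviour of standard WLS fitters — rather than treating the
  weights as known variances. With 16 observations and 4 parameters the
  t reference matters.
* **Era structure.** One joint fit with an interaction, matching the
  reported table layout; per-era lines are derived from it
  (`trend_lines()`) rather than fitted separately.

## The synthetic registry and what it does (not) emulate

The simulator generates the study conditions end to end so that every
stage is testable without registry access. Per race, age band and
diagnosis year it draws a Poisson case count with mean person-years
$\times$ rate; each case receives a latent cancer-death time,
exponential with rate $-\log(1-p_k)/k$ so that the window death
probability equals the configured $p_k$ in the absence of competing
events, and an independent exponential other-cause death time; the
earliest of the two and the administrative cutoff determines outcome and
follow-up. A configuration whose implied Black death probability exceeds
1 is rejected with the offending stratum named — never clipped silently.

Default parameters are chosen to emulate a SEER-9-scale registry under
the two-era design: annual person-years per band of $6\times10^5$
(White) and $8\times10^4$ (Black); White incidence rising from 10 to 650
per 100,000 across the bands in the earlier era with a 1.6-fold
screening-era multiplier; White 10-year death probability rising from
0.25 to 0.46, halved in the screening era (screening-era survival gains
from lead time, overdiagnosis and treatment); other-cause hazards rising
from 0.010 to 0.100 per year; an incidence ratio $2.2\,e^{-0.06k}$
(declining from 2.2 toward 1.4 across bands, a linear-approximation
slope of about $-0.11$) and a nearly flat death-probability ratio
$1.49\,e^{-0.008k}$. These magnitudes reproduce registry-like case
volumes (about 200,000 cases per era) and ratio trends of the size seen
in US prostate-cancer surveillance. The administrative cutoff (2017 by
default) truncates follow-up of late screening-era diagnoses below the
10-year window, as in the real data span; the product-limit estimator
absorbs this as ordinary censoring.

Deliberate simplifications: age at diagnosis is fixed at the band level
(the analysis never uses attained age); person-years are exogenous
constants rather than a population model; latent times are exponential
and independent — there is no screening natural-history model, no lead
time, and no within-band heterogeneity or stage mix. Passing tests
therefore demonstrate that the estimators recover the quantities the
analysis consumes under a registry-shaped sampling process, not that
the biological model of any real registry is exponential.

Randomness: one root seed; each race/age/year stratum draws from a
sub-stream whose seed is a deterministic (Lehmer-style) hash of the root
seed and the stratum key, so the same seed is byte-identical and adding
strata to a configuration never perturbs existing ones.

## Recovery targets: comparing like with like

The generated ratio trend is log-linear in the age index while the
fitted model is linear in the ratio, so recovery studies need a
straight-line summary of the curved truth as their target.
`truth_trend_coefficients()` returns the least-squares line through the
exact true ratios — and, when the fit is inverse-variance weighted, the
*weighted* projection with analytic true-variance weights
(`truth_ratio_weights()`), because that weighted projection is the
estimand of the weighted fit. With the default configuration the
equal-weight slope is $-0.108$ and the weighted one $-0.100$: the
weights concentrate on the older, case-rich bands where the exponential
curve is flatter. Comparing the weighted fit to the equal-weight line
would report this estimand difference as spurious "bias". The analytic
weights treat the death-probability variance as binomial, ignoring the
modest censoring inflation; only relative weights across strata enter
the projection, so this approximation is benign.

## Numerical and degenerate-input conventions

* Incidence variances and rates are exact closed forms; no iteration
  anywhere in the pipeline, so the only tolerances are statistical.
* Degenerate strata (zero cases, zero death probability) propagate as
  flagged `NA` ratio rows, are logged by the pipeline, and are excluded
  from trend fits; they are never imputed.
* `fit_trend()` refuses under-identified designs (fewer than
  parameters + 1 usable rows, a single age band, or a rank-deficient
  design) with explicit errors rather than returning unstable fits.
* All randomness flows from configuration seeds; the simulator restores
  the caller's RNG state.

## Validation strategy and problem sizes

The test suite validates each stage against an independent oracle:
hand-computed product-limit toys and an exhaustive small-sample
risk-set walk (plus `survival::survfit`) for the survival estimator;
closed-form Poisson arithmetic for incidence; a Monte-Carlo propagation
oracle for the composite variance; brute-force normal equations for the
weighted fits. Calibration studies run at sizes chosen to make their
Monte-Carlo error small relative to the bands they check: 1000
replicates of a two-band registry for the delta-vs-Monte-Carlo standard
error comparison; 1000 replicates of a four-band, one-era registry at
full per-year person-years for interval coverage; 500 replicates of the
full default two-era registry for trend recovery; and 500 replicates of
a no-disparity registry (equal rates and fatality in both races, about
14,000 cases each) for the size of the slope test. On one CPU the whole
suite runs in roughly ten minutes, the trend-recovery study dominating.

## Known limitations

* Cause-specific (censoring-based) net survival, not relative survival;
  no Ederer or Pohar-Perme life-table correction, and no
  age-standardisation within bands.
* The aggregate mode trusts the supplied survival standard errors; it
  cannot reconstruct risk sets from aggregate input.
* The trend model is a straight line per era by design; no joinpoint or
  spline alternatives.
* Ratios only: absolute-scale disparities (rate differences) are out of
  scope, though the per-stratum estimates the pipeline writes are
  sufficient to compute them.
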