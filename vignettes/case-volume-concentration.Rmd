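---
title: "Measuring case-volume concentration in a surgical workforce"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring case-volume concentration in a surgical workforce}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caseconc)
```

## The measurement problem

Surgical registries record operations, not rosters. From one row per
operation — provider, unit, date — we want to answer: how unevenly are
operations spread across the workforce, what mathematical law describes the
spread, and how does a system shock (a pandemic lockdown) redistribute it?

Three classical concentration doctrines provide reference points. The
Pareto principle predicts 20% of providers perform 80% of the operations.
Price's law predicts half the operations come from the square root of the
number of providers. Lotka's law predicts the number of providers
performing $X$ operations in a period decays as an inverse power,
$Y = aX^{-b}$. `caseconc` computes, for real or simulated registries,
exactly the statistics needed to confront these predictions.

## From events to caseloads

Two cleaning rules precede everything:

* **Study window.** Registries have poorly completed early periods; events
  before the window's start (default 1 May 2016) are excluded, with the
  count recorded in an audit trail. Month attribution is by calendar month
  of the event date; no week-based logic.
* **Activity rule.** A registry cannot distinguish a provider who performed
  zero operations in a month from one who has left practice. We define the
  active workforce as providers with at least one operation on or after a
  cutoff (default April 2019, chosen as the start of the period with
  near-mandatory data entry) and give every active provider an explicit
  zero in months without operations. The modal monthly caseload is then 0,
  which is itself a finding, not an artefact.

Rows with a missing provider or unit, or an unparseable date, are dropped
and counted; a conservation identity (cells + dropped + excluded = raw
rows) is enforced in the test suite. Whether whole-period denominators
should use all observed providers or only the active subset is not
decidable from the data; the audit record preserves both counts so either
can be reported.

The result is the package's central object: a months × providers count
matrix (`caseload_matrix`). Unit-level analysis reuses the same machinery
with `entity_kind = "unit"` and all units active, since activity is only
defined for surgeons.

## Which law fits? Curve families and AIC

For each month we histogram the caseloads into a frequency table ($Y$
providers performing $X$ operations) and fit two two-parameter families by
nonlinear least squares on the raw $Y$ scale:

$$Y = aX^{-b} \quad\text{(inverse power / Lotka)} \qquad
  Y = ae^{-bX} \quad\text{(exponential decay)}$$

Numerical choices, all deliberate:

* **Initialisation.** The log-linearised OLS estimate ($\ln Y$ on $\ln X$
  or on $X$) seeds a Levenberg–Marquardt refinement; on noise-free data the
  seed is already the optimum, and the test suite checks recovery to
  relative error $10^{-6}$ and against a dense $200\times200$ log-spaced
  grid-search oracle. A Nelder–Mead fallback on the same objective guards
  degenerate tables.
* **Zero handling.** The power law is undefined at $X=0$, so both families
  are fitted on $X \ge 1$ and the zero bin is carried alongside, never
  silently discarded; asking for `include_zero = TRUE` with the power
  family is an error rather than a silent offset transform.
* **AIC convention.** With least squares on a common scale, the Gaussian
  profile likelihood gives $\mathrm{AIC} = n\ln(\mathrm{rss}/n) + 2(p+1)$,
  $p = 2$ parameters plus one for the error variance. Comparisons are valid
  because both families see identical points; `compare_families()` enforces
  this. An exact fit has $\mathrm{rss}=0$ and $\mathrm{AIC}=-\infty$; the
  AIC difference of the best fit is defined as 0 so noise-free comparisons
  stay well-posed. Ties break toward fewer parameters, then lexical family
  name, for determinism.
* **Weighting.** Poisson-type weights ($1/\max(Y,1)$) are available but off
  by default: the headline comparison is unweighted least squares on the
  raw scale.

Monthly fits are pooled by inverse-variance weighting of the per-month
estimates (variances from the fit curvature), with the spread of monthly
estimates reported as a between-month standard deviation. This two-stage
scheme replaces a nested-random-effects (year/month) nonlinear mixed model:
it preserves the interpretation of the fixed-effect coefficients while
keeping each month's fit — the object actually being compared across
families — as a first-class result. Months whose fits are exact (zero
residual) carry no usable curvature and fall back to equal weights.

## Concentration statistics

Sort a month's volumes in descending order and accumulate shares. For a
target share $q$, $k_q$ is the smallest number of top providers whose
cumulative share reaches $q$, linearly interpolated within the marginal
provider (interpolation is on by default: monthly series and tight
confidence intervals need sub-integer resolution; integer $k$ is
available). Then:

* **Pareto fraction** $= k_q/N$. The test suite proves by exhaustive subset
  enumeration on small instances that the greedy descending prefix is a
  minimum-cardinality cover, so this is not merely a convention.
* **Price root** $n = \ln N / \ln k_{0.5}$, the exponent solving
  $k_{0.5} = N^{1/n}$; $n = 2$ is Price's law. Undefined when a single
  provider covers half the volume (an error, not an NA, since a registry
  where that happens needs different tools).

The denominator $N$ defaults to providers who operated that month
(`operating_only`); `all_active` includes explicit zeros. Monthly medians
of operating surgeons sit far below the whole-period provider count in
registry-like data, and fractions move materially between the two rules, so
the choice is exposed rather than hidden. Ties between equal volumes are
ordered by entity id to make outputs byte-reproducible; all statistics are
scale-invariant (multiplying volumes by a constant changes nothing).

Monthly series are summarised by the arithmetic mean with a 95%
t-interval, $\bar{x} \pm t_{0.975,m-1}\,s/\sqrt{m}$ over the $m$ months —
the minimal-assumption summary for "mean of monthly values with a CI".
Quantiles throughout (IQRs, monthly 75th centiles, box statistics) use
linear interpolation between order statistics (type 7), which is why
reported IQR bounds can be fractional.

## Volume bands and shocks

To ask "what happened to the high-volume surgeons?", providers are grouped
by contribution rather than by count: sorted ascending by reference-period
volume, band 1 is the (largest) group of lowest-volume providers whose
operations accumulate to the first 20% of the total, and so on; the final
band is the small group of highest-volume providers. A provider belongs
wholly to the band containing its cumulative-share endpoint — people are
not split — with the final band absorbing the remainder; a lone contributor
degenerates to band 1. Providers with zero reference volume are unassigned,
since the grouping is by contribution. Band labels run 1..⌈1/share⌉; a
band can be empty when one provider's share straddles it.

Bands are tracked across periods by each member's **mean monthly volume**
(not the total, so periods of unequal length are comparable), summarised
with type-7 quartiles and Tukey $1.5\cdot\mathrm{IQR}$ whiskers with
outliers listed explicitly.

Shock scenarios thin each entity's shock-month counts binomially with a
band-specific multiplier. Suppressing only the top band reproduces the
distributional signature seen during lockdowns — the top band's median
collapses while band 1 barely moves — and the suite asserts exactly that.
It is worth noting what such a shock does *not* do: because it equalises
the surviving volumes, the monthly Pareto fraction among operating
providers *rises* (concentration falls). An observed concentration
*increase* under a real lockdown requires the additional mechanism of
low-volume providers dropping to zero and leaving the operating denominator
— which a bottom-band multiplier of 1 deliberately switches off.

## The synthetic registry

The generator's default configuration is the study condition, not a knob:
~650 providers across ~285 units over the 58 months from May 2016 to
February 2021, gamma–Poisson caseloads (shape 0.5, mean 4 operations per
provider-month, so ~150,000 events), and a 52.9% chance that a provider
works at more than one unit (extra affiliations 1 + geometric with
$p = 0.6$, capped at seven units — a realistic upper bound for consultant
practice). Event dates are uniform within month; day-of-week structure is
out of scope. A single integer seed makes every draw reproducible, and
generated events round-trip through the ingest machinery to the exact
matrix they came from.

Rate models: `gamma_poisson` draws a latent rate per provider once and
Poisson counts around it each month (overdispersed, exponential-like
frequency tables — the regime registry data resembles); `zeta_power` and
`geometric` draw counts directly and independently per provider-month
(the former gives Lotka-type power-law tables); `explicit` takes rates
verbatim, optionally without dispersion, for exact-arithmetic tests.

What the generator does *not* emulate: seasonal and secular trends in
ascertainment, case-mix differences between providers, provider entry/exit,
and within-provider month-to-month rate drift. Tests passing on synthetic
data therefore validate the *machinery* (counting, fitting, concentration
algebra), not claims about any particular real registry.

A deterministic companion, `make_pareto_tail_population()`, sets volumes to
Pareto quantiles at probabilities $(i-0.5)/N$. With tail index
$\alpha = \ln 5/\ln 4 \approx 1.161$ the continuous distribution is the
self-similar 80/20 population. A caveat established analytically and
verified in the tests: the top-20% share of the *finite* discretised
population converges to 80% only like $N^{-(1-1/\alpha)} = N^{-0.139}$,
because the midpoint construction truncates the extreme tail that carries
much of the volume. At $N = 10^5$ the fraction of top contributors covering
80% is ≈ 0.262, not 0.200; the closed-form finite-$N$ value
$f = (q + (1-q)\varepsilon^{\theta})^{1/\theta}$ with
$\theta = 1 - 1/\alpha$, $\varepsilon = 0.5/N$ approximates it. Analyses
using this fixture should quote the finite-$N$ value, not the limit.

## Model selection in small months

On *expected* gamma–Poisson frequencies the AIC prefers exponential decay
over the power law across shapes 0.5–2 (the suite asserts this). In
individual sampled months of ~300 providers, however, the sparse singleton
bins in the upper tail ($Y = 1$ at large $X$) resemble a heavy tail and tip
raw-scale least squares toward the power family in a substantial minority
of months. Model preference tallies over months at that scale are therefore
noisy, and the pooled comparison — or comparison on several months jointly
— is the more stable summary. Similarly, log–log diagnostics of power-law
samples are linear only where expected bin occupancy is well above 1; the
suite restricts its linearity check to bins with expected count ≥ 5 for
this reason.

## Problem sizes used in the tests

The suite exercises: exhaustive-enumeration oracles at $N \le 12$ (200
instances); grid-search fitting oracles on 5–15 point tables; perfect-square
Price-root identities up to $N = 10^4$; the Pareto-tail fixture at
$N = 10^5$; model selection over 100 synthetic months of 300 providers and
one month of 10,000 providers; shock scenarios over 50 replicates of a
300-provider year; and one full registry-scale run (650 providers, 58
months, ~150k events) through the complete pipeline. These sizes were
chosen to make every stochastic assertion well-powered while keeping a full
test run interactive.

## Known limitations

* The two-stage pooled fit is not a likelihood-based mixed model; its
  between-month dispersion is descriptive, not a variance component.
* Concentration statistics condition on the chosen denominator rule;
  neither rule is "the" truth when activity status is unobservable.
* No Gini/Lorenz machinery, no geographic stratification, and no
  ascertainment modelling: the pipeline treats the registry as a census of
  the activity it records.
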