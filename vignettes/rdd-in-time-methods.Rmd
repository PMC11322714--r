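---
title: "Methods: regression discontinuity in time for person-day event panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regression discontinuity in time for person-day event panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdtime)
```

## The estimation problem

`rdtime` estimates the causal effect of an abrupt, dated policy change — the
motivating setting is the first COVID-19 lockdown in Antananarivo, Madagascar,
beginning 2020-03-23 — on the daily use of a mobile money service for
maternal health care. Three binary outcomes are tracked per user per day:
whether the user saved to her health wallet, paid for a delivery, or redeemed
an electronic voucher at the point of care. The unit of analysis is the
person-day: a cohort of `n` users observed over `D` days contributes
`n x D` binary indicators per outcome ("active use", not volume — repeated
same-day events collapse to a single 1, and days with no recorded event are
structural 0s, so the dense panel has no missing cells).

Because the lockdown applies to everyone from a known calendar day, the
identification strategy is a regression discontinuity in *time*: the running
variable is the day index `t` (zero-based from the study start, so
2020-01-01 is day 0 and 2020-03-23 is day 82), treatment is `L = 1{t >= c}`
with the cutoff day itself on the treated side, and the estimand is the
discontinuity in the event rate at `c`.

## The segmented modified Poisson model

Within a window of `h` days on each side of the cutoff the log event
probability is modelled as piecewise linear with a level shift:

```
log p(t) = b0 + b1 (t - c) + b2 L + b3 (t - c) L
```

* `exp(b2)` — the incidence rate ratio (IRR) at the lockdown: the jump.
* `exp(b1)` — the pre-lockdown daily trend IRR.
* `exp(b1 + b3)` — the lockdown daily trend IRR (time and interaction
  coefficients added); `b3` is the slope change, and its Wald p-value is the
  test for a trend break.
* `exp(b0)` — the pre-lockdown line evaluated at the cutoff;
  `exp(b0 - c b1)` extrapolates it back to day 0, the baseline rate at the
  study start. Both parameterizations are reported
  (`pre_rate_at_cutoff` and `baseline_day0` in the IRR table) because either
  can be meant by "the intercept" depending on where the running variable is
  anchored; the model itself is fitted with the running variable centered at
  the cutoff.

The outcome is binary, but the model is fitted as a Poisson regression with
log link — the "modified Poisson" device — so that exponentiated
coefficients are rate ratios rather than odds ratios. The price is a
misspecified variance (Bernoulli, not Poisson), which is paid by reporting
heteroskedasticity-robust sandwich standard errors: `B^{-1} M B^{-1}` with
bread `B = sum_i mu_i x_i x_i'` and meat `M = sum_i (y_i - mu_i)^2 x_i x_i'`
(HC0). With 10^5–10^6 person-days, finite-sample corrections are immaterial;
HC1 and a cluster-by-user variance are available as sensitivity options. The
cluster option exists because person-days within a user may correlate; it is
not the headline estimator, and under the independence of the default
generator it changes standard errors only within Monte Carlo noise.

`fit_poisson()` implements its own iteratively reweighted least squares
(IRLS) rather than delegating, so the scoring, convergence and covariance
conventions are fully specified here: initialization at
`b = (log ybar, 0, 0, 0)`, convergence when the relative deviance change
falls below `1e-10`, a hard cap of 100 iterations (non-convergence is an
error carrying the deviance trace, never a silent result), collinear designs
rejected rather than repaired, and a warning when fitted probabilities
exceed 1 (the log link does not constrain them; with these event rates it
does not occur in practice). The test suite cross-checks coefficients
against an independently coded Newton maximizer and `stats::glm`, and the
sandwich against `sandwich::vcovHC`, at `1e-8`.

### Exact aggregation

All covariates are functions of the day alone, so the Poisson likelihood
factorizes over days. Two consequences are used heavily:

1. The person-day fit equals (to numerical precision) the fit of daily event
   *counts* with a `log(n)` exposure offset.
2. The person-days of day `t` can be collapsed to two weighted rows
   (`y = 1` with weight `k_t`, `y = 0` with weight `n - k_t`) without
   changing the coefficients *or* the HC0 sandwich, because `(y - mu)^2` is
   constant within each row group.

`fit_rdd()` uses the second form, so a fit on 820,000 person-days costs a
GLM on at most `2 x (2h + 1)` rows. Both identities are standing tests.

## Bandwidth selection

The window half-width `h` trades bias (wider windows see more curvature)
against variance. `ik_bandwidth()` implements the Imbens–Kalyanaraman
plug-in on the daily aggregate rate series: a first-stage window
`h1 = 1.84 sd(t) N^{-1/5}` yields the conditional variance `sigma^2(c)` and
density `f(c)` at the cutoff; a global cubic (with a jump dummy) estimates
the third derivative, which sets second-stage windows for local quadratic
fits whose second derivatives `m''(c)` on each side enter the final step

```
h = C_K * ( 2 sigma^2(c) / ( f(c) [ (m''_+ - m''_-)^2 + r_+ + r_- ] ) )^{1/5} * N^{-1/5}
```

with regularization terms `r = 2160 sigma^2 / (N2 h2^4)` guarding against a
vanishing curvature difference. The result is truncated to the days
available on the shorter side and rounded to whole days.

Because the estimation stage applies an unweighted hard window, the uniform
(rectangular) kernel constant is the default. The constants are derived
from the boundary local-linear expansion — one-sided bias `C1 h^2 m''` and
variance `V_K sigma^2/(N h f)` give `C_K = (V_K / (4 C1^2))^{1/5}`:
`144^{1/5} = 2.70` for the uniform kernel (`C1 = 1/12`, `V_K = 4`) and
`480^{1/5} = 3.4375` for the triangular kernel (`C1 = 1/20`, `V_K = 4.8`),
the latter matching the classical constant and available via
`kernel = "triangular"`.

Two behaviors of the plug-in deserve flagging. First, when the true curve
has *no* curvature difference (piecewise linear, or constant), the
finite-sample MSE-optimal window is the whole available range — any `h` is
unbiased and variance falls in `h` — while the regularized plug-in stays
interior by construction: the `r` terms and the noise floor of the
curvature estimates keep `h` near half the pilot window regardless of the
noise scale. Second, on strongly convex exponential trends the pooled cubic
pilot underestimates the boundary curvature, widening `h` somewhat. For
these reasons the selector is validated against a brute-force oracle on the
canonical well-posed design — rates locally linear at the cutoff with a
genuine curvature difference between sides plus a level shift — where the
pilot fits are correctly specified: there the plug-in lands within a few
days of the bandwidth minimizing the empirical MSE of the local-linear jump
estimator over 500 replicates (median 32 vs 30 days at cohort scale in the
frozen test). The selector is also exactly invariant to rescaling all
rates, and the final plug-in step shrinks by exactly `2^{-1/5}` when `N`
doubles with pilot quantities held fixed.

The analysis cutoff itself is configuration-supplied (day 82 by default):
the policy date is known, so `detect_cutoff()` on the stringency series is
a verification aid, not the source of the cutoff.

## Counterfactual recovery time

After the drop, does use return to where the pre-lockdown trend was
heading? On the log scale the extrapolated counterfactual minus the fitted
post line is `-b2 - b3 s` at `s` days after the cutoff, so the curves cross
at `s* = -b2 / b3` when the jump and slope change have opposite signs; a
zero jump crosses at 0; parallel lines never cross. `crossing_time()`
evaluates the closed form (with a bisection cross-check agreeing to
`1e-6`), reports `Inf` for "never", and bounds the search by a horizon of
999 days — also the sentinel value used in tabular exports, where "never"
is written as 999 and a stratum whose window has an event-free side is
written as `"inestimable"`, never as the sentinel.

The crossing is computed from the coefficients of the *same*
bandwidth-restricted fit and then extrapolated beyond the window — that is
what "extrapolated counterfactual" means here; refitting on all data is
available by passing a larger bandwidth explicitly. `recovery_by_age()`
refits per age stratum, by default reusing each outcome's whole-cohort
bandwidth (per-stratum reselection tends to be unstable at stratum sizes of
roughly a thousand users and would conflate bandwidth noise with stratum
differences; it is available by calling `ik_bandwidth()` on stratum rates).
No confidence intervals are attached to crossing times; they are smooth but
strongly nonlinear functionals of the coefficients, and interval coverage
would require a bootstrap that is out of scope.

## The synthetic cohort generator

Raw service logs of this kind are not publicly depositable, so
`simulate_panel()` generates panels with exactly the statistical structure
the analysis assumes, making every downstream stage testable offline:

* Independent Bernoulli person-day indicators with
  `p(t) = baseline * pre^t` before the cutoff and
  `baseline * pre^c * jump * post^(t-c)` after — the minimal model implied
  by daily binarization. Defaults: a fixed cohort of 3416 users over 240
  days, cutoff day 82, and per-outcome blocks (baseline rate, daily trend
  IRRs, jump IRR) of 0.0090/1.0124/0.4152/1.0113 for savings,
  0.0026/1.0111/0.5412/1.0054 for payments, and 0.0051/1.0034/0.5047/1.0067
  for vouchers. The generator refuses any configuration whose rate curve
  reaches 1 rather than clipping silently.
* Ages from a log-normal calibrated to median 26 years, IQR 9, rounded to
  whole years (only these two quantiles are pinned down, so the family is a
  modelling choice); groups `<25`, `25-30`, `>30`, with the middle group
  the closed interval so the labels partition integer ages. Per-group
  overrides of the jump and post-trend let tests build age-dependent
  recovery patterns.
* Service constraints: a user's payments after her first are suppressed
  (keep-first, matching a service that admits one delivery payment per
  user); voucher indicators are at most one per user-day by construction.
  Keep-first suppression thins later payment days by the survival factor
  `S(t) = P(no prior payment)`; `S` is continuous at the cutoff, so the
  fitted *jump* stays unbiased while the fitted slopes absorb
  `d log S / dt = -p(t)` — at the default payment rates a per-day
  attenuation of under half a percent, visible only as a small conservative
  bias in payment trend estimates. The parameter-recovery tests confirm the
  jump is recovered for all three outcomes at full scale.
* One seed drives everything; per-outcome substreams are derived
  deterministically from it, so a panel is reproducible outcome by outcome.

Two things the generator deliberately does **not** model: within-user
correlation or overdispersion (events are independent given `p(t)`; the
cluster-robust variance option exists precisely so real data can be checked
against this assumption), and enrollment growth — the person-day accounting
of a fixed `3416 x 240` cohort implies structural zeros before a user's
first activity, and the default keeps that fixed cohort. The trend-IRR and
baseline defaults, taken together with a fixed cohort, over-predict total
event counts relative to a cohort whose enrollment was still ramping up;
the denominator convention is genuinely ambiguous, so the generator exposes
`enrollment = TRUE` (uniform enrollment days over the pre-cutoff period,
zeroing pre-enrollment person-days) rather than guessing a single
convention. Passing tests therefore demonstrate correctness of the
*estimator* under the stated data-generating process, not robustness to
clustered or autocorrelated real-world usage.

## Stringency index

The policy-side input is a per-day series of the eight
containment-and-closure indicators (school closure, workplace closure,
public event cancellation, gathering restrictions, public transport
closure, stay-at-home requirements, internal movement restrictions,
international travel controls) with ordinal codebook bounds 3, 3, 2, 4, 2,
3, 2, 4. The index is their plain sum, spanning 0–23; it is monotone in
every indicator. (Describing all eight as "rated 0 to 4" is a common
shorthand but wrong for five of them; the bounds above are what cap the
index at 23.) Geographic-scope flag columns are ignored. Missing indicator
values impute as 0 — the least severe level, a conservative choice that
never manufactures restrictions — with a warning and a per-day flag;
last-observation-carried-forward is available via `missing = "carry"`.

## Problem sizes and determinism in the shipped tests

The test suite regenerates all data in code. The heavy checks run 200
replicates per outcome at full cohort scale (3416 users x 240 days) for
jump recovery within 3 Monte Carlo standard errors, 500 replicates at 1000
users for 95% CI coverage (required inside [92%, 98%]), 500 replicates of
the bandwidth oracle comparison, 300 replicates for the robust-SE versus
empirical-SD check (within 10%), and 1000 random coefficient draws for the
closed-form/bisection agreement; together they complete in well under a
minute. These sizes were chosen so that Monte Carlo error is far below
every asserted tolerance. All randomness flows through fixed seeds, and the
pipeline writes bit-identical outputs for identical configuration and seed.
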