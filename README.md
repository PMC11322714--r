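# rdtime

Regression discontinuity in time for person-day event panels, built for
interrupted health-service utilization questions: when a policy with a known
start date (the motivating case is a COVID-19 lockdown beginning
2020-03-23) abruptly changes how people use a service, how large was the
drop, did the trend change, and when — if ever — does use return to where
the pre-policy trend was heading?

The package is aimed at epidemiologists and health economists working with
transaction-level service logs (here: mobile-money savings, delivery
payments and electronic voucher redemptions for maternal care), and at
methodologists who want a fully testable, simulation-backed implementation
of the design.

## The model

Each user contributes one binary indicator per day and outcome (any event
that day = 1). Within a window of `h` days around the cutoff day `c`, the
log event probability is segmented-linear in the day index `t`:

    log p(t) = b0 + b1 (t - c) + b2 1{t >= c} + b3 (t - c) 1{t >= c}

fitted as a **modified Poisson regression**: Poisson likelihood with log
link on the binary outcome, paired with a heteroskedasticity-robust
sandwich (HC0) covariance so that `exp(b2)` is the incidence rate ratio
(IRR) at the cutoff with valid standard errors, `exp(b1)` the pre-cutoff
daily trend, and `exp(b1 + b3)` the post-cutoff daily trend. The window
half-width is chosen by an **Imbens–Kalyanaraman plug-in bandwidth** on the
daily aggregate rates (uniform-kernel constant, matching the hard
estimation window), and robustness is probed by refitting across a
±20-day bandwidth grid. The **recovery time** is the crossing of the
extrapolated pre-cutoff counterfactual by the post-cutoff fitted line,
`s* = -b2 / b3` days after the cutoff ("never" when signs do not oppose;
999 is the export sentinel). A policy-stringency module builds the 0–23
containment index (sum of the eight containment-and-closure ordinal
indicators) from OxCGRT-style files to verify the cutoff date.

Since raw service logs of this kind are not publicly depositable, a
first-class synthetic generator (`simulate_panel()`) produces person-day
panels with the exact assumed structure — log-linear rates with a jump,
age-group heterogeneity, one-payment-per-user and one-voucher-per-user-day
constraints — so the whole pipeline is testable offline, with known truth.

## Worked example

```r
library(rdtime)

sim   <- simulate_panel(sim_config(seed = 20200323))
panel <- sim$panels$saving
panel
#> Person-day panel (saving): 3416 users x 240 days = 819840 person-days; 19617 events; cutoff day 82

bw <- ik_bandwidth(daily_rates(panel), cutoff_day = 82)
bw
#> IK plug-in bandwidth: 48 days (raw 48.14, cap 82; uniform kernel)

fit <- fit_rdd(panel, bw$h_opt)
fit
#> RDD fit: outcome 'saving', stratum all, bandwidth 48 days (days 34-130), HC0 variance
#>   3416 users, 331352 person-days, 5345 events
#>                term      irr conf_low conf_high       p
#>       baseline_day0 0.008163 0.006973  0.009555 0.0e+00
#>  pre_rate_at_cutoff 0.026000 0.024350  0.027760 0.0e+00
#>                jump 0.367400 0.328800  0.410500 5.6e-70
#>           pre_trend 1.014000 1.012000  1.017000 1.7e-27
#>          post_trend 1.014000 1.011000  1.017000 8.2e-20
#>        trend_change 0.999700 0.995800  1.004000 8.8e-01

irr_to_percent_change(0.3674)
#> [1] 63.3
```

Reading the output: savings events ran at about 0.8% of users per day at
the study start (`baseline_day0`), climbing about 1.4% per day
(`pre_trend`); at the lockdown the daily saving rate dropped to 36.7% of
its counterfactual level (`jump`, a 63.3% decrease in this simulated
cohort, robust-CI 0.33–0.41), and the post-lockdown trend is
indistinguishable from the pre-lockdown trend (`trend_change` p = 0.88), so
the fitted savings rate never crosses the extrapolated counterfactual.

Age-stratified recovery for vouchers from the same simulated cohort:

```r
rec <- recovery_by_age(sim$panels,
                       bandwidths = c(saving = 110, payment = 55, voucher = 70))
subset(rec, outcome == "voucher")
#>    outcome stratum bandwidth_days crossing_days_after_cutoff recovered
#>  9 voucher     all             70                      92.71      TRUE
#> 10 voucher     <25             70                      62.40      TRUE
#> 11 voucher   25-30             70                     383.77      TRUE
#> 12 voucher     >30             70                      93.76      TRUE
```

`run_pipeline()` orchestrates the same stages end to end (simulate or
ingest CSV logs, summarize, select bandwidths, fit, scan, export recovery
tables) into a run directory with a seed-stamped log;
`inst/scripts/rdtime-cli.R` is a thin command-line wrapper with
`simulate` / `analyze` / `sensitivity` / `report` subcommands. See the
methods vignette (`vignettes/rdd-in-time-methods.Rmd`) for the model,
bandwidth-selector derivation, generator design and limitations.

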