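---
title: "Predictive-probability monitoring for umbrella trials: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictive-probability monitoring for umbrella trials: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pptrial)
```

## The design model

Each arm of the umbrella trial is a single-arm phase II study of a binary
endpoint, the confirmed objective response. The response probability $p$
carries a conjugate prior $p \sim \mathrm{Beta}(a_0, b_0)$; after $x$
responders among $n$ evaluable patients the posterior is
$\mathrm{Beta}(a_0 + x,\, b_0 + n - x)$. The arm succeeds at its final
analysis of $N_{\max}$ patients when

$$\Pr(p > p_0 \mid x, N_{\max}) > \theta_T,$$

with $p_0$ the reference response rate a new regimen must beat. At an
interim look with $n < N_{\max}$ patients the *predictive probability* of
eventual success is

$$\mathrm{PP}(x, n) \;=\; \sum_{y=0}^{m}
  \binom{m}{y}\frac{B(a_0 + x + y,\; b_0 + n - x + m - y)}{B(a_0 + x,\; b_0 + n - x)}
  \; \mathbf{1}\!\left[\Pr(p > p_0 \mid x + y, N_{\max}) > \theta_T\right],
  \qquad m = N_{\max} - n,$$

the beta-binomial-weighted probability that the final criterion will hold.
The arm stops for futility when $\mathrm{PP} < \theta_L$ and for efficacy
when $\mathrm{PP} > \theta_U$. All three comparisons are strict, so a PP
exactly on a threshold continues (interim) or fails (final). At
$n = N_{\max}$ the predictive probability collapses to the 0/1 verdict of
the final rule, so the interim machinery and the final rule are one
formula.

The package defaults are $p_0 = 0.15$, prior $\mathrm{Beta}(0.05, 0.05)$,
$\theta_T = 0.5$, $\theta_L = 0.1$, $\theta_U = 0.9$ and $N_{\max} = 20$:
the monitored-trial parameter set used in all examples, describing a
heavily pretreated metastatic TNBC population in which a ~15% response
rate is the historical benchmark.

```{r}
des <- ppd_design(n_max = 20, monitor_start = 10)
stopping_boundaries(des)
```

### Numerical choices

Posterior exceedance is the upper regularized incomplete beta tail
(`pbeta(..., lower.tail = FALSE)`). Predictive masses are computed in
log-beta arithmetic (`lchoose` + `lbeta`) to avoid overflow, normalize to
1 within $10^{-12}$, and the PP sum is clamped into $[0,1]$ so that a
floating-point excess of order $10^{-16}$ can never trip a strict
comparison against a disabled threshold ($\theta_U = 1$). Boundary cutoffs
exploit that PP is nondecreasing in $x$ at fixed $n$, so each is a simple
threshold scan; the test suite verifies the whole table against
brute-force evaluation of PP on the full $(x, n)$ grid.

### Monitoring schedule

When interim looks occur is genuinely open: the design is defined by its
thresholds, not its calendar. We default to continuous monitoring
(`monitor_start = 1`, `monitor_step = 1`), the standard reading of
predictive-probability designs, and expose both knobs. Two consequences
are worth knowing. First, with the very diffuse bathtub-shaped
$\mathrm{Beta}(0.05, 0.05)$ prior, a look after the first patient is
already decisive — one response pushes PP above 0.9 and one failure below
0.1 — so continuous monitoring from $n = 1$ makes the first evaluable
patient determine the arm. Analyses that want the monitor to see a
stabilized estimate first should set `monitor_start` to the first
realistic decision point (the examples here use 10, matching a 10–20
patient first stage). Second, the operating-characteristics engine
(`operating_characteristics()`) treats the schedule exactly: the exact
mode propagates the $(n, x)$ Markov chain look by look; the Monte-Carlo
mode simulates Bernoulli accrual through the same boundary table; the two
are cross-checked within simulation error in the tests.

### The final success cutoff and the "three or more" shorthand

The smallest responder count that clears the final posterior criterion is
computed, never hard-coded:

```{r}
data.frame(n_final = 10:20,
           cutoff = vapply(10:20, final_success_cutoff, integer(1),
                           design = ppd_design()))
```

A widely used shorthand for this design summarizes the efficacy boundary
as "three or more responders". The computed cutoffs show that shorthand is
exact only for final sizes 13–18: two responders suffice at 10–12
patients, and four are needed at 19–20. The package reports the computed
cutoff and treats the shorthand as descriptive.

### Dropout inflation and arm expansion

`inflate_for_dropout(n, rate)` returns $\lceil n / (1 - \mathrm{rate})
\rceil$ — e.g. 41 evaluable patients at 10% dropout require 46 enrolled.
`expand_arm()` raises an open arm's maximum mid-trial (as done for the
best-performing arm of the motivating trial, 20 to 41 evaluable); every
expansion is audited, and later PP computations automatically use the new
horizon, which generally changes PP at the same $(x, n)$.

## Endpoint derivation

### Confirmed best overall response

`derive_bor()` reduces a patient's timestamped assessments
(CR/PR/SD/PD/NE) to one best overall response. CR or PR counts only when
confirmed by a same-or-better scan at least 28 days ("4 weeks",
inclusive) later; stable disease requires an SD-or-better scan at least 56
days ("8 weeks", inclusive) from first dose; progression before any
qualifying response gives PD; no postbaseline scan gives `NA` (and such
patients stay in the intention-to-treat denominator). Scans on or after
the first documented progression never upgrade the result, and NE scans
are skipped for confirmation. Two edge conventions are ours and are
logged in the per-patient `reason` field: an unconfirmed PR is downgraded
to SD when the SD-duration rule holds, and a patient whose scans exist but
qualify for nothing (for example one early SD followed by loss to
follow-up) is returned as `NA` with reason `"not_evaluable"` rather than
forced into PD. Timepoint classification from percent changes uses the
solid-tumor thresholds: PD at $\geq +20\%$ growth from nadir (the nadir
rule dominates), PR at $\leq -30\%$ change from baseline.

Rates are reported as percentages rounded half-up to one decimal, with
two-sided exact Clopper–Pearson intervals in their beta-quantile form:

```{r}
summarize_orr_dcr(data.frame(bor = c(rep("PR", 42), rep("PD", 99)),
                             confirmed = c(rep(TRUE, 42), rep(FALSE, 99))),
                  denominator = 141)$orr
```

### Survival conventions

`derive_pfs()` implements the trial's censoring rules with a
machine-readable reason on every censoring: documented progression events
on the PD day; death without documented progression events on the death
day unless more than one scheduled visit was missed first —
operationalized as a gap above `2 * visit_interval_days` between the last
adequate assessment (or day 0) and death — in which case the patient is
censored at the last documented nonprogression; discontinuation without
documented progression censors at the last progression-free assessment.
The visit interval is two treatment cycles (42 or 56 days for 21- and
28-day cycles). Days convert to months at 30.4375 days/month, a fixed
documented convention. `derive_os()` events at death, else censors at
last contact.

Kaplan–Meier estimation, Greenwood errors and the Brookmeyer–Crowley
log–log median interval are delegated to the `survival` package; the
median itself is reported as the earliest time with $\hat S(t) \le 0.5$
(rather than `survfit`'s midpoint convention on flat intervals), matching
the definition above. The univariate Cox biomarker screen
(`cox_univariate()`) uses Breslow tie handling by default (Efron
optional) and flags monotone partial likelihoods as nonconvergent instead
of reporting a spuriously finite hazard ratio; the tests pin its
estimates to a grid-search maximizer of the Breslow partial likelihood on
all small fixtures.

## The synthetic umbrella trial

`synthetic_trial_config()` / `simulate_trial()` generate complete trials
in the exact input schemas of the analysis modules. The defaults are the
study conditions the package is exercised under: 151 screened patients
thinned by a 10/151 screening-failure rate; seven arms with multinomial
prevalences proportional to 4/20/46/10/46/6/9; per-arm true response
probabilities at the observed arm-level point estimates (0.75, 0, 0.435,
0.20, 0.283, 0.167, 0.333); exponential latent progression and death
times at the observed per-arm medians, with death generated as
progression plus an exponential post-progression increment so OS never
precedes PFS; imaging every two cycles (21- or 28-day cycles per arm);
and 10% dropout, uniform over the first two cycles — i.e. before the
first scan, which is what made dropouts non-evaluable in the motivating
trial. Accrual is a Poisson process at 3.5 patients/month, a rate that
spreads ~141 patients over roughly the trial's 40-month accrual window.

Two generator conventions matter for interpretation. Responders'
progression times are left-shifted past the confirmation scan (PD is
drawn as confirmation day plus an exponential), so a responder always
*can* be confirmed unless dropout intervenes; this makes the confirmed
responder count among evaluable patients exactly binomial at the true
rate — the property the interval-coverage tests rely on — at the cost of
slightly longer responder PFS than the configured median. And because a
patient enters the monitoring state $(n, x)$ only once their best
response is adjudicated, early looks are enriched for fast progressors
(progression adjudicates at the first PD scan, response only at the
confirmation scan): interim $x/n$ is pessimistic relative to the true
rate early in accrual. That is a real feature of response-adjudicated
monitoring, not an artifact.

What the generator does not emulate: correlation between response and
survival beyond arm membership (a knob exists but is off by default),
non-exponential hazards, assessment-window jitter, lesion-level
measurements, and informative dropout. Passing tests therefore
demonstrate the pipeline's correctness under clean exponential/binomial
structure, not robustness to real-world messiness.

## Problem sizes used in the test suite

The suite pins: the PP grid against exhaustive enumeration for all
$(x, n)$ up to $N_{\max} = 25$ at $10^{-10}$; exact-DP operating
characteristics against 10,000-replicate Monte Carlo at four true rates;
KM median recovery on 2,000-patient exponential cohorts (median 3.4
months, within 0.15 months; 0.2 with 30% censoring); Cox estimates
against a $10^{-4}$-resolution grid search on $\le 12$-patient fixtures;
interval coverage over 200 replicate 30-patient arms; and a 3,000-patient
pooled run of the full response pipeline in the generator's recovery
checks. These sizes were chosen so each check's sampling error is well
below the tolerance it asserts.

## Known limitations

* The per-arm survival summaries of the motivating trial are not
  reproducible from counts alone (patient-level data are not public), so
  survival correctness is established by parameter recovery on synthetic
  cohorts, not by reproducing published medians.
* The monitor adjudicates confirmed responses only; trials that pool
  unconfirmed responses at interims will stop differently (a
  configuration hook exists at the BOR level via `derive_bor()`'s
  thresholds, not at the monitor).
* Operating characteristics assume evaluable-patient looks in adjudication
  order and independence across patients; accrual-rate effects on
  information timing are visible only through the simulator.
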