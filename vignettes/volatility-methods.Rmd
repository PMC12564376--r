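---
title: "Modelling within-session volatility in exposure-therapy signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling within-session volatility in exposure-therapy signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vretvol)
```

## The problem

Virtual-reality exposure therapy (VRET) sessions yield continuous
physiological and behavioural signals — heart rate, head-pose angular
velocity, time-on-task — whose *variance* is itself dynamic: arousal
arrives in bursts, and how quickly those bursts settle is informative
about habituation in a way session means are not. `vretvol` provides the
measurement layer (AR(p)–GARCH(1,1) conditional-variance models plus a
diagnostic battery), the control layer (a deterministic micro-relaxation
controller), the cohort-level outcome statistics, and a synthetic-cohort
generator that stands in for raw recordings, which are typically not
shareable.

## Model and estimation

The per-session signal is modelled as

$$Z_t = c + \alpha_1 Z_{t-1} + \dots + \alpha_p Z_{t-p} + \tau_t, \qquad
\tau_t = \sigma_t \epsilon_t, \quad \epsilon_t \sim \mathrm{IID}(0,1),$$
$$\sigma^2_t = \delta + \beta \tau^2_{t-1} + \gamma \sigma^2_{t-1},
\qquad \delta > 0,\ \beta, \gamma \ge 0 .$$

Estimation is **two-stage**: the AR mean model by conditional least
squares (`fit_ar()`, order by BIC via `select_ar_order()`), then Gaussian
quasi-maximum likelihood of the GARCH(1,1) recursion on the AR residuals
(`fit_ar_garch()`). The two-stage sequence mirrors the analysis workflow
the package implements (AR first, ARCH-LM on AR residuals, variance model
only when heteroskedasticity is indicated) and keeps each stage
individually testable. QMLE means the Gaussian likelihood is maximised
even if innovations are heavy-tailed; the estimator remains consistent
for the variance-equation parameters.

Numerical choices, all deterministic:

- Parameters are optimised on a transformed scale ($\delta = e^a$,
  persistence $\rho = 0.999\,\mathrm{logit}^{-1}(b)$ split between
  $\beta$ and $\gamma$ by a second logistic), which enforces
  $\delta > 0$, $\beta, \gamma \ge 0$, $\beta + \gamma \le 0.999$ without
  boundary failures.
- Nelder–Mead from two fixed starts — a volatile start
  ($\beta = 0.05, \gamma = 0.85$) and a near-homoskedastic one — with
  relative tolerance `1e-8` and at most 500 iterations; the better
  optimum wins. If the nested homoskedastic point
  ($\delta = s^2, \beta = \gamma = 0$) beats both, it is returned, so the
  fitted likelihood never falls below the constant-variance model it
  nests.
- The variance recursion is initialised at the unconditional variance
  $\delta/(1-\beta-\gamma)$ (the residual mean square when persistence
  $\ge 1$); the recursion itself is evaluated with a vectorised linear
  recursive filter.
- `constrained = FALSE` switches to unconstrained QMLE with a warning.
  This mode exists because published variance equations for this kind of
  data sometimes report negative ARCH coefficients or lag-variance
  coefficients above one — parameter sets the constrained recursion could
  never produce; the unconstrained mode lets such fits be reproduced and
  examined rather than silently clipped.

**Identifiability note.** Under homoskedastic data the likelihood is flat
along the ridge $\delta/(1-\gamma) = s^2$ when $\beta = 0$: $\beta$ and
the implied unconditional variance are pinned down, $\gamma$ alone is
not. Tests therefore check $\beta \to 0$ and the implied variance, never
$\gamma$ itself, in that regime.

### Volatility summaries

Persistence is $\beta + \gamma$; the half-life is
$\ln(0.5)/\ln(\beta+\gamma)$ for persistence in $(0,1)$ — the package's
closed form for the "steps until a variance shock halves" notion, chosen
because it is the standard geometric-decay solution of the variance
recursion. Persistence at or above one yields an infinite half-life; at
or below zero the half-life is reported as not applicable (`NA`), not an
error.

## Diagnostic battery

Skewness and kurtosis use the moment-ratio form with the $m-1$ divisor
and the sample standard deviation; kurtosis is on the raw scale with
normal reference 3. Jarque–Bera is $n S^2/6 + n(K-3)^2/24$ against
$\chi^2_2$; rejection indicates **non**-normality (the package reports
the standard interpretation). Durbin–Watson is
$\sum(\Delta e)^2/\sum e^2$ with the usual `<2` / `>2` band labels.
ARCH-LM is $n R^2$ from the auxiliary regression of squared residuals on
their own lags (default 5 lags — the lag order is a convention, so it is
configurable); Ljung–Box is applied to squared standardised residuals at
the same lag. The augmented Dickey–Fuller test (constant, AIC-chosen
augmentation) interpolates the Dickey–Fuller $\tau_\mu$ quantile table in
both sample size and probability; p-values outside the tabulated range
clamp to 0.01/0.99.

Information criteria are computed in **two forms**: the published-table
forms (`sic = -2\ell + T + T\ln M`, `hqc = -2\ell + 2(T + T\ln M)`) and
the textbook forms (`bic = -2\ell + T\ln M`,
`hqc = -2\ell + 2T\ln\ln M`). The published forms are nonstandard but are
the defaults for reproducing table layouts; order selection uses the
textbook forms. Per-observation variants (raw / $M$) are returned because
the published tables report on that scale (values ~5–7 for
log-likelihoods near −150 at $M = 55$).

Forecast scores are in-sample one-step: MAE, MAPE (percent, undefined
when an actual is zero), RMSE, and Theil's U implemented as the bounded
$U_1 = \mathrm{RMSE}/(\sqrt{\overline{g^2}} + \sqrt{\overline{Z^2}})$,
which satisfies $0 \le U \le 1$ with 0 exactly at a perfect fit; the
unnormalised ratio is available behind `u_variant = "raw_ratio"`.

## The adaptive controller

`run_session()` replays, per second, the micro-relaxation rule over the
exposure segment of a trace:

| parameter | default | meaning |
|---|---|---|
| `hr_z_threshold`, `hr_sustain_s` | +1.0, 10 s | heart-rate trigger |
| `hmv_z_threshold`, `hmv_sustain_s` | +1.0, 5 s | head-movement trigger |
| `prompt_duration_s` | 30 s (allowed 30–45) | breathing prompt |
| `trigger_count_hold`, `trigger_window_s` | 3, 300 s | hold rule |
| `quiescence_stepup_s` | 300 s | step-up rule |
| `hr_hard_ceiling_bpm` | 120 bpm | relaxation-scene switch |

Heart rate is smoothed by a 5-s trailing median and z-scored to the
pre-exposure baseline; head-movement variability is the 5-s trailing
rolling SD of head-pose velocity, z-scored to its distribution over the
first two minutes. Windows are trailing, and the first `window − 1`
samples reuse the partial window, so series lengths are preserved.

Decisions where the rule statement leaves room, fixed as package
defaults:

- Sustain counters reset the moment z drops below threshold: a 9-s
  excursion never fires the 10-s rule.
- During a prompt, threshold evaluation is suspended (prevents re-trigger
  storms) and resumes at prompt end; a hold lasts until the end of the
  block.
- The 120-bpm ceiling is tested on the **raw** signal (fastest possible
  reaction); exit from the relaxation scene requires the smoothed heart
  rate below the ceiling for 30 consecutive seconds. Trigger evaluation
  and the quiescence clock pause inside the relaxation scene, and
  accumulated triggers persist across a scene switch.
- Simultaneous heart-rate and head-movement triggers in the same second
  log as one trigger with both causes.

The controller is a pure function of (trace, config): identical inputs
give identical logs, and the final difficulty always equals the starting
level plus the number of step-up events.

## Outcome statistics

Paired pre/post comparisons use the standard paired t-test with the
paired-design effect size $d_z = t/\sqrt{n}$. That convention (rather
than a pooled-SD $d$) is used because it reproduces published
effect-size tables exactly from their printed $t$ and $n$ — e.g.
$41.40/\sqrt{55} = 5.58$. Percent reduction is
$100(\bar{x}_{pre} - \bar{x}_{post})/\bar{x}_{pre}$. Fear-severity
strata partition scores at 40/50/80 (below 40 is the operational
exclusion threshold). Two-sided p-values, no multiplicity correction by
default (`stats::p.adjust` composes trivially if wanted).
Post-session-questionnaire scoring keeps the two 0–100 anxiety items
separate from the 1–7 Likert domains, reverse-codes the nausea item T2
as $8 - x$, and gates step-up readiness on readiness $\ge 5$,
tolerability $\ge 5$ and no adverse event.

## Model-utility benchmarking

`fit_gain()` implements the preconditioned sequence: GARCH is fitted only
when ARCH-LM on the AR residuals is significant at 0.05 (or on request),
and reports $\Delta\mathrm{AIC} = \mathrm{AIC}_{AR} -
\mathrm{AIC}_{AR\text{-}GARCH}$ (positive favours the variance model)
plus whether Ljung–Box on squared standardised residuals has become
non-significant. Volatility proxies need no time-series model: trailing
rolling SD, or EWMA variance with decay $\lambda = 1 - 2/(w+1)$ so the
effective memory matches a $w$-second window (30–60 s intended).

Incremental validity uses **participant-level nested linear models**
fitted by maximum likelihood — outcome ~ session means, then + volatility
metrics — with the LR statistic, $\Delta$AIC and $\Delta R^2$. Nested
`lm`s were chosen over mixed-effects models because the inferential
target (do volatility metrics add predictive information beyond means?)
is identical, while a mixed model would require a random-effects
structure the analysis plan does not pin down; the interface leaves room
for a random-intercept extension. The outcome variable is by convention
the pre–post fear-score change.

## The synthetic cohort: what it emulates, what it does not

The generator's defaults are the study conditions: 55 participants,
seven sessions, severity strata of 18/24/13 with the published pre/post
score targets, and per-session mean/SD targets for time-on-task
(rising 56.56 → 97.33 s), head movement (falling 171.47 → 135.93) and
heart rate (falling 118.31 → 86.62 bpm). Session traces are sampled at
1 Hz (the controller is checked each second; the sensor rate is a
configuration knob), 600 s long by default (an arbitrary but fixed
choice; the source material never states trace lengths), with a 120-s
resting baseline (HR ≈ 72 bpm) so controller baselining is exercisable,
and exposure-phase innovations from the AR–GARCH recursion
(defaults: AR(1) with coefficient 0.6, $\delta = 0.4$, $\beta = 0.1$,
$\gamma = 0.8$, persistence 0.9, unconditional innovation variance
4 bpm²). Innovations are Gaussian by default, matching the QMLE
assumption; a scaled-t option exists for leptokurtosis experiments.
Time-on-task is generated at session level only, since it is reported as
a per-session scalar.

Two deliberate fidelity notes. First, the published record is internally
inconsistent about the direction of the time trend (a summary claims
completion time fell, the printed per-session means rise); the generator
follows the printed per-session trajectory and exposes the direction
through the target table rather than resolving the contradiction.
Second, pre/post fear scores are drawn **independently** within stratum,
because only marginal means and SDs are published; real pre/post scores
are strongly correlated, so synthetic paired t statistics are honest but
much smaller than published ones. Passing tests therefore demonstrate
that the machinery is correct under its stated generating model — not
that real exposure data have these properties: real signals have
circadian drift, motion artefacts, sensor dropout and non-Gaussian
tails that the generator does not emulate.

## Problem sizes and reproducibility

The test-suite and acceptance computations use the sizes at which their
statistical claims are stated: 20 replicates of length 3000 for GARCH
parameter recovery (median absolute persistence error below 0.05), 1000
Gaussian-null replicates for the type-I-error calibration of ARCH-LM,
Jarque–Bera and Ljung–Box (rates within 0.05 ± 0.02), n = 50,000 for the
closed-form unconditional-variance check (within three Monte-Carlo
standard errors, with the autocorrelation of squared GARCH innovations
inflating the plain iid standard error), and 500 replicates at n = 200
for the incremental-validity calibration. Every stochastic computation
derives from an explicit seed; fit and replay functions are
deterministic given their inputs.

## Known limitations

- Only GARCH(1,1) is fitted; higher-order GARCH(p,q) and asymmetric
  variants (EGARCH/GJR) are out of scope.
- The ADF p-value is table-interpolated, hence clamped at 0.01/0.99.
- The two-stage estimator forgoes the (small) efficiency gain of joint
  mean-variance QMLE.
- Cohort-level published tables cannot be reproduced numerically without
  the raw recordings; the package reproduces their *pipeline* and the
  printed-summary arithmetic instead.
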