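---
title: "PBRTQC methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PBRTQC methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbrtqc)
```

## The monitoring model

Patient-based real-time quality control treats the time-ordered stream of
patient results for one analyte as its own quality-control material. After
excluding results outside a truncation range, the accepted values $x_t$
feed an exponentially weighted moving average,

$$ q_t = \lambda x_t + (1-\lambda)\, q_{t-1}, \qquad q_0 = \bar x_{\text{train}}, \qquad 0 < \lambda < 1, $$

whose smoothing suppresses patient-to-patient biological scatter while
accumulating persistent analytical bias. The chart's assumptions are worth
stating plainly: accepted results are exchangeable in the absence of
analytical error (no strong time-of-day or case-mix structure), the
training window is error-free, and error manifests as a change in location
or spread of the measurand — not, say, as a change in the patient
population.

Control limits come from the training window only:
$\text{sd}_{\text{EWMA}} = s_{\text{train}}\sqrt{\lambda/(2-\lambda)}$,
with warning and action limits at $k_{\text{warn}} = 2$ and
$k_{\text{action}} = 3$ chart SDs. We default to the asymptotic SD rather
than the exact time-varying factor $\sqrt{1-(1-\lambda)^{2t}}$; the two
differ only over the first $\approx 3/\lambda$ accepted samples and
`exact_factor()` exposes the exact correction for anyone monitoring very
short streams. Validation data never update the limits: a drifting
instrument must not be allowed to recalibrate its own chart.

## Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| $\lambda$ | — | grid $\{0.02, 0.03, 0.05\}$ | the deployment-relevant memory range: $1/\lambda \approx$ 20–50 samples. Smaller $\lambda$ detects smaller bias but reacts (and recovers) more slowly |
| $k_{\text{warn}}, k_{\text{action}}$ | chart SDs | 2, 3 | classic Shewhart-style bands; the action band drives scoring |
| $k_\sigma$ (Box-Cox arm) | transformed-space SDs | 3 | $\approx$ 99.7% central coverage once the transform has normalised the data |
| $k_{bv}$ (biological-variation arm) | — | 2 | half-width $= k_{bv}\cdot\text{median}\cdot\sqrt{CV_i^2+CV_g^2}/100$; two group SDs of the combined biological variation |
| CV$_i$, CV$_g$ | % | per analyte | from the biological-variation literature; CV$_g$ may be missing (some immunoassays), in which case the half-width degrades to CV$_i$ alone |

## Truncation

**Box-Cox arm ("traditional").** The exponent is fitted by profile maximum
likelihood on a dense grid over $[-2, 2]$ (step 0.01) with local
refinement; the profile log-likelihood is
$-\tfrac{n}{2}\log\hat\sigma^2(y_\lambda) + (\lambda-1)\sum\log x$. Bounds
are mean $\pm k_\sigma$ SD *in transformed space*, back-transformed and
intersected with the observed range. Whether published truncation ranges
were central coverage in raw or transformed space is generally unstated; we
fix transformed space (that is where the normality argument lives) and
expose $k_\sigma$. The in-transform SD uses the MLE $1/n$ denominator so
the bounds are invariant to duplicating the data set. Non-positive values
are shifted by $\varepsilon - \min$ with $\varepsilon = 10^{-6}\cdot$range
before the transform, and the shift is inverted afterwards. When a
back-transformed bound leaves the transform's domain
($\lambda y + 1 \le 0$) it falls back to the observed extreme.

**Biological-variation arm ("bv_heuristic").** A documented heuristic
standing in for proprietary AI range selection: centre on the median,
half-width from the combined biological variation, clipped to the
0.5th–99.5th data percentiles so the range never extends far beyond
observed results. It is *not* a reconstruction of any vendor algorithm and
is labelled accordingly throughout.

Truncated-out results are **excluded, not winsorised** — the failure mode
this reproduces is real: a large step bias can push results outside the
truncation range so that truncation eats the very signal the chart should
see. Errors in the simulator therefore act on the measurand value before
truncation.

## Alarms and scoring

The limit chart yields warning/action states; Westgard multirules (1-2S
warning; 1-3S, 2-2S, R-4S, 10-X rejection) can additionally run on the
EWMA z-series. R-4S is interpreted as a consecutive-pair range rule, since
patient streams have no within-run duplicate structure. Note that on a
heavily autocorrelated EWMA series the 10-X run rule fires constantly even
in control — it is provided for completeness and for z-scored IQC series,
and is off by default for PBRTQC monitoring (`rules_enabled =
"limit_chart"`).

Scoring joins the alarm log to ground-truth risk windows (half-open
$[\text{onset}, \text{closure})$; overlapping windows' union is the
positive region, the earliest onset claiming shared samples):

* **Ped** — percentage of events with at least one qualifying alarm inside
  their window (event-level sensitivity); **FNR** $= 100 -$ Ped by
  construction.
* **FPR** — percentage of negative accepted samples that are alarmed
  (sample-level).
* **ANPed** — accepted samples from onset up to and including the first
  alarmed sample, averaged over detected events; an alarm on the very
  first in-window sample scores 1; undefined (rendered "-") when nothing
  was detected.
* **AUC** — threshold sweep of the limit multiplier $k$ over the score
  $|q - \text{center}|/\text{sd}_{\text{EWMA}}$ (grid 0–6 by 0.05, or the
  exact empirical curve with `thresholds = NULL`), trapezoid area with
  (0,0) and (1,1) appended.

By default only **action-level** alarms count toward Ped/FPR/ANPed. Source
platforms often count "warning or out of control" alike; that reading is
available via `level = "warning"`. We default to action-only because a
2-SD warning band alone flags $\approx 4.6\%$ of in-control samples, which
is irreconcilable with the standard FPR $< 5\%$ acceptability bound the
selection filter itself applies — warnings are treated as watch states, not
rejections.

The optimal model per analyte is the maximum-AUC survivor of Ped $> 90$,
FPR $< 5$ (both strict), ties broken toward smaller $\lambda$ (the cheaper,
more bias-sensitive setting); with no survivor the best-AUC model is
reported but flagged `meets_criteria = FALSE`.

## The simulator: what it emulates and what it does not

Patient results are generated as lognormal subject levels (between-subject
CV$_g$) times lognormal within-subject-plus-analytical noise
($\sqrt{CV_i^2 + CV_a^2}$), so the stream median equals the specified
median exactly and the distribution is right-skewed like most clinical
analytes; arrivals are a Poisson process. Defaults used by the power and
null studies: median 100, CV$_i$ = CV$_g$ = 7%, CV$_a = \sqrt 2$% — a
round 10% total CV with biological variation dominating analytical, as is
typical — at 100 results/day for 50 days ($\approx$ 5000 samples), the
first half training. Error injection covers step bias (calibration shift),
drift (reagent deterioration; bias grows per 100 in-window samples) and
imprecision inflation (deviations from the baseline median rescaled).
Every stream requires an explicit seed and restores the caller's RNG
state.

What a green simulation test does **not** establish: the generator has no
case-mix or seasonal drift, no duty-cycle structure in arrivals, no
pre-analytical artefacts, and its outlier model (a uniform fraction over
$[\text{median}/5,\, 5\cdot\text{median}]$) is deliberately crude. Passing
power properties on this stated world says the chart logic is correct, not
that any particular laboratory will see Ped $> 90\%$.

Three generator scales in the Box-Cox recovery tests were chosen once for
identifiability and then frozen: lognormal$(0, 0.4)$ for exponent 0,
$(0.5y+1)^2$ with $y \sim N(4,1)$ for 0.5, and $N(20,4)$ for 1. The
exponent is poorly identified when the coefficient of variation is small
(a near-constant positive variable looks equally normal under any power),
so a low-CV generator would test sampling noise, not the estimator.

## Numerical choices and degenerate inputs

* EWMA via a recursive linear filter; exact to the plain recursion at
  machine precision (tested to $10^{-12}$ relative).
* Box-Cox refuses fewer than 20 distinct values or zero variance;
  `boxcox_transform` is continuous in the exponent at 0 (switches to
  $\log$ below $10^{-12}$).
* Westgard inequalities are strict (e.g. 2-2S needs both $z > 2$); zero is
  on neither side of the mean for 10-X, so it breaks a run.
* Ties in timestamps preserve file order (stable sort); parsing is
  locale-independent (ISO-8601, decimal point, UTC).
* Empty alarm logs, zero-event registers (Ped undefined, reported `NA`),
  and single-class label vectors (AUC refused) are all first-class cases.
* Reports render an undefined ANPed as `-` in CSV, `null` in JSON.

## Known limitations

* Only the EWMA statistic is implemented (no moving median / moving SD /
  moving outlier-sum variants).
* The biological-variation truncation arm is a heuristic, not a
  reconstruction of any proprietary selector; comparisons between arms on
  real data should be read with that in mind.
* ANPed counts accepted samples, so its scale depends on the truncation
  range when errors push results out of range.
* No plotting layer; traces and alarm logs are returned as plain data for
  the user's tooling.
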