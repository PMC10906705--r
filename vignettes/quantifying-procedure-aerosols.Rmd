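---
title: "Quantifying aerosol and droplet generation during clinical procedures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying aerosol and droplet generation during clinical procedures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aerosolwatch)
```

## The measurement problem

Upper-GI procedures such as esophagogastroduodenoscopy (EGD) generate
respiratory aerosols (particles ≤ 5 µm diameter, which stay airborne for
hours and reach the lower airways) and droplets (> 5 µm, which settle
quickly and contaminate surfaces). Both are transmission routes for
respiratory viruses, so quantifying how much a candidate replacement
procedure — here the capsule-sponge ("Cytosponge") test — produces relative
to EGD matters for infection control.

The instrument is an optical particle counter sampling near the patient's
mouth at 100 L/min, reporting counts in six diameter channels (0.5–0.7,
0.7–1.0, 1.0–3.0, 3.0–5.0, 5.0–10.0, 10.0–25.0 µm) averaged over 7-second
intervals. Two analyses are supported:

* **Whole-procedure**: total particle production over the procedure,
  duration-normalised to a 20-minute equivalent and compared between arms
  and against each patient's own pre-procedure reference window.
* **Event-based**: excess particles attributable to individual annotated
  events (device insertion/removal, endoscope intubation/extubation,
  anesthetic throat spray, burping — defined to include coughs and gags),
  compared against "null reference" pseudo-events placed where nothing
  happens.

## Statistical model

### Whole-procedure comparisons

Particle count totals are modelled as log-normal, following standard models
of respiratory aerosol emission. Comparisons are therefore Welch
(unequal-variance) two-sample t-tests on log-transformed 20-minute-equivalent
counts; the reported fold change is the geometric-mean ratio
$\exp(\overline{\log a} - \overline{\log b})$ with the exponentiated Welch
95% interval. The within-patient comparison pairs each procedure window with
its own 5-minute pre-procedure reference window and applies a paired t-test
to the log differences.

Zero totals are handled by a +1 pseudocount applied identically to both
groups (configurable). Welch rather than pooled variance is used because
the arms have unequal sizes and no variance-equality assumption is
defensible. The confidence level is fixed at 95% and p-values are reported
raw, without multiple-testing correction, matching how such studies are
conventionally reported.

Room background drifts slowly (ventilation, passers-by, continuous patient
respiration). The *spike* variant therefore subtracts a running median
(default kernel 11 samples ≈ 77 s; shrinking windows at the recording
edges, so no counts are fabricated) and sums only the positive residuals.
The kernel is long relative to seconds-scale events but short relative to
background drift; it is configurable because no single value is canonical.
The filter runs on the aggregated aerosol/droplet series; filtering per
channel before aggregation is available via the same function applied
upstream.

### Event excess and the mixture model

The excess attributable to an event at time $t$ is the count sum over
$[t, t + 21\,\mathrm{s})$ (three intervals — events last seconds but the
counter's 7-s averaging smears them) minus the expected background over the
same span, estimated as the median per-interval count over the preceding 70
seconds. Background subtraction makes excesses signed; the population of
excesses is modelled as a two-component mixture
$w \cdot \mathrm{LogNormal}(\mu_L, \sigma_L) + (1-w) \cdot
\mathcal{N}(\mu_N, \sigma_N)$: genuine bursts are positive and roughly
log-normal, subtraction noise is roughly normal. The fit is by EM with
multiple starts, including responsibility-based starts that seed the
log-normal component with the positive samples; because the mixture nests
both single-component models and plain maximum likelihood will happily
spend a small weight chasing sampling noise (or find label-switched
optima), the fitted mixture is compared by BIC against the pure log-normal
and pure normal fits and the parsimonious winner is reported.

Event-level fold changes are ratios of mean *positive* excess (excesses can
be ≤ 0, so geometric means are unavailable; means of the positive part are
the headline statistic, with plain means and medians available as
alternatives). Inference is a percentile bootstrap over events (default
10,000 resamples); the two-sided p-value is the proportion of bootstrap
ratios crossing 1 with a $+1/(n_\mathrm{boot}+1)$ continuity correction, so
p is never exactly zero. Both the numerator and denominator statistics are
floored at a small positive value so a resampled group with no positive
excess cannot produce an infinite or zero ratio; floored comparisons are
flagged.

Null-reference events are drawn uniformly without replacement from interval
starts at least 60 s from every annotation and from each other, with the
additional constraint that the baseline-plus-event span must not straddle a
supplied "avoid" time. The pipeline passes the procedure start and end as
avoid times: activity levels step there, and a null window spanning the
step would measure the step, not quiet background.

### Cohort statistics

Discrete cohort variables are compared with Fisher's exact test, computed
in-package by log-space hypergeometric summation under the conventional
minimum-likelihood two-sided rule (all tables with point probability not
exceeding the observed one). Continuous variables use the same Welch t-test
exposed as `welch_t()`. Cohort summaries for age and BMI published as
range/median only are not reproducible as p-values from summaries alone;
the functions operate on full per-patient data.

## The synthetic-data generator

Real recordings from the motivating study are deposited externally; the
package instead validates every stage against synthetic studies whose
ground truth is known. The generator emulates:

* **Cohort design**: 37 EGD and 18 capsule-sponge procedures by default,
  with log-normal procedure durations around per-arm means of 7.2 and 8.1
  minutes (CV 0.25, floored at 5 minutes), a ≥ 5-minute pre-procedure
  recording margin (default 6 minutes), sedation assignment (all EGD
  receive throat spray, 16/37 with midazolam; 22% of capsule-sponge
  patients receive spray), and demographics drawn to match the published
  cohort's ranges and proportions.
* **Room background**: a first-order autoregressive process on log total
  intensity (coefficient 0.9, innovation SD 0.05 per 7-s interval,
  optional linear drift), initialised at stationarity — the simplest
  strictly positive process that is "slowly varying". Intensity is split
  across the six channels by a decreasing power-law weight vector
  ($k^{-1.5}$, most particles are small; the real channel-level
  distribution is unpublished, so nothing downstream depends on the
  specific weights) and rounded deterministically to integer counts.
* **In-procedure emission**: each patient adds a constant per-interval
  emission during the procedure window, log-normal across patients
  (geometric means 600 aerosol / 60 droplet counts per interval for the
  capsule-sponge arm, between-patient log-SD 0.6). The EGD arm's emission
  is multiplied by the configured true fold difference (default 2.16
  aerosol, 1.0 droplet). Emission is constant within a procedure, so the
  local-median baseline removes it exactly in event windows and the null
  noise level during procedures matches the background-only level.
* **Events**: scheduled per arm (insertion/intubation ~2–3 minutes after
  the procedure start, removal/extubation shortly before the end, spray
  before insertion, burps Poisson at the published per-arm rates of 1.97
  and 1.46 per 20 minutes), each adding a log-normally distributed
  amplitude decayed geometrically over 3 intervals. Scheduled events sit at
  least 75 s after the procedure start so their 70-s baselines are
  homogeneous, and at least 35 s apart — longer than an analysis window
  plus the decay span — so one event's activity cannot contaminate
  another's excess measurement and each configured ratio remains a clean
  per-event truth. (Real recordings offer no such guarantee; overlapping
  events there are attributed to whichever annotation's window captures
  them.)

A deliberate design point: configured event strengths are *fold ratios over
the null level*, the same scale on which results are reported. The expected
null positive excess is an emergent property of the background process, so
`synthetic_config()` calibrates it once by an internal seeded Monte Carlo
(`expected_null_excess()`): procedure-shaped recordings are simulated
(background plus constant emission, scheduled annotations, no spike
amplitudes) and the analysis-side null-sampling protocol is run on them, so
the calibrated level is the expectation of exactly the statistic the event
analysis uses as its denominator. Each event's mean amplitude is then set
to `(ratio − 1) × null level`: the measured excess of an event is its
amplitude plus the same subtraction noise whose positive part defines the
null level, so this convention makes the expected measured event excess
`ratio × null level` — exact at ratio 1 (nothing is injected) and
asymptotically exact for strong events. A configured removal ratio of 14.6
is then a true parameter of the quantity the estimator targets. Event
amplitude variability is log-SD 1.0 — order-of-magnitude spread between
repetitions of the same event type, consistent with the very wide intervals
such studies report.

What the generator does **not** emulate: counting (shot) noise beyond
deterministic rounding, coincidence losses, within-procedure emission
dynamics, aerosol transport physics (evaporation, deposition, ventilation),
room-to-room differences, or operator technique. Passing tests therefore
demonstrate that the estimators recover the truth under the assumed
log-normal/AR model, not that the model captures every feature of real
recordings.

### Recovery bias worth knowing about

Raw whole-procedure totals include the room background, so the recovered
arm ratio is attenuated toward 1 by roughly
$(\mathrm{bg} + e \cdot r)/(\mathrm{bg} + e)$ relative to the configured
emission ratio $r$. At the default background (~46 aerosol counts/interval)
against emission (~600/interval) the attenuation is ≈ 4%, well inside the
15% recovery tolerance the tests assert. Similarly, the mean-positive
statistic for events is upward-biased by the noise floor for weak events;
for the strong events that drive conclusions the bias is a few percent.

## Numerical and implementation choices

* Running medians use `stats::runmed` for interior points with explicit
  shrinking windows at the edges; equivalence with a brute-force sliding
  median is asserted over random series in the test suite.
* Exact-test probabilities are evaluated with `lchoose` in log space; ties
  in the minimum-likelihood rule are accepted within a relative tolerance
  of $10^{-7}$ to absorb rounding.
* EM convergence is declared when the log-likelihood improves by < 1e-8;
  the trace is retained and its monotonicity asserted on every fit.
  Component scales are floored at $10^{-4}$ times the sample SD to prevent
  point-mass collapse.
* Degenerate inputs: constant groups (zero variance on the log scale)
  short-circuit the t machinery (p = 1 for equal means); all-non-positive
  excess samples return a flagged degenerate fit with zero log-normal
  weight; bootstrap denominators are floored and flagged.
* All stochastic steps consume an explicitly seeded RNG stream
  (`withr::with_seed`); `run_study()` wraps the whole analysis in one
  stream, so a rerun with the same seed is bit-identical.

## Problem sizes used in the validation suite

The test suite calibrates type-I error over 1000 replicate null studies at
reduced cohort size (10 + 10) and checks parameter recovery over 200
replicate studies at the full default design (37 + 18), with 1000 bootstrap
resamples per event comparison inside simulation loops (the
user-facing default remains 10,000). These sizes give Monte-Carlo standard
errors comfortably inside the asserted bands while keeping the suite quick
to run.

## Worked example

```{r example, eval = FALSE}
library(aerosolwatch)

cfg <- synthetic_config(seed = 42)
study <- generate_study(cfg, dir = "study_dir")   # or keep in memory
res <- run_study(study, seed = 43)

res$comparisons      # every fold change with CI, p, n
res$cohort           # demographics table with exact/Welch p-values
glance(res$mixture$aerosol)

plot_comparisons(res)
autoplot(aggregate_size_fractions(study$procedures[[1]]$frame),
         annotations = study$procedures[[1]]$record$annotations)
```

## Known limitations

* The event-level fold change is a ratio of means of positive parts; the
  statistic actually bootstrapped in comparable published analyses is not
  always stated, so medians and plain means are provided as alternatives
  behind the `stat` argument.
* Percentile bootstrap intervals undercover slightly for heavy-tailed
  amplitude distributions at small event counts; the recovery tests
  quantify this under the generator's assumptions.
* No covariate adjustment (age, BMI, smoking) or mixed-effects structure is
  provided; comparisons are marginal.
* Cumulative-format instrument exports are supported by differencing on
  read, but proprietary binary formats and live streaming are out of scope.
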