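---
title: "Suction events and heart-rate responses: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Suction events and heart-rate responses: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neosuction)
```

## The problem

During delivery-room resuscitation of newborns, providers frequently
suction the mouth and nose with a bulb device or catheter, although
guidelines recommend suctioning only for an obstructed airway. Suctioning
can stimulate the posterior pharynx and provoke vagally mediated
bradycardia or arrhythmia, and it interrupts ventilation. This package
implements a reproducible pipeline for quantifying that phenomenon from
delivery-room recordings: typed annotation timelines (suction insertions,
ventilation bouts, stimulation, covering), a ~1 Hz heart-rate stream
derived from dry-electrode ECG, and optionally a beat-time series.

The raw observational data this kind of analysis is performed on cannot be
shared, so the package pairs the analysis pipeline with a synthetic-cohort
generator that plants known responses, letting every stage be validated
against ground truth.

## Event model and classification rules

**Suction events.** A suction event (SE) is a maximal run of suction
insertions in which no pause between consecutive insertions exceeds 5 s
(`max_pause_s`); a pause strictly greater than 5 s starts a new SE. Pauses
are measured stop-to-start, i.e. idle time. All intervals are half-open
`[start, stop)` in seconds since birth, so an event ending at *t* and one
starting at *t* do not overlap. Suction annotations are analysed within a
420 s window after birth (`analysis_window_s`); an SE straddling the
boundary is truncated rather than dropped, since the annotation covers the
window.

**Pre/post heart rate.** The HR before (after) an SE is the median of the
five samples (`hr_samples_k`) nearest the SE boundary within 20 s
(`hr_window_s`). When more than five samples fall in the window, the five
nearest the boundary are used -- the most recent physiology. With fewer
than five but at least three (`min_hr_samples`), the median of those is
used; below three the value is missing and, absent an arrhythmia, the SE
is `INDETERMINATE`.

**Response classification** (fixed precedence):

1. Pre- or post-SE HR missing, no arrhythmia detectable: `INDETERMINATE`.
2. A ventilation bout ended at most 5 s (`vent_cessation_gap_s`) before SE
   start **and** HR fell by strictly more than 30 bpm
   (`vent_cessation_fall_bpm`, absolute, vs the pre-SE HR) during the SE
   or within 20 s after: `VENT_CESSATION_FALL`. Such falls are attributed
   to interrupting positive-pressure ventilation, not to suctioning, which
   is why this check precedes the suction-related ones.
3. Bigeminy in the beat series overlapping `[start, stop + 20 s]`:
   `SUCTION_RELATED_ARRHYTHMIA`. Bigeminy is a run of at least 8 beats
   with strictly alternating short/long RR intervals at a long/short ratio
   of at least 1.5 on every adjacent pair; it is the only arrhythmia
   pattern detected, the one relevant to this setting.
4. A fall strictly greater than 15% (`fall_fraction`) of the pre-SE HR,
   sustained for at least 2 consecutive samples (`fall_min_samples`),
   during the SE or within 20 s after, with no ventilation interval
   overlapping the excursion itself: `SUCTION_RELATED_FALL`.
5. Otherwise `NO_CHANGE`.

The "brief/sustained" qualifier of the fall rule is operationalized as the
`fall_min_samples` persistence requirement: at ~1 Hz sampling, a single
sub-threshold sample is indistinguishable from sensor noise. The 15% rule
is relative and the ventilation-cessation rule absolute (in bpm), exactly
as each criterion is conventionally stated; both use the same persistence
rule, a package choice since manual review has no persistence convention.
All thresholds live in one `analysis_config()` object with the defaults
above; every operation takes the configuration explicitly so sensitivity
analyses can vary any cutoff.

**Inter-annotator agreement** is the fraction of the episode during which
two annotators' active label sets (by event kind) are identical, with
jointly idle time counting as agreement; a pair scoring below 0.80
(`agreement_threshold`) is flagged for consensus review. An agreement
protocol can also be stated per event rather than per unit time; the
time-based metric is the one computable from interval data alone and is
what the package implements.

**Complete-data restriction.** Episodes whose SE responses are all
`INDETERMINATE` (no usable HR coverage) are excluded from the analysis set
and logged, mirroring how incomplete monitor recordings are handled in
practice.

## Statistical layer

* Descriptives with repeated observations per newborn first reduce each
  newborn to the mean of its own values (`summarize_repeated()`), so
  babies with many SEs do not dominate. Quartiles use the
  linear-interpolation (type 7) convention; printed quartiles depend on
  this choice, so it is fixed and documented.
* The one-sample Wilcoxon signed-rank test discards zeros, uses the exact
  signed-rank distribution for n <= 20 without ties, and otherwise the
  normal approximation with midranks, tie correction and continuity
  correction.
* 2x2 mortality comparisons use Pearson's chi-square **without** the Yates
  continuity correction: on the canonical tables `[[9,5],[11,29]]` and
  `[[5,2],[15,32]]` this variant reproduces p = 0.014 and p = 0.043 to
  three decimals, while the corrected variant does not, which pins down
  the test choice.
* Continuous predictors of a suction-related change enter a three-knot
  restricted cubic spline logistic model. The basis is the truncated-power
  construction scaled by `(t3 - t1)^2`, linear beyond the outer knots;
  knots default to the 0.10/0.50/0.90 empirical quantiles, the common
  default placement. Nonlinearity is Wald-tested on the nonlinear
  coefficient; if p > 0.05 linearity is assumed and the odds ratio is
  reported per conventional unit (per 100 g birthweight, per 10 bpm first
  observed HR, per 10 s); otherwise the overall 2-df Wald p is reported
  and the effect is displayed as a predicted-probability curve.
* Because SEs repeat within newborns, covariances use the cluster sandwich
  estimator with small-sample factor G/(G-1) (G = newborns) and no
  residual-df adjustment; point estimates are ordinary IRLS and are
  unaffected by clustering. Confidence intervals use z = 1.96, the usual
  large-sample sandwich practice. The probability-curve band is computed
  on the logit scale by the delta method, so it always contains the point
  estimate and stays inside [0, 1].
* Perfect separation is detected (diverging coefficients / non-vanishing
  score) and raised as an explicit error rather than returned as a fit.

## The synthetic-cohort generator

`scenario_config()` defaults encode the study conditions the cohort should
emulate: 91% of newborns suctioned; 1-8 SEs per suctioned baby with median
2 (quartiles 1-4); lognormal SE duration with median 14 s (quartiles
~7-23); mean 3.6 insertions per SE; 22% of babies with at least one
catheter SE; a marginal per-SE suction-related-change rate of 12.6% (1 in
17 of them an arrhythmia); an 8.1% ventilation-cessation-fall rate; death
probabilities of 0.64 given at least one suction-related change and 0.28
otherwise; first observed HR lognormal with median 77 bpm fitted to
quartiles (55, 139); episode duration lognormal with median 390 s clamped
to [100, 1500] s.

Each episode's HR stream is a piecewise-linear recovery from the first
observed HR toward a plateau drawn from 120-170 bpm (reached within 2-5
min), plus Gaussian noise (sd 3 bpm, a dry-electrode-like noise floor) and
5% missing-at-random samples -- dropout being the dominant artifact of
dry-electrode ECG and the feature that exercises the minimum-sample rules.
Planted responses are inserted as:

* **suction-related fall**: a dip of 25% of the pre-SE level
  (`planted_fall_fraction`) starting just inside the SE, holding ~10 s and
  recovering within 40 s, with no ventilation overlapping the dip;
* **ventilation-cessation fall**: a ventilation bout ending 1-4 s before
  SE start followed by a dip of at least 40 bpm (`planted_vent_fall_bpm`);
* **arrhythmia**: a bigeminy segment (alternating RR 0.32/0.62 s)
  replacing the normal beat train over the SE.

The per-SE change probability is not flat: it is modulated by an
inverted-U weight in the baseline HR at the SE, peaked at 135 bpm with
width 40 bpm, so that changes are most likely at pre-SE HR in the normal
range (~100-170 bpm) -- depressed newborns below 100 bpm and
catecholamine-stressed ones above 170 bpm are less reactive. The weight is
divided by a fixed normalization constant (`hr_effect_norm = 0.667`, a
design-time Monte Carlo estimate of the mean weight under the baseline
model) so the marginal change rate still equals
`p_suction_related_change`. Likewise `vent_cessation_norm = 0.666`
compensates for SEs that cannot host a ventilation-cessation fall
(unventilated babies, baselines too low to fall 30 bpm from).

Three structural choices keep the planted truth unambiguous:

* consecutive SEs are separated by at least 45 s, so each dip recovers
  before the next SE's pre-window opens;
* the baseline decline rate for babies whose first HR exceeds their
  plateau is capped at 0.15 bpm/s, so the trajectory itself can never
  satisfy the 15% fall rule within even the longest (90 s + 20 s)
  assessment window;
* ventilation bouts are placed clear of every planted fall excursion, and
  "prior ventilation" bouts end 8-18 s before an SE, exercising the prior
  flag without triggering the 5 s cessation rule.

Outcomes are drawn from the **truth** labels, never from detected labels,
so the downstream 2x2 mortality machinery can be validated against a known
association. Reproducibility: one master seed spawns one sub-seed per
newborn from a single stream, making any individual newborn bit-identical
across cohort sizes.

**What the generator does not emulate.** Ventilation waveform physics
(pressure/flow/CO2), Apgar and labor covariates beyond the screening set,
drift or bias in the HR sensor (only additive noise and dropout),
annotator label errors other than boundary jitter and missed events
(`generate_second_annotator()`), and clinical correlation between
covariates and suctioning practice (covariates other than the planted
HR dependence and mortality link are generated independently). Passing
recovery tests on this cohort therefore demonstrates the pipeline's rule
logic and statistics, not robustness to every artifact of real recordings.

## Validation problem sizes

The test-suite and acceptance checks run at sizes chosen to make binomial
bounds meaningful while staying desk-scale: noiseless and noisy recovery
on cohorts of 120 newborns (~250 SEs each, sensitivity 1.0 and zero false
positives without noise; both >= 0.95 with the default noise model),
merging versus a brute-force transitive-closure oracle on 1000 random
interval sets, exact-vs-approximate Wilcoxon agreement within 0.02 for
n = 15-20, rate calibration on 500-newborn cohorts at exact-binomial 99%
bounds, inverted-U recovery (curve argmax within 100-170 bpm) on a
250-newborn cohort, and type-I calibration of a null predictor over 50
replicate 60-newborn cohorts.

## Known limitations

* The classification implements the printed 20 s rule literally; a human
  reviewer may integrate context beyond 20 s.
* Whether the 11 "unrelated" (ventilation-cessation) SEs must also fail
  the 15% criterion is a protocol ambiguity; the package resolves it by
  precedence (cessation is checked first), one defensible reading.
* Arrhythmia detection is limited to RR-alternation bigeminy; general
  arrhythmia detection from ECG is out of scope.
* The agreement metric is time-based; an event-count-based metric would
  need a matching rule that interval data alone do not determine.
* The quantile (median) regression and robust log-linear models sometimes
  used for skewed descriptive comparisons are not reimplemented here; the
  descriptive layer provides the per-baby summaries those comparisons
  start from.
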