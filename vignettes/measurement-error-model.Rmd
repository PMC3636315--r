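---
title: "The measurement-error model behind web-based pure-tone audiometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The measurement-error model behind web-based pure-tone audiometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(webaudiometry)
```

## The problem

Self-administered pure-tone audiometry on an ordinary PC with consumer
headphones cannot rely on a laboratory calibration. Instead, a
normal-hearing "reference person" anchors the level scale at 1 kHz (the
resulting unit is dBRP-HL, decibels relative to the reference person's
hearing level), an A-weighting model extrapolates that anchor to the other
test frequencies, and the subject sets their own threshold with a 5 dB
volume slider. Every one of those steps adds measurement error. This
package implements the study design used to quantify those errors — three
threshold series on the same ears —

1. clinical audiometry (ascending method, calibrated audiometer),
2. a supervised self-test on one professionally calibrated station,
3. an unsupervised self-test at home on the subject's own hardware,

together with the agreement statistics comparing the series and the
variance algebra that decomposes the observed disagreement into named error
components.

## The additive error model

For ear $e$ with true threshold $T_e(f)$ at frequency $f$, the three series
observe

$$
\begin{aligned}
L^{(1)}_e(f) &= Q_5\!\left[T_e(f) + \varepsilon_{\mathrm{clin}}\right] \\
L^{(2)}_e(f) &= \max\!\left(0,\; Q_5\!\left[T_e(f) +
  \varepsilon_{\mathrm{proc}}\right]\right) \\
L^{(3)}_e(f) &= \max\!\left(0,\; Q_5\!\left[T_e(f) +
  \varepsilon_{\mathrm{proc}} + c_s + \nu_s(f) + g_s\right]\right)
\end{aligned}
$$

where $Q_5$ is round-half-up quantization to the 5 dB attenuator grid, the
$\max(0,\cdot)$ is the floor of the dBRP-HL scale, and for the home station
$s$: $c_s \sim N(0, \sigma_{pop}^2 + \sigma_{proc\_cal}^2)$ is the
calibration offset (reference person's true threshold plus the calibration
task's error), $\nu_s(f) \sim N(0, \sigma_{nonlin}^2(f))$ the frequency
nonlinearity (headphone RETSPL spread and sound-card response; identically
zero at the 1 kHz calibration frequency), and $g_s$ the gain error. All
components are independent, so between-series difference variances add:

$$
\operatorname{Var}(L^{(2)} - L^{(1)}) = \sigma_{clin}^2 + \sigma_{proc}^2,
\qquad
\operatorname{Var}(L^{(3)} - L^{(1)})\big|_{1\,\mathrm{kHz}}
 = \sigma_{clin}^2 + \sigma_{proc}^2 + \sigma_{cal}^2 .
$$

The supervised station's own calibration offset is shared by every subject
in series 2, so it shifts the mean difference, not the SD; the simulator
defaults it to 0.

## The decomposition chain

`decompose()` inverts the additivity by variance subtraction,
$\sigma_a = \sqrt{\sigma_{tot}^2 - \sum_i \sigma_i^2}$ (`var_subtract()`),
carried out in this order:

1. a clinical test–retest SD is adopted from a packaged literature
   compilation (per-frequency means across studies, grand mean rounded to
   the nearest integer dB: 6 dB);
2. one clinical measurement: $\sigma_{clin} = 6/\sqrt{2} \approx 4.25$ dB;
3. the web procedure error from the supervised pairing's pooled SD, and
   the home series' total error from the home pairing's pooled SD;
4. the calibration error from the home-vs-supervised comparison at 1 kHz,
   where nonlinearity vanishes by construction;
5. per-frequency nonlinearity errors by removing the supervised SD and the
   calibration error at each remaining frequency;
6. the reference-population SD from a literature figure for
   ascending-method thresholds in young normal-hearing listeners
   ($\sigma_{pop\_asc} = 5.6$ dB, a configuration constant — its quartile
   source data are not published), and from it the calibration-task SD.

Two numerical conventions matter and are pinned package-wide:

* **Unrounded intermediates.** Every subtraction uses full-precision
  inputs; rounding happens only at presentation. Rounding the calibration
  error first would change the 250 Hz nonlinearity value and its mean in
  the second decimal.
* **Clamping.** A negative radicand (a component smaller than the sampling
  noise of the SDs) is clamped to 0 and flagged (`clamped`), and clamped
  zeros are included in the nonlinearity mean. At 8 kHz the home-pairing SD
  is smaller than the supervised SD plus calibration error, so the 8 kHz
  nonlinearity is a flagged 0; without the clamp the mean over the five
  non-calibration frequencies would be undefined.

Gain and background-noise SDs are set to exactly 0 in the default chain:
the supervised series shows no level-dependent SD excess over the home
series (gain), and the smallest SDs occur at the small hearing losses where
masking noise would bite hardest (noise). Both are overridable for
sensitivity analysis.

`reference_budget()` runs this chain on the packaged fixtures and is the
deterministic head-line computation of the package.

## The synthetic cohort

The generator emulates the validation study's conditions: 51 subjects /
102 ears, hearing-loss strata of exactly 45/17/31/9 ears (mean threshold
≤ 25, (25, 40), [40, 70), ≥ 70 dBHL; largest-remainder apportionment, so
counts are exact, not expected values), and a random 37-subject home
follow-up subset. No per-frequency truth model is published for the
cohort, so the audiogram shape is the package's own choice: the ear's mean
threshold is uniform over its stratum band, a linear slope across the
log-spaced grid with total span uniform in ±10 dB adds the typical
sloping-audiogram form, independent N(0, 3 dB) jitter roughens it, and the
deviations are centered so the ear's mean equals its stratum draw before
clipping to [−10, 120] dBHL. Thresholds above the 100 dB maximum output
become no-response measurements, which all analyses exclude pairwise.

What the generator does **not** emulate: age/sex structure, conductive vs
sensorineural configurations, within-subject ear correlation (exposed as a
parameter, default 0 — the study treated ears as independent observations),
level-dependent error growth, and non-Gaussian listener behavior. Passing
tests therefore validate the estimators under the stated error model, not
the clinical realism of any particular audiogram.

All randomness flows from one master seed through named substreams
(cohort / devices / series / follow-up), so each stage is independently
reproducible and a full run is byte-identical given the same configuration.

## Behavioral procedure models

Beyond the reduced additive model, `mode = "behavioral"` replaces the
Gaussian procedure draws with simulations of the procedures themselves over
a cumulative-Gaussian psychometric listener (slope 5 dB, lapse = guess =
0.02 — a standard psychoacoustics choice; the slope is set so the simulated
ascending method lands in the 3–6 dB single-test SD range implied by the
test–retest literature):

* **Ascending method** (`ascending_threshold()`): descend 10 dB while
  responses occur, then ascend in 5 dB steps; after each ascending response
  drop 10 dB and ascend again; stop at the lowest level holding responses
  on at least half the ascending runs with a minimum of two. Runs are
  capped at 30 before a distinct no-response reason is returned; the level
  grid is anchored at the 60 dB start level.
* **Self-adjustment** (`self_adjust_threshold()`): true threshold plus
  N(0, σ_adjust) quantized to the 5 dB slider, σ_adjust configured directly
  (default 6.64 dB).
* **Calibration task** (`calibration_task()`, `calibrate_station()`): the
  midpoint of the final 5 dB tone pair equals the reference person's
  threshold plus N(0, σ_task), quantized by the 1 dB slider; the station
  coefficient averages six single calibrations by three persons.
* **A-weighting reference model** (`a_weight()`, `reference_levels()`): the
  IEC closed form normalized to 0 dB at 1 kHz; the reference level at f is
  `cal − A(f)`, so frequencies perceived as softer are driven harder. The
  sign of the correction is exposed (`aweight_sign`) because only the use
  of an A-weighting based model, not its orientation, is fixed by the test
  design.

## Agreement statistics

`stratify()` pairs two series by subject, ear and frequency (dropping any
pair with a no-response) and emits per-frequency strata, a pooled total, a
per-ear mean (over the frequencies with complete pairs for that ear; a
stricter complete-ears-only variant is available), and two hearing-loss
groups assigned by the mean of the pair's two values around 40 dBHL.
For each stratum `agreement_table()` reports the mean difference, the SD of
differences (n−1 denominator), the Pearson correlation with a Fisher-z
interval (SE $1/\sqrt{n-3}$), and a Deming errors-in-variables fit — the
clinical reference is itself noisy, so ordinary least squares would be
biased toward zero slope. The closed-form moment estimator is used with
error-variance ratio δ = 1 by default (the two series' error SDs, 4.25 and
6.64 dB, are of comparable size; δ is a parameter), and jackknife
(leave-one-out, normal-quantile) intervals. Neither the correlation-CI nor
the Deming-CI method is dictated by the study design; Fisher-z and the
jackknife are the package's choices, validated by interval-coverage
simulations in the test suite.

## Screening

The noise-induced hearing-loss rule: positive when the threshold strictly
exceeds 30 dB at one of 500/1000/2000 Hz, or 25 dB at more than one of
them, or 50 dB at 4 kHz. A no-response at a criterion frequency counts as
positive evidence (the tone was inaudible at maximum output).
Sensitivity/specificity intervals are Wald, truncated to [0, 1] — the
truncated symmetric shape matches how such intervals are conventionally
reported for small screening samples — with Wilson available behind a flag.

## Problem sizes and tolerances

The stochastic validation suites run at 10^4 ears (one ear per subject in
the recovery checks, so every ear carries its own home device), where the
SE of a per-frequency difference-SD estimate is about 0.06 dB. Components
recovered by subtracting two nearly equal variances — the calibration
error, extracted at the single calibration frequency — have sampling SDs
up to about 0.25 dB when the procedure error is large, so a ±0.5 dB
recovery check is roughly a 2-sigma bound there, not a generous one.
Coverage checks use 800–2 000 replicates at n = 100. Quantization and the
dBRP-HL floor are disabled (step 0, floor −∞) in the variance-bookkeeping
checks because both are variance-distorting nonlinearities; they stay at
their defaults everywhere else.

## Known limitations

* Cohort-dependent published statistics (the −1.54/−1.34 dB mean
  differences, the per-frequency correlations, the 0.92/0.96 screening
  rates) depend on the unpublished patient data; the package reproduces
  their *form* and validates the estimators by simulation instead.
* The decomposition inherits the independence assumptions of the additive
  model; correlated components (e.g. a subject-specific self-assessment
  bias present in both web series) would be attributed to the procedure
  term.
* No confidence intervals are produced for the decomposed components, and
  the error model is level-independent by construction.
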