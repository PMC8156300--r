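---
title: "Methods: thoracoabdominal asynchrony assessment from dual-band RIP signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thoracoabdominal asynchrony assessment from dual-band RIP signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Respiratory inductance plethysmography (RIP) records breathing through two
elastic bands — one around the rib cage (RC), one around the abdomen (ABD) —
whose inductance tracks the cross-sectional area of each compartment. In
healthy tidal breathing the two compartments move almost synchronously and
contribute roughly equally to tidal volume. Obstructive or restrictive
dysfunction desynchronises them: the abdominal excursion lags the rib cage
(thoracoabdominal asynchrony, TAA), up to fully paradoxical motion where one
compartment moves inward while the other moves outward. Because the test is
passive — the subject just breathes — it suits patients who cannot perform
effort-dependent tests such as spirometry.

`ripasync` implements the index pipeline end to end: signal ingestion,
per-window respiratory indices, the inverse-cumulative-percentage (ICP)
summary of the phase series, an elastic-net logistic classifier on ICP
values, and per-subject flag reports. A seeded synthetic-signal generator
stands in for patient recordings, so every stage is testable and
demonstrable without clinical data.

## Respiratory indices

All indices are computed per analysis window (default 30 s, stepped by 5 s)
after linear detrending, and all are ratios or angles, so they are invariant
to the unknown calibration of the band signals.

**Phase difference (φ).** Each window of both channels is detrended,
Hann-tapered and Fourier-transformed. The dominant respiratory frequency is
the bin in [0.05, 2] Hz that maximises the *product* of the two channel
power spectra — a frequency must carry energy in both compartments to
qualify, which protects against one-channel artifacts. φ is the argument of
the cross-spectrum at that bin. For two sinusoids at a shared frequency this
equals their lag exactly; the Hann taper keeps spectral leakage from the
negative-frequency image negligible once a window holds at least about three
breath cycles (the function warns below that). The reported phase is the
magnitude folded into [0, 180]°, because severity of asynchrony is unsigned;
the signed value is retained in the output for directional diagnostics.

**Amplitude estimator.** The "absolute amplitude" of a windowed channel is
estimated as √2 × RMS of the detrended samples, which equals the sinusoid
amplitude for a pure tone and is robust to single-sample spikes. Half the
peak-to-peak range is available as `amp_method = "peak"` for users who want
the literal excursion range.

**%RC** = 100·A_rc / (A_rc + A_abd): the rib-cage share of the combined
excursion, ≈50% in healthy breathing. The mirrored abdominal share is its
exact complement by construction.

**Labored breathing index (LBI)** = (A_rc + A_abd) / A_sum, where A_sum is
the amplitude of the summed signal rc + abd (the tidal-volume analog). The
numerator is the excursion the compartments would deliver moving in perfect
unison; the denominator is what they actually deliver. Synchrony gives 1;
a 90° lag at equal amplitudes gives 2/√2 ≈ 1.414; equal-amplitude paradoxical
motion cancels the sum, and the package reports the divergence as an `Inf`
sentinel with a warning rather than a spurious large number. Because linear
detrending is additive and RMS obeys the triangle inequality, LBI ≥ 1 holds
for every window; values a rounding error below 1 are clipped to 1.

**Respiratory rate** is 60× the dominant in-band frequency of the summed
detrended signal, refined by parabolic interpolation of log-power around the
spectral peak (sub-bin resolution: about ±0.1 breaths/min on a 3-min
recording). A peak is accepted only above five times the median in-band
power. When a pulse-oximeter rate is supplied in the vitals record it takes
precedence in reports, as the monitor is the conventional source.

## The ICP summary

The phase series is summarised as an *inverse cumulative percentage* curve:
for every integer angle θ in 0–180°, the percentage of windows whose phase is
at or above θ — an empirical survival function on a fixed grid. It starts at
100%, is non-increasing, and is invariant to permutation of the windows; it
is read like a dwell-time profile ("the subject spent 40% of the recording
at or above 60° of asynchrony"). Unlike the mean phase it is robust to
outliers and shows bimodal patterns.

Markers are read off the curve with a deterministic tie rule: the marker for
percentile p is the **largest grid angle whose ICP still exceeds 100 − p**
(median: largest θ with ICP > 50%). On integer-valued phase series this is
exactly the inverse-empirical-CDF (type 1) order statistic, and the tests
assert that equivalence on random series.

Cohort reference envelopes are pointwise min–max bands of the labelled
training curves (percentile bands are available via `method = "quantile"`;
min–max was chosen as the default because with 10 curves per class extreme
envelopes are more honest than interpolated quantiles). Classifier features
are the ICP values sampled every 5°, 37 predictors — fine enough to follow
the curve's shape, coarse enough that the elastic-net penalty meaningfully
prunes it against 20 training subjects.

## The classifier

The model is logistic regression on the ICP features with an elastic-net
penalty, mixing L1 and L2 at α (default 0.5, the conventional midpoint; the
path fitting is delegated to glmnet, the standard implementation). The
penalty weight λ is chosen by stratified, seeded 10-fold cross-validation
under **misclassification loss** — stated explicitly because deviance is the
more common library default — and the selected λ is the largest one whose
mean CV error is within one standard error of the minimum (the one-SE rule;
`rule = "min"` selects the error minimum instead). Features are standardized
internally before penalization and coefficients are reported on the original
percentage scale. Class encoding is abnormal = 1, with a 0.5 probability
threshold. Given the same features, labels and seed, the fold assignment,
selected λ and coefficients are identical across runs, and models round-trip
bit-exactly through their JSON serialization.

Two design points worth noting: the CV curve stores the fold-mean error and
its standard error per λ along with the nonzero-coefficient count, so the
usual error-versus-log(λ) plot (`autoplot()`) can be reproduced from a saved
model; and at λ = 0 the fit reduces to unpenalized logistic regression,
which the tests verify against an independent IRLS implementation to 1e-4.

## The synthetic generator

`simulate_breathing()` generates both channels as sinusoids sharing one
instantaneous rate, the abdomen delayed by a fixed lag, plus a shared linear
drift and independent Gaussian channel noise. Breath-to-breath variability
is an Ornstein–Uhlenbeck perturbation of the instantaneous rate (10 s
correlation time), which produces naturalistic rate wander without the
segmentation artifacts of per-breath resampling. All randomness flows
through R's Mersenne–Twister generator under the supplied seed; cohort
sub-seeds derive from the master seed as (seed + 7919·i) mod (2³¹−1), so any
subject is reproducible in isolation.

The two cohort conditions emulate a training design in which healthy
subjects are recorded breathing quietly and again through a resistive load
that induces asynchrony. Asynchrony is modelled *kinematically* — as phase
lag plus amplitude imbalance — not mechanically: no airway resistance,
compliance or gas exchange is simulated, which is defensible because changes
in relative RC/ABD motion are nonspecific to the underlying obstructive or
restrictive cause. Defaults: normal lag uniform on [0°, 30°] (healthy delay
is near zero), abnormal on [60°, 180°]; normal amplitudes near-equal
(%RC ≈ 50), abnormal imbalanced; rates 12–25 breaths/min; noise SD 1–3% of
amplitude. The abnormal lag distribution is a stand-in — no published
distribution for resistively loaded breathing was available — and the
intervals are deliberately separable with a margin, so a perfect held-out
classification on these synthetics demonstrates that the pipeline preserves
and recovers the generating separation, **not** that real patients are
classified with that accuracy. Overlapping intervals can be configured to
study degradation.

Simulated vitals draw end-tidal CO₂ inside 35–45 mmHg and SpO₂ above 95%
for normal subjects, and may fall outside both for abnormal subjects.

## Flag rules and reports

Per-subject reports flag each quantity as normal / abnormal / unavailable:

* **Relative deviation rule** (respiratory rate, %RC, LBI, mean phase):
  abnormal when the value deviates from the age-matched healthy mean by more
  than 20% of that mean. Boundary values count as normal. The rule is
  two-sided for rate and %RC but one-sided (elevation only) for LBI and
  phase, since depressed values of either do not indicate dysfunction; the
  sidedness of each flag is configurable.
* **Range rule**: end-tidal CO₂ healthy within the closed interval
  35–45 mmHg.
* **Saturation rule**: SpO₂ normal only when strictly above 95%.

Missing measurements and ages outside the reference table degrade to
`"unavailable"` rather than erroring. The healthy reference table shipped in
`inst/extdata/reference_ranges_synthetic.json` contains *synthetic
placeholder* means on plausible physiological scales; sites must substitute
values from a real healthy reference population before any clinical use.

## Numerical and scale choices

* Window 30 s / step 5 s: ≥5 breath cycles per window at 10 breaths/min
  while yielding ~31 phase samples from a 3-min recording — enough to give
  the ICP meaningful resolution.
* Default sampling rate 50 Hz — more than 10× the highest plausible
  breathing frequency (~2 Hz); the CSV reader infers the true rate from the
  time column when it differs.
* Gap policy: ≤5% missing samples per channel are linearly interpolated
  with a warning; more is rejected as a quality failure.
* Recording CSVs are written with 17 significant digits so write-then-read
  reproduces signals bit-exactly; model JSON likewise.
* Degenerate inputs: zero-variance windows are skipped (an error only if no
  window survives); both-compartment-dead windows are dropped from the
  ratio indices; LBI cancellation yields `Inf`, never negative or `NaN`.

The test suite exercises the pipeline at reduced problem sizes chosen for
desk-scale runs — e.g. 90 s recordings for classifier unit tests and 60 s
recordings in the 100-draw fuzz suite — while the acceptance-style checks
use the full 3-min, 50 Hz recording conditions.

## Limitations

* The generator emulates the *kinematics* of asynchronous breathing, not
  its mechanics; real RIP data add sensor drift, motion artifacts, sighs,
  and non-sinusoidal waveforms the synthetic conditions do not contain.
* Indices are windowed, not breath-by-breath; no per-breath tidal-volume
  estimation is attempted, and band signals are never calibrated to volume.
* The classifier is only as good as its training cohort; the packaged
  defaults demonstrate the machinery on separable synthetic conditions.
* Reference means for the deviation flags are placeholders, as noted above.
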