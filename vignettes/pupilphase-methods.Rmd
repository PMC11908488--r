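---
title: "Methods: quantifying the pupillary respiratory-phase response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the pupillary respiratory-phase response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

Human pupil size fluctuates with the respiratory cycle: it tends to be
smallest around inhalation onset and largest during exhalation — the
pupillary respiratory-phase (PRP) response. The effect is small (on the
order of 0.1–0.35 z of the within-session pupil variability, roughly
0.1–0.25 mm), so detecting it requires careful artifact handling, a robust
definition of respiratory phase, and inference that controls the family-wise
error across the phase bins being compared. `pupilphase` implements that
full path: staged cleaning of per-eye pupil traces, airflow-based phase
estimation, phase-binned statistics, and a synthetic-data generator with
known ground truth so that every stage can be validated without access to
human recordings.

## Pupil preprocessing

Cleaning operates per eye on a `pupil_trace` (values + a validity mask + a
`removed` mask for permanently missing data) in a fixed stage order:

1. **Reliability rules.** Valid stretches shorter than 250 ms are marked
   invalid (tracker validity is unreliable at that scale), as are valid
   islands shorter than 500 ms surrounded on both sides by more than 2 s of
   invalid data.
2. **Removal.** Invalid stretches longer than 500 ms are unlikely to be
   blinks; they are permanently removed — never interpolated — and keep
   counting as invalid for session exclusion.
3. **Interpolation.** Each remaining gap is extended by a 2-frame buffer on
   each side and filled with a cubic spline through the 3 nearest valid
   samples on each side. If the filled range exceeds the anchor range by
   more than 30%, the fill is retried with 3- and 4-frame buffers, and
   finally falls back to a linear fit through the two buffer frames and the
   anchors. Gaps touching the trace edge, or whose anchors lie farther than
   2 s away, stay invalid.
4. **Rapid-change recheck.** Samples whose first difference exceeds
   16 × MAD of the valid first differences (a standard robust pupillometry
   speed criterion; the multiplier is configurable because no single value
   is canonical) are re-interpolated under a stricter 20% range guard.
5. **Post-interpolation reliability rules.** The 250 ms and 500 ms/2 s rules
   are re-applied, plus a third: valid islands shorter than 1000 ms inside
   more than 5 s of invalid data are dropped.
6. **Outlier mask.** Valid samples outside mean ± 3 SD of the trace's valid
   samples are invalidated. The reference statistics are computed per eye
   and per session on the post-interpolation trace — the most local reading,
   since the reference population is genuinely ambiguous.
7. **Finalization.** Remaining invalid samples become `removed`; every
   sample is then exactly one of valid or removed. Sessions with more than
   30% invalid data *in both eyes* are excluded; one good eye keeps the
   session.

Eyes are then averaged samplewise; where exactly one eye is valid, that
eye's value is used (configurable), which maximizes data use and coincides
with the average whenever both eyes exist. Relative (pixel) traces are
z-scored with the population SD (divisor *n*) over the pooled valid samples
of each participant's sessions, so that each participant contributes on a
common scale; per-session scope is available as an option.

**Idempotence.** Re-running the pipeline on its own output must be a no-op.
A literal re-run would not be: after the ±3 SD mask the remaining SD is
slightly smaller, so a second pass would mask a few additional boundary
samples (about 0.1% on Gaussian traces). Finished traces therefore carry a
finalization flag, and `preprocess_pupil()` returns them unchanged.

## Respiratory phase

Airflow (inspiration-positive) is low-pass filtered at 5 Hz with a
zero-phase 4th-order Butterworth filter. The filter uses odd-symmetric
reflection padding; without it, edge transients of the forward–backward pass
corrupt the first and last seconds of a session. On the mean-centred result,
inhalation onsets are negative-to-positive zero crossings (sub-sample
interpolated), exhalation onsets the opposite crossings, and the
inhalation/exhalation peaks the extremum between consecutive crossings.
Crossings closer than 250 ms to the previous one are merged, and crossing
directions must alternate, so sensor noise cannot create micro-cycles.

Phase is piecewise linear within each cycle: 0° at inhalation onset, 90° at
peak inhalation, 180° at exhalation onset, 270° at peak exhalation, and 360°
(≡ 0°) at the next inhalation onset, with half-open segments so every sample
has a unique phase. Half-breaths shorter than 500 ms or longer than 6000 ms
are physiologically implausible and marked invalid; their samples contribute
no observations. The 270–360° segment runs literally to the next inhalation
onset, so inter-breath pauses are absorbed into late exhalation — the
simplest defensible convention, since no landmark separates pause from
exhalation here.

**Timing precision.** A zero-crossing detector locates an onset with error
approximately (filtered noise SD)/(airflow slope at the crossing). At 60 Hz
with sensor noise of 5% of the airflow amplitude this is ~13 ms — a little
under one sample — plus a few milliseconds of systematic shift from
low-pass filtering the asymmetric inhale/exhale waveform. Tests assert the
precision that analysis implies (99% of onsets within 3 samples at 5%
noise; 95% within 1 sample at 1% noise). For the binned analyses this is
immaterial: 13 ms on a ~4.4 s cycle is about 1° of phase against 20° bins.

## Phase-binned statistics

The cycle is divided into 18 half-open 20° bins. Jointly valid samples
(pupil valid AND phase valid) are aggregated as per-bin means, and per-bin
derivatives are computed by summing consecutive-sample pupil changes within
each bin of each cycle (each difference attributed to the bin of its second
sample; pairs spanning invalid samples or cycle boundaries are dropped, so
the per-bin sums telescope exactly to the cycle's endpoint difference) and
averaging over cycles.

**Permutation test.** For each bin the one-sample statistic is
t = x̄/(s/√n). The null (mean zero per bin) is simulated by independently
flipping the sign of every observation; each of 10,000 permutations records
the maximum |t| across the 18 bins, and a bin's family-wise-corrected
p-value is the proportion of permuted maxima ≥ its observed |t|. The
proportion is used as-is (no +1 smoothing), so p = 0 is possible and is
printed as "< 1/n_permutations". Degenerate bins follow a fixed convention:
zero variance with nonzero mean gives t = ±∞ (sorting above all finite
values); zero variance with zero mean gives t = 0. "Observations" default to
individual jointly valid z-scored samples pooled across participants within
a condition, which matches per-bin observation counts in the tens of
thousands for a 40-participant cohort; a per-participant-means mode is
provided because sample pooling and participant pooling are both defensible
readings and give the same qualitative answer at these effect sizes.
Conditions are corrected independently (the max statistic spans the 18 bins
of one condition). Sign flips come from R's Mersenne-Twister stream seeded
once per call, so results are exactly reproducible given the seed.

**Circular summaries.** Each participant's mean direction is the angle of
the resultant vector Σ wₖ·exp(iθₖ), with the per-bin mean z-pupil values as
weights (used as-is — negative weights point away from their bin, which is
exactly what a below-average sector should do) and bin centres as angles. A
zero resultant leaves the direction undefined; the function warns and
returns `NA` rather than silently reporting 0°. Uniformity of the
participants' directions is tested with the Rayleigh test (mean resultant
length R, p from the standard series approximation). The "proportion toward
exhalation" counts directions in [180°, 360°), matching the phase
convention's exhalation half.

**ANOVA.** Group-level effects of phase bin (and route/condition, when
present) on per-participant bin means use a fully within-subject ANOVA:
F, degrees of freedom and p from a multivariate linear model
(`car::Anova`), η² as effect SS over total SS (partial η² optional —
conventions differ and neither is universal). Mauchly's test is run per
effect with more than two levels; when it signals non-sphericity
(p < 0.05) the Greenhouse–Geisser ε (Box's formula) corrects the degrees of
freedom. When the covariance of the within-subject contrasts is singular —
which necessarily happens whenever participants ≤ levels − 1, e.g. 18 bins
with few participants — sphericity cannot be assessed and the one-way
analysis falls back to the Friedman test with Kendall's W = χ²/(n(k−1)).
All of F, η², Mauchly W, ε, and the Friedman χ² are verified against direct
matrix/rank-formula oracles in the test suite.

Absolute (mm) pupil analyses over time use 18 equal-duration time bins of
the session and the same ANOVA machinery.

## The synthetic-data generator

The generator emulates the study conditions: 5-minute sessions at 60 Hz,
cycle durations from a truncated normal (1.2–12 s) matched to
13.58 breaths/min (SD 3.58), inspiratory fraction 0.45 (SD 0.05), airflow as
an inhale half-sine followed by an exhale half-sine scaled by Ti/Te so each
cycle's airflow integrates to zero (inhaled volume = exhaled volume —
without this, mean-centring in the detector would bias every onset), plus
5% Gaussian sensor noise. The pupil signal is
A·cos(θ − θ₀) + random-walk drift + white noise, with defaults A = 0.15 z
and θ₀ = 220°: a peak in mid-exhalation and a trough near inhalation onset,
i.e. the qualitative PRP shape. 220° is a testing convention inside the
mid-exhalation sector, not an empirical estimate. Per-eye noise is
correlated at 0.8 so eye averaging demonstrably reduces noise;
between-participant jitter (amplitude SD 0.05 z, peak-phase SD 20°) mimics
cohort spread. Blinks arrive at 12/min with 100–400 ms durations (both eyes,
values zeroed as a tracker would); occasional 700–1500 ms dropouts exercise
the removal rule. A 4.5 mm baseline with 0.5 mm per z converts to
millimetres. Everything is drawn from a single seeded stream, so cohorts are
byte-reproducible.

What the generator does **not** emulate: the asymmetric empirical shape of
the PRP curve (a single cosine keeps ground truth analytic; a two-harmonic
skew option exists for robustness checks), hippus and the pupillary light
and near responses, gaze-dependent foreshortening, and temporally correlated
measurement noise. Passing recovery tests therefore shows the pipeline
recovers a phase-locked component of realistic size under realistic
artifact rates — not that every property of human data is reproduced. One
consequence of the white-noise choice: spline anchors are noisier than in
smooth real data, so the occasional fill is extreme and is subsequently
reclaimed by the ±3 SD mask; this is the pipeline behaving as designed.

## Numerical and design choices

* Threshold durations are strict inequalities exactly where the rules say
  "shorter/longer than"; the 500–6000 ms half-breath bounds are inclusive.
* Cubic fills use `stats::splinefun(method = "fmm")`, which reproduces
  global cubics exactly (the test suite checks a parabola to 1e-6).
* Bin assignment is `floor(phase/20°)` on half-open sectors; phase 360°
  wraps to bin 0.
* The Rayleigh p approximation can marginally exceed 1 for tiny R and is
  clamped.
* Downsampling is nearest-neighbour selection (validity carried with the
  selected sample), never averaging, so validity semantics survive.
* All tolerances in the test suite were computed from independent oracles:
  exhaustive sign-flip enumeration (2⁸ assignments), numeric integration of
  the cosine per bin, direct SS/rank/matrix formulas, and binomial bounds
  for Monte-Carlo comparisons.

Problem sizes used in validation: the family-wise error calibration uses
200 null datasets of 18 × 100 Gaussian observations at 500 permutations
each; the recovery check uses a 40-participant cohort of 5-minute sessions
with 2,000 permutations in the test suite and 10,000 in the acceptance
script. These sizes give binomial/Monte-Carlo error well inside the asserted
bounds.

## Known limitations

* The rapid-change criterion (16 × MAD) is a convention; the analysis that
  inspired this package does not pin a definition, so the multiplier is a
  config field.
* The Friedman fallback is implemented for one-way designs (the only case
  that arises); a two-way design with a singular contrast covariance raises
  an error advising per-factor one-way analyses.
* Landmark timing is noise-limited (see above); at plausible sensor noise
  this contributes ~1° of phase error.
* Inter-breath pauses are not modelled; they stretch the 270–360° segment.
* The permutation "observation" ambiguity (samples vs participant means) is
  surfaced as an option rather than resolved.
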