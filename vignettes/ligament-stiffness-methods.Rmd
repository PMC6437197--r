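---
title: "Measuring knee ligament stiffness with a calibrated balancer: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring knee ligament stiffness with a calibrated balancer: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligastiff)
```

## The measurement problem

During total knee arthroplasty a spring-loaded knee balancer distracts the
femur from the cut tibial surface, one measuring unit per compartment
(medial and lateral). Each unit displays the applied tibiofemoral force on a
joint-force scale and the extension gap on a gap scale. Filming the scales
while the surgeon manually extends the ligament complex from a ~10–20 N
preload up to 170 N, and digitizing six scale points per analysed frame,
yields everything needed to reconstruct a force–displacement curve of the
intact ligament complex *in vivo* — a quantity otherwise only available from
cadaver work on isolated ligaments.

`ligastiff` implements the full measurement chain: the device calibration
model, the per-frame geometry that converts pixel coordinates to force and
displacement, the stiffness fit, cohort summaries, and a synthetic forward
model used to validate the chain by parameter recovery.

## Device model

Each measuring unit is calibrated on a universal testing machine. The
package ships the bench constants (`default_calibration()`): the forces at
the force scale's start point A and reference endpoint B
(left: 21.2 N and 123.3 N; right: 18.1 N and 116.9 N), the spring constants
of the paddle drives (12.0 and 11.8 N/mm), and the paddle feed per quarter
knob turn (0.7 mm). The two units differ in every force field, so the
unit-to-compartment assignment is mandatory metadata throughout the
pipeline, never defaulted. Bench standard deviations at the four scale lines
are stored as metadata only; the reconstruction uses the endpoint means.
Re-calibrated devices can be described in a flat YAML/JSON config
(`read_calibration()`).

## Per-frame reconstruction

For each frame, with digitized points A, B, C (force scale) and D, E, G
(gap scale), origin at the image's bottom-left corner:

* the relativity factor `m = |AC| / |AB|` locates the force pointer on the
  scale, and `F = F_A + m (F_B − F_A)` converts it to newtons;
* the gap reading is `EG_real = 20 mm × |EG| / |DE|`, using the known 20 mm
  reference span DE to cancel per-frame camera magnification and tilt;
* displacement is referenced to the first analysed frame:
  `p_i = EG_real(frame 1) − EG_real(frame i)`, so `p_1 = 0` exactly and
  extension gives positive p.

Both m and `EG_real` are ratios of Euclidean lengths, hence exactly
invariant under any similarity transform of the image; the test suite
verifies this to 1e-9 relative under rotations up to π, scale factors
0.25–4, and large translations.

Numerical and edge-case choices:

* **Extrapolation above B.** In vivo forces reach 170 N, beyond `F_B` on
  both units, so the linear force map is extrapolated above `m = 1` up to a
  configurable bound (default 1.6 ≈ (170 − 18.1)/(116.9 − 18.1)); the scalar
  operation warns on extrapolation, and curve reconstruction records the
  count of extrapolated frames. Beyond the bound an error is raised.
* **Sign of p.** The frame-1-minus-current convention is implemented
  literally. Negative displacements (gap reading growing after frame 1) are
  kept, counted, and reported — clamping them would hide orientation
  mistakes in annotations.
* **Unsigned m.** A pointer below the scale start cannot be distinguished
  from one above it (a length ratio is unsigned). This is a documented
  limitation of the method; the synthetic generator never produces it.
* **Degenerate scales** (|AB| = 0 or |DE| = 0) raise classed errors.

Frames are whatever the annotator chose to digitize (typically every 10th
video frame, 15–20 per pull); the module accepts any ≥ 2 ordered frames from
one unit.

## Stiffness estimation

A ligament-complex curve has a compliant non-linear toe region
(straightening of crimped collagen fibres) followed by a linear region whose
slope dF/dp defines structural stiffness in N/mm. The toe-to-linear
transition is gradual and individual, but across all measurements linearity
holds from 80 N onward, so `select_linear_region()` keeps exactly the
samples with `F ≥ 80 N` (boundary inclusive, configurable threshold) and
`fit_stiffness()` fits ordinary least squares of force on displacement —
force on displacement, not the reverse, because stiffness is defined as the
gradient of F(p). The fit reports slope, intercept, OLS standard error, R²
and the number of points, and refuses fewer than 3 points or an all-equal
displacement vector. Samples are unweighted: the bench data provide no
per-reading uncertainties.

Repeats of one compartment are aggregated by `aggregate_repeats()` to an
arithmetic mean and a **population** (divide-by-n) standard deviation. The
population convention is fixed by evidence from the shipped cohort: the
sample SD of the five patients' ages (11.7) would print as 12, but the
published summary prints 10, matching the population SD (10.45 → 10); the
same holds for BMI, leg axis, and both stiffness columns. One convention is
used everywhere.

`detect_linearity_onset()` is a QC helper, not part of the published
procedure: it scans candidate thresholds over the observed forces and
returns the smallest whose suffix of ≥ 3 points fits with R² ≥ 0.995,
falling back to 80 N with a warning. The 0.995 cutoff and 3-point minimum
are package choices.

## Cohort module

`load_table1_fixture()` ships the five-patient study cohort (sex, age, BMI,
leg side, leg axis, per-compartment stiffness mean and SD over two repeated
pulls). `summarize_cohort()` computes unrounded means, population SDs and
extremes; `round_cohort_summary()` renders the 1-decimal display values.
The across-patient stiffness extremes are the extremes of the per-specimen
means. Leg-axis values straddle 180° and are stored verbatim (hip–knee–ankle
angle convention, not interpreted). One published number disagrees with its
own source data at display precision: the LLC cohort mean computes to
30.82 → 30.8 N/mm from the per-specimen values, while the published text
prints 30.9 (the published SD 8.9 is consistent with the unrounded 30.82).
The package reports the computed value.

## Synthetic forward model and what it validates

No raw surgical videos are publicly available, so the per-patient stiffness
values cannot be reproduced directly. Validation instead uses parameter
recovery: simulate the entire chain from known ground truth, run the real
reconstruction-and-fit pipeline, and score the estimates.

**Ground-truth curve.** `ground_truth_curve()` uses an exponential toe
joined C¹-continuously to a linear branch:
`F(p) = preload + a (e^{λp} − 1)` for `p < p*`, then
`F(p) = F* + k (p − p*)`. Given preload, k, the transition force `F*` and
the rate λ, the amplitude a and transition displacement p* follow from
value- and slope-continuity, so the linear branch's slope is *exactly* k and
recovery has an unambiguous truth. The exponential toe is the standard
tendon/ligament idealization; the true in-vivo toe shape is unknown, so
recovery results are conditional on it. Setting `F* = preload` collapses the
toe and yields a pure line — used as a closed-form limit check. Defaults:
preload 15 N, k 30 N/mm, transition 60 N (below the 80 N threshold, as the
fluent transitions in the measured curves require), λ 0.3 /mm (toe lengths
of ~2 mm at cohort-typical stiffness, matching the measured curve shapes),
max force 170 N.

**Device inversion.** Displacements are placed on a uniform grid (the
manual pull is quasi-static at roughly constant speed; time itself is not
modelled) from the first frame where the force pointer has reached the
scale start (`F ≥ F_A` — below that the pointer is off the scale and m
would be unsigned) to the frame where 170 N is reached. Each force maps to
`m = (F − F_A)/(F_B − F_A)` and each displacement to a gap reading
`EG_real = initial gap − p` (default initial reading 15 mm, comfortably
above the few-mm pulls of cohort-typical stiffness).

**Scale layout.** Canonically the force scale lies along x with
`|AB| = 200 px` and C at `A + m (B − A)`; the gap scale is orthogonal with
`|DE| = 200 px`. E is the gap reading's zero mark and D its 20 mm mark, and
the pointer G sits on the graduated stretch *between* the marks at
`EG_real/20` of the reference length from E — readings of 0–20 mm live on
the 20 mm reference span that the DE calibration corrects, as on a physical
scale. This placement matters for error propagation: E's pixel noise enters
|DE| and |EG| with partially cancelling effect when G lies between the
marks, whereas a pointer outside the span would see coherent (amplified)
noise.

**Camera.** Every frame gets its own pose: rotation U(−0.1, 0.1) rad,
uniform scale U(0.9, 1.1), translation U(−20, 20) px, optional mild
perspective (a projective division; strength 0 means a pure similarity and
exactly zero reconstruction error), and i.i.d. Gaussian pixel noise on
every coordinate, truncated at ±4 SD (a human annotator is never tens of
pixels off). All randomness flows from a single seed; the same seed
reproduces byte-identical frame files.

**What passing tests show — and what they do not.** Recovery at the study
geometry (15–20 frames, preload U(10, 20) N, k U(20, 47) N/mm spanning the
cohort, 0.5 px noise, 200 px scale bars, 200 seeds) achieves a median
relative stiffness error of ~1.4–1.9% and a 95th percentile of ~5%; at zero
noise the pipeline is exact to floating precision. This validates the
geometry, the device inversion and the estimator under the stated noise
model. It does not validate the toe's physiological shape, annotator error
structure beyond Gaussian jitter, lens distortion beyond what the DE ratio
corrects, soft-tissue relaxation between repeats, or strain-rate effects
(the quasi-static pull justifies ignoring viscoelasticity, and the package
follows that).

## Problem sizes and runtimes

The shipped validation uses 200 Monte-Carlo measurements at 0.5 px noise
plus 25 at zero noise (seconds on one core); the test suite uses the same
sizes plus 1000 randomized OLS-oracle cases. These sizes give stable
medians and percentiles (re-running across seeds moves the recovery median
by ~±0.2 percentage points) while keeping the whole suite fast.

## Entry points

`cmd_simulate()`, `cmd_fit()` and `cmd_summarize()` wire the modules
together for scripted use, and `inst/scripts/ligastiff.R` exposes them to a
shell. `cmd_fit()` consumes a manifest (file, patient, compartment) because
the unit-to-compartment mapping must be explicit; failed measurements (for
example, pulls that never reach 80 N) are recorded and skipped without
aborting the run. All stored numbers are unrounded; rounding to one decimal
happens only at display, matching the source's printed precision.
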