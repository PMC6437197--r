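# ligastiff

In vivo knee ligament stiffness from calibrated balancer video annotations.

## The problem

Knee stability is governed by the medial and lateral ligament complexes, yet
almost all stiffness data come from cadaveric tests of isolated ligaments
pulled along their fibre direction — not from the intact complex loaded the
way a surgeon loads it. During total knee arthroplasty, a standard
spring-loaded knee balancer already applies a measurable tibiofemoral force
and displays the extension gap, one measuring unit per compartment. Filming
its two mechanical scales during a manual extension from a 10–20 N preload
to 170 N, and digitizing six scale points per analysed frame, is enough to
reconstruct the force–displacement curve of each ligament complex *in vivo*.

`ligastiff` is for biomechanics researchers and engineers working with such
recordings: it turns per-frame scale-point coordinate tables into
force–displacement curves, stiffness estimates, and cohort summaries, and it
ships a seeded synthetic forward model of the whole measurement chain so the
pipeline can be validated by parameter recovery.

## The method

For each analysed frame, with points A, B, C on the joint-force scale and
D, E, G on the extension-gap scale (pixel coordinates, origin bottom-left):

* relativity factor: `m = |AC| / |AB|`
* force: `F = F_A + m (F_B − F_A)`, with per-unit bench calibration
  (left paddle `F_A = 21.2 N`, `F_B = 123.3 N`; right paddle `18.1 N`,
  `116.9 N`)
* gap reading: `EG_real = 20 mm × |EG| / |DE|` (DE spans 20 mm, cancelling
  per-frame camera magnification and tilt)
* displacement: `p_i = EG_real(frame 1) − EG_real(frame i)`

Every quantity is a ratio of lengths, hence invariant to camera similarity
transforms. The curve's linear region (force ≥ 80 N) is fit by ordinary
least squares of force on displacement; the slope is the structural
stiffness in N/mm. Repeats are aggregated as mean ± population SD.

## Worked example

Simulate one noisy measurement with known ground truth (true stiffness
30 N/mm, preload 12 N, 0.5 px annotation noise), reconstruct, and fit:

```r
library(ligastiff)

cal   <- default_calibration("left")
truth <- ground_truth_curve(preload = 12, linear_stiffness = 30)
meas  <- project_measurement(cal, truth, camera_model(pixel_noise_sd = 0.5),
                             n_frames = 17, seed = 42)

rec <- reconstruct_curve(cal, meas$frames)
head(as.data.frame(rec), 4)
#>   frame        m force_N gap_mm displacement_mm
#> 1     1 0.001643   21.37  14.93          0.0000
#> 2    11 0.058090   27.13  14.60          0.3241
#> 3    21 0.133271   34.81  14.32          0.6104
#> 4    31 0.209016   42.54  14.00          0.9305

fit_stiffness(select_linear_region(rec, 80), force_threshold = 80)
#> Ligament stiffness fit: 29.91 N/mm (SE 0.657), R^2 = 0.9966, n = 9, force >= 80 N
```

The fitted slope, 29.91 N/mm, recovers the generating stiffness of 30 N/mm
to 0.3% from 9 linear-region samples; the standard error (0.66 N/mm) and R²
quantify the fit. Forces below 80 N (the toe region, where crimped collagen
fibres are still straightening) are excluded before fitting.

Summarizing the packaged five-patient study cohort:

```r
summarize_cohort(load_table1_fixture())
#> Cohort summary (n = 5), mean +/- population SD [min, max]:
#>   age [a]                  72.0 +/- 10.4  [58.0, 85.0]
#>   BMI [kg/m^2]             30.6 +/-  4.5  [23.7, 36.6]
#>   leg axis [deg]          176.1 +/-  5.4  [167.2, 184.0]
#>   MLC stiffness [N/mm]     32.2 +/-  4.5  [28.4, 39.9]
#>   LLC stiffness [N/mm]     30.8 +/-  8.9  [19.9, 46.6]
```

The medial ligament complex averages 32.2 ± 4.5 N/mm and the lateral
30.8 ± 8.9 N/mm across the cohort (population-SD convention).

A shell dispatcher for `simulate` / `fit` / `summarize` ships at
`inst/scripts/ligastiff.R`; see the methods vignette
(`vignettes/ligament-stiffness-methods.Rmd`) for the models, parameter
choices, and the validation design.

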