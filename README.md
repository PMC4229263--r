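# facemotion3d

Quantitative assessment of facial-nerve function needs objective,
repeatable measurements of facial motion, not subjective grading scales.
`facemotion3d` implements a complete marker-based 3-D dynamic facial
motion analysis pipeline for R — the kind of system built around a
six-camera optical motion-capture rig observing 21 reflective facial
landmarks plus a rigid three-marker reference helmet — together with a
synthetic capture simulator so every stage can be validated against
ground truth without hardware.

The pipeline covers:

* **Synthetic capture rig** — six pinhole cameras in a symmetric "L"
  at an 800 mm working distance; calibration wands (T-rod with three
  collinear markers), accuracy rods (a 176.84 mm linear rod and a 90°
  L-rod), and a parametric 21-landmark face with scheduled expressions,
  rigid head motion and Gaussian pixel noise.
* **Wand calibration** — per-camera direct linear transform (DLT)
  estimation with Hartley conditioning, gated by the calibration
  *systemic error*: the RMS discrepancy between reconstructed and known
  wand inter-marker distances, which must stay below 0.3 mm.
* **Reconstruction** — homogeneous linear least-squares triangulation,
  marker labelling/tracking by mutual-nearest and gated
  nearest-neighbour association, and cubic interpolation of short gaps.
* **Reference frames** — a per-frame helmet coordinate system (origin and
  plane from the three rigid helmet markers, third axis perpendicular to
  that plane) removes head motion; an anatomical frame built from the
  tragus points and the nasal landmark carries the reporting
  conventions: X left(+), Y up(+), Z forward(+).
* **Kinematics** — Savitzky–Golay smoothed central-difference velocity
  and acceleration at 100 Hz; per-expression maxima of deviation, speed
  and acceleration with moving direction; and the 20-parameter static
  measure set (8 distances, 4 vertex angles, 8 direction components).
* **Accuracy validation** — static/dynamic rod protocols: measure the
  rod's reference quantity in ≥10 randomly sampled frames and test the
  mean against the manufactured value with a one-sample t-test,
  `t = (x̄ − ref)/(s/√n)`, `df = n − 1`.
* **Test–retest reliability** — one-way random single-measures
  intraclass correlation, `ICC(1,1) = (MSB − MSW)/(MSB + (k−1)MSW)`,
  with F-based 95% confidence intervals from
  `F = (1+(k−1)ICC)/(1−ICC)` divided by / multiplied with the upper
  α/2 F quantiles at `(n−1, n(k−1))` and `(n(k−1), n−1)` degrees of
  freedom.

## Worked example

Calibrate a rig from a simulated wand sweep, run the dynamic rod
accuracy protocol, and estimate test-retest reliability on a synthetic
19-subject cohort:

```r
library(facemotion3d)
rig  <- default_rig()
wand <- simulate_wand_sweep(rig, n_frames = 3000, sigma_px = 0.5, seed = 1)
cal  <- calibrate_dlt(wand, seed = 1)
print(cal)
#> DLT calibration of 6 cameras
#>   systemic error: 0.1954 mm over 3000 frames (gate 0.30 mm) -> PASS

acc <- run_rod_protocol(rig, cal, rod_linear(), "dynamic",
                        duration_s = 20, sigma_px = 0.5, seed = 1)
print(acc)
#> Accuracy report (distance): n = 10 sampled frames
#>   mean 176.8453 +/- 0.1185 (reference 176.8400)
#>   mean error 0.005324, mean absolute error 0.0913
#>   t = 0.142 (df = 9), two-sided p = 0.890

coh <- simulate_static_cohort(n_subjects = 19, seed = 1)
tab <- reliability_table(coh$session1, coh$session2)
head(tab[, c("parameter", "class", "icc", "lower", "upper")], 5)
#>        parameter    class   icc lower upper
#> 1 G-H (distance) distance 0.990 0.976 0.996
#> 2 g-h (distance) distance 0.982 0.955 0.993
#> 3 I-G (distance) distance 0.991 0.976 0.996
#> 4 I-g (distance) distance 0.985 0.961 0.994
#> 5  H-h(distance) distance 0.993 0.982 0.997
```

The calibration passes its 0.3 mm systemic-error gate; the dynamic rod
measurements average within ~0.1 mm of the manufactured 176.84 mm
length (the t-test finds no significant bias); and the static distance
measures are highly repeatable across the two synthetic sessions, with
ICC point estimates bracketed by their F-based 95% intervals.

A command-line front end over the same functions ships in
`inst/cli/facemotion` (subcommands `simulate`, `calibrate`,
`reconstruct`, `analyze`, `validate`, `reliability`, `demo`); `demo`
runs the whole chain into one output directory.

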