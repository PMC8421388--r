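# gedipipe

Automated single-cell death detection for time-lapse fluorescence microscopy
of neurons expressing a genetically encoded death indicator (GEDI).

## The problem

In longitudinal imaging studies of neurodegeneration, each neuron expresses
two fluorophores from one transcript (via a self-cleaving P2a peptide): a
low-affinity calcium sensor whose fluorescence rises only when cytosolic
Ca²⁺ reaches catastrophic, death-associated levels, and a constitutive
morphology fluorophore used for segmentation and normalization. The
per-neuron readout is the **GEDI ratio** — background-subtracted mean GEDI
intensity over the soma mask divided by the mean morphology intensity. The
ratio sits in a low band while the neuron lives, jumps irreversibly at
death, and stays high while the debris decays, making death a binary,
time-resolved event that survival statistics can use.

`gedipipe` implements the analysis side of such experiments end to end:

* **Synthetic plates** — a generator rendering two-channel 16-bit TIFF time
  series of soma-like objects with programmed death times drawn from
  per-well hazards, post-death exponential decay, stage jitter and noise,
  with full ground truth (`plate_config()`, `generate_plate()`).
* **Image processing** — median background subtraction, montage stitching,
  FFT cross-correlation registration, soma segmentation (Gaussian smooth →
  Otsu with a robust noise floor → connected components → 100 px size
  filter → bright-core restriction), per-object feature extraction
  (`subtract_background()`, `stitch_montage()`, `align_timepoints()`,
  `segment()`, `extract_features()`).
* **Tracking** — mutual-nearest centroid-proximity linking with
  loss-at-first-missing-timepoint semantics and reversal-artifact flagging
  (`link_tracks()`, `flag_reversal_artifacts()`).
* **Death calling** — the calibrated threshold

  ```
  threshold = mean(live) + 0.25 * (mean(dead) - mean(live))
  ```

  from live (pre-treatment) and dead (lethal positive-control) reference
  populations; a neuron dies at the first timepoint its ratio strictly
  exceeds the threshold, or when its track is lost; otherwise it is censored
  (`calibrate_threshold()`, `assign_death_time()`).
* **Survival and kinetics** — Kaplan–Meier curves, cumulative risk-of-death
  (cumulative incidence and Nelson–Aalen hazard), Cox proportional hazards
  with Efron ties (`km_estimator()`, `cumulative_risk()`, `cox_fit()`),
  log₂-linear decay half-life fits and plateau + one-phase-association rise
  fits (`fit_log_decay()`, `fit_rise()`), plus equilibrium Hill-model curves
  for sensor design (`hill_fluorescence()`).

## Worked example

The numbered scripts under `analysis/` run the whole workflow on a
demonstration plate (500 neurons in four wells: two vehicle, one treated at
hazard ratio 2, one lethal calibration control; imaged 0–96 h every 24 h):

```sh
Rscript analysis/01_simulate_plate.R
Rscript analysis/02_process_images.R
Rscript analysis/03_survival_analysis.R
Rscript analysis/04_kinetics.R
Rscript analysis/05_sensor_curves.R
```

Output of stages 2 and 3 on this plate:

```
  calibrated threshold: 0.1312 (live mean 0.0103, dead mean 0.4938)
Death-call confusion vs ground truth:
      truth
call   dead live
  dead  254    0
  live    0  189
  sensitivity = 1.0000, specificity = 1.0000 (443 tracks matched)

group treated vs vehicle: HR = 2.208 (95% CI 1.723-2.829), p = 3.92e-10
Generator-truth Cox fit: HR = 2.204 (95% CI 1.721-2.823) on 450 neurons
```

The calibrated threshold lands a quarter of the way between the live and
dead ratio bands; every ground-truth death inside the imaging window is
called (by ratio crossing or track loss) and no survivor is miscalled; and
the hazard ratio estimated from image-derived death calls reproduces the
fit on the generator's programmed death times almost exactly — the imaging,
segmentation and tracking stages lose essentially no survival information
at these settings.

Stage 4 recovers the post-death decay half-life of both reporters from the
truth traces (20.45 h each here; equal decay of the two fluorophores is what
keeps the dead-band ratio stable), and stage 5 shows the
stimulation:death response ratio separating a death indicator (~10⁻⁵) from
an activity indicator (~0.95).

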