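---
title: "Methods: death detection from ratiometric biosensor imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: death detection from ratiometric biosensor imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gedipipe)
```

## The measurement model

A neuron co-expresses a low-affinity calcium sensor (the death indicator)
and a constitutive morphology fluorophore at a fixed stoichiometry. The
per-neuron, per-timepoint readout is the GEDI ratio: the mean
background-subtracted death-indicator intensity over the segmented soma
divided by the mean morphology intensity. Because both proteins come from
one transcript, the ratio cancels expression level; it is low while the
membrane maintains the Ca²⁺ gradient and jumps irreversibly when that
gradient collapses at death.

Sensor equilibria are described by a Hill curve,
$F(\mathrm{Ca}) = F_{\min} + (F_{\max}-F_{\min})
\frac{\mathrm{Ca}^{n}}{K_d^{n} + \mathrm{Ca}^{n}}$,
implemented on the log scale so saturating concentrations do not overflow.
The package ships **no literature $K_d$/Hill constants**: published values
vary between reports and calibration conditions, so sensor parameters are
configuration inputs (see `inst/extdata/sensors_example.yaml`, which is
explicitly marked as placeholder values). The stimulation:death response
ratio — peak $\Delta F/F_0$ under physiological stimulation over peak
$\Delta F/F_0$ during lethal treatment — is reported unclamped, preserving
sign information when a stimulation window dips below baseline. The
$\Delta F/F_0$ baseline $F_0$ is the mean over an explicit index window
(default: samples before the first stimulus marker); the estimator is a
design choice, since only "fold change after background subtraction" is
pinned down by the measurement model.

## The synthetic plate generator

The generator exists to give the pipeline inputs with known truth that
reproduce the *statistical structure* the method assumes, at desk scale.
One well is rendered as:

* **Objects.** `n` somata as Gaussian blobs (scale `psf_sigma`, default
  3 px) with two thin neurite strokes at 10% of soma amplitude, placed with
  a minimum spacing (default 50 px) by rejection sampling; amplitudes are
  log-normal around 20 000 (16-bit range). Strokes render in both channels
  at the cell's current ratio, so the ratio is uniform across the cell.
* **Fates.** Death times are exponential with the well's hazard (Weibull
  optional via a shape parameter; the exponential default reflects that the
  downstream contrast is semi-parametric Cox, which does not care).
  A `lethal` well has every neuron dead from the first frame — the
  positive-control population used to calibrate the dead band.
* **The ratio process.** Each neuron draws a live ratio
  ($\mathcal{N}(0.01, 0.003)$, truncated positive) and a dead ratio
  ($\mathcal{N}(0.5, 0.05)$). The live/dead band centres are generator
  defaults chosen to give the clear two-population separation the method
  relies on — they are settings of this artifact, not measured constants.
  At death the ratio jumps and stays in the dead band while both channels
  decay exponentially; the default half-lives are equal at 20.45 h (equal
  decay of the two reporters is what makes the activated ratio a stable
  death record; the package's decay-fit analysis checks exactly this).
* **Disappearance.** Debris is removed once the soma peak falls below
  `2 * noise_sd`, emulating eventual loss of the fluorescent debris; the
  implied disappearance time is part of the ground truth.
* **Imaging.** Per-timepoint global integer stage jitter
  (sd `jitter_px` = 1.5), constant background (500) with optional gradient,
  additive Gaussian noise (sd 50), rounding and clipping to unsigned 16-bit,
  optional montage tiling with overlap. Identical config + seed reproduces a
  plate byte for byte.

What the generator deliberately does **not** emulate: photobleaching,
realistic optics beyond Gaussian blur, 3D stacks, debris scavenging,
density-dependent death, and (by default) fragmentation of the soma at
death — a flag renders 2–4 sub-blobs, but it is off so segmentation tests
stay interpretable. Passing tests therefore demonstrate correctness of the
*computational* chain under the stated statistical structure, not
robustness to every property of real microscopy data.

## Image processing

* **Background.** Subtract the per-image median, clamping negatives to
  zero. The clamp keeps downstream ratio means non-negative; the median
  makes ratios comparable across datasets. On an image whose median is 0
  the operation is idempotent.
* **Stitching.** Tiles are averaged in overlap regions; output size is
  exact, `(rows·h − (rows−1)·ov) × (cols·w − (cols−1)·ov)`.
* **Registration.** Whole-image translation only (the drift model is stage
  error): integer shifts from the maximum of the FFT circular
  cross-correlation against frame 0, capped (default 20 px) with a warning,
  zero with a warning on featureless frames.
* **Segmentation.** Gaussian smooth (σ = 2) → global threshold at the
  maximum of Otsu's value, a configurable quantile floor, and a robust
  noise guard (`median + 5·MAD` of the smoothed image — without it, Otsu
  splits the noise distribution of an object-free frame and fabricates
  components) → 4-connected components → minimum area 100 px → components
  larger than a soma cap (1000 px) are restricted to pixels above their
  75th intensity percentile and relabelled. The operator is pluggable by
  parameters; the target is the bright soma core, because neurite-level
  masks merge neighbouring cells and dilute the ratio. Pixel coordinates
  are 0-based, x rightwards, y downwards; areas in px; times in hours.

## Tracking and artifact handling

Linking is iterated mutual-nearest centroid matching within
`max_link_dist` (default: twice the median soma diameter estimated from the
data), taking the globally closest remaining pair first, ties broken by the
lower object label. There is no gap closing by default — a missed detection
terminates the track, consistent with treating track loss as a death
event — but a one-frame tolerance flag exists for sensitivity analysis.

A track whose ratio exceeds the death threshold and later falls below it is
flagged as a **reversal artifact** and excluded from survival analysis by
default rather than re-classified: such patterns trace to segmentation or
tracking errors, not resurrection, so they belong in an audit log. The drop
log records every excluded object and track with a reason code.

## Death calling

The threshold interpolates a quarter of the way from the live calibration
mean to the dead calibration mean. The 0.25 weight is treated as a fixed
convention with a config override; by default live = all objects at the
first (pre-treatment) timepoint of non-control wells and dead = all objects
of lethal positive-control wells, and the threshold is recalibrated per
experiment because population means shift with expression level. The
boundary is strict (`ratio > threshold` is dead; equality is live). A
track's death time is the earliest of its first strict crossing and its
loss time, dated at the **first missing timepoint** (that is when the loss
is observed; interval-censoring refinements are out of scope); a track with
neither is censored at the last imaging time. Raising the threshold can
only delay or remove death calls, never create them.

## Survival and kinetics statistics

Kaplan–Meier, Nelson–Aalen and Cox fits delegate to the `survival` package
behind thin tidy wrappers. Cox uses the **Efron** tie correction: imaging
at 12–24 h intervals puts many deaths at identical recorded times, where
Efron is less biased than Breslow. Confidence intervals are Wald,
$\exp(\beta \pm 1.96\,\mathrm{se})$. "Cumulative risk-of-death" is reported
as both $1 - S(t)$ and the Nelson–Aalen cumulative hazard, because the
phrase is used loosely in the field; group contrasts come from the Cox
hazard ratio either way. The per-neuron analysis ignores within-well
clustering by default (a well-cluster robust-SE option exists). The test
suite cross-checks the Cox wrapper against an independent hand-written
maximiser of the Efron partial likelihood.

Decay fits regress $\log_2$ intensity on time so the slope is directly
$-1/t_{1/2}$; non-positive samples are dropped with a warning and at least
three must remain. Rise fits use the plateau-then-one-phase-association
model $F_0$ for $t<t_0$, $F_0 + (P-F_0)(1-e^{-(t-t_0)/\tau})$ after onset.
For each candidate onset on the observed-time grid, $F_0$ and $P$ are
profiled out linearly and $\tau$ is found by one-dimensional optimisation;
the onset is then refined continuously around the best gridpoint. This
multi-start scheme avoids the local minima of a joint four-parameter
descent; flat traces (negligible amplitude or $\tau$ at its bounds) are
flagged as $\tau$-unidentifiable rather than reported.

## Numerical choices and degenerate inputs

* Equality at the death threshold is live (strict "exceeds").
* A numerically constant trace (|slope| < 1e-12) reports an infinite
  half-life rather than ±1e16.
* Empty wells, all-censored cohorts and single-group inputs flow through
  with notices: KM only, Cox skipped.
* A calibration where the dead mean falls below the live mean returns a
  model flagged unreliable, with a warning, instead of failing.
* Undefined ratios (non-positive morphology mean) drop the object into the
  log, never silently.

## Problem sizes

The bundled analyses and tests use a four-well, 500-neuron plate at
1024×1024 px and 5 timepoints, cohorts of up to ~2 300 subjects for
hazard-ratio recovery, 200-replicate coverage checks and 500-replicate
decay-bias checks. These sizes were chosen so the full workflow demonstrates
every property it claims (two separated ratio bands, exact tracking at the
configured spacing/jitter, CI coverage near nominal) while remaining
desk-scale.

## Known limitations

Tracking is purely positional (no appearance model, no division handling);
segmentation assumes sparse bright somata on a dark background; the
generator's realism limits are listed above; and the death-calling accuracy
reported on synthetic plates (sensitivity and specificity 1.0 at default
settings) should be read as validation of the computational chain, not as a
claim about any particular microscope or biology.
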