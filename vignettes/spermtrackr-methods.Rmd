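---
title: "Methods: tracking, kinematics and validation in spermtrackr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tracking, kinematics and validation in spermtrackr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spermtrackr)
```

## What the package computes

`spermtrackr` performs computer-aided sperm analysis (CASA) on grayscale
microscopy video of semen samples: bright sperm heads on a dark background,
as produced by negative phase-contrast imaging at 10--20X and 50--60 frames
per second. From a video it derives

* per-cell **kinematics**: straight-line velocity (VSL), curvilinear
  velocity (VCL), average-path velocity (VAP), linearity (LIN = VSL/VCL),
  maximum amplitude of lateral head displacement (ALH~max~), and beat-cross
  frequency (BCF);
* a **WHO 6th-edition motility grading** of every cell (rapid progressive,
  slow progressive, non-progressive, immotile) and the per-sample
  percentages, reporting non-progressive and immotile merged (IM&NP);
* a **concentration estimate** in millions/mL, via a linear calibration of
  the number of cells tracked in the opening frames against reference
  concentrations;
* **method-agreement statistics** for benchmarking one analyser against
  another: per-parameter linear calibration, R^2^/RMSE/MAE, Bland--Altman
  limits of agreement, and duplicate-measurement repeatability.

A synthetic video simulator with analytically known ground truth closes the
loop: every estimator in the package can be checked against the exact
kinematics of the curves it is shown.

## Detection and tracking

Sperm heads are compact, high-contrast blobs, so their centers respond
strongly to the Shi--Tomasi minimum-eigenvalue corner measure while
low-contrast debris does not. `detect_heads()` keeps local maxima of that
response above `quality_level * max(response)` (default 0.05), suppresses
neighbours closer than `min_feature_distance` (8 px), and refines each
detection to a sub-pixel centroid by intensity-weighted averaging; on
noiseless synthetic blobs the refined centers are accurate to well under
half a pixel.

`track_video()` propagates each detected head frame to frame with a
pyramidal Lucas--Kanade optical-flow solver (default 3 levels, 15 px
integration window, 20 iterations at 0.01 px tolerance). Identity
management uses three rules:

1. **Forward--backward consistency.** Each point is tracked forward and
   then backward; if the return misses the origin by more than
   `fb_error_max` (2 px) the track terminates. This catches drift onto the
   background and onto neighbouring cells.
2. **Re-detection.** Every `redetect_interval` (5) frames, fresh detections
   farther than `min_feature_distance` from every active track are enrolled
   with new IDs, so cells entering the field or recovering from a tracking
   failure are reacquired.
3. **Merge handling.** When two active tracks come within `merge_distance`
   (5 px), the younger terminates. This is a deterministic tie-break for
   collisions; after the cells separate, re-detection restores the lost
   identity under a new ID.

Tracks shorter than `min_track_length` (0.5 s of frames) are discarded;
very short fragments carry too little of a beat cycle for stable
kinematics. All tracker constants are exposed in `tracker_config()`;
they were chosen once on simulated scenes at the package's default imaging
geometry and are not tuned per video.

Identity switches between crossing cells are the dominant residual failure
mode, exactly as in commercial CASA systems, and they grow with cell
density. The package's default synthetic scene therefore places 200 cells
in a 666 x 666 um field (~23 M/mL at 20 um chamber depth), inside the
concentration range where collision artefacts are rare; denser scenes are
possible but increasingly trade tracking fidelity, which is the documented
reason clinical protocols dilute concentrated samples.

## Kinematics

All kinematics are computed in physical units after `to_microns()`; pixels
exist only inside the tracker. For a track sampled at `fps`:

* **VSL** is the first-to-last point distance over the duration; **VCL**
  the polyline length over the duration. `VCL >= VSL` holds exactly.
* The **average path** is a centered moving average applied after
  extending the track by odd (point-symmetric) reflection about its end
  points, so the full window applies everywhere. This boundary rule keeps
  the output the same length, preserves the end points exactly (so
  `VAP >= VSL` by construction), and leaves straight paths unchanged.
  The alternative of shrinking the window towards the ends leaves the raw
  beat oscillation in the path ends, which inflates the smoothed path
  length — and hence VAP — by tens of percent for slow cells with vigorous
  beats. **VAP** is the smoothed polyline length over the duration,
  clamped into `[VSL, VCL]` at the 1e-9 relative level to absorb
  floating-point rounding.
* **ALH~max~** is the maximum perpendicular distance from a raw sample to
  the nearest segment of the smoothed polyline (point-to-segment, not
  point-to-point, which would overestimate on sparse paths). Within half a
  window of the track ends the average path is ill-determined — any
  boundary rule distorts it there — so the maximum is taken over the
  interior samples, with distances still measured against the full
  polyline. ALH~max~ is the maximum deviation itself, not twice it: some
  commercial devices report the doubled "riband width", so cross-device
  comparisons must check this convention.
* **BCF** counts sign changes of the signed lateral offset (computed
  against the local tangent of the smoothed segment at the same arc index)
  per second. A sinusoidal beat of frequency $f_b$ crosses its average path
  twice per cycle, so a clean oscillator reports $2 f_b$. Zero offsets
  inherit the previous sign. Two reporting rules apply: cells with
  VSL <= 2 um/s report no BCF (at such low progression the instantaneous
  and average paths barely separate, and crossing counts are dominated by
  noise), and reported values are capped at the Nyquist frequency fps/2,
  above which a crossing rate is an alias rather than a beat.

### The smoothing window

The only genuinely open numerical choice is the moving-average window. A
window much shorter than one beat period leaves most of the oscillation in
the "average" path: at 60 fps a 5-frame window retains ~75% of a 5 Hz
sinusoid (the attenuation of an N-point average at frequency f is
$\sin(N \omega / 2) / (N \sin(\omega/2))$, $\omega = 2\pi f / \mathrm{fps}$),
which would bias ALH~max~ low by the same amount. A window spanning a
whole number of beat periods nearly annihilates the oscillation, and the
residual at two periods is about half that at one. Since the beat
frequency varies cell to cell, the default
(`path_config(smoothing_window = NULL)`) selects the window per track: a
pilot window of 0.2 s estimates the crossing rate, and the final window is
the odd frame count nearest two estimated beat periods (clamped to
[5, n]). With a 4--10 Hz beat at 60 fps this keeps the median ALH~max~
error under 5% and BCF within 1 Hz of truth. A fixed odd
window can be supplied instead, and `select_smoothing_window()` exposes the
choice. Note that BCF itself is nearly insensitive to the window (a linear
smoother scales a sinusoidal offset without moving its zero crossings);
the window matters for ALH~max~ and VAP.

Tightly circling cells (radius of a few microns) remain a documented
limitation: a moving average shrinks small circles, inflating the apparent
lateral deviation and VAP error. These cells are almost always in the
non-progressive grade, where BCF is suppressed by the VSL rule and grading
depends only on VSL, so the headline outputs are unaffected.

## Grading and concentration

WHO6 grade boundaries act on VSL with both boundaries inclusive on their
lower side: rapid progressive VSL >= 25 um/s, slow progressive
5 <= VSL < 25, non-progressive VSL < 5. "No active movement" is made
operational as maximum excursion from the starting point < 2 um together
with VCL < 10 um/s; both constants are configurable, and because IM and NP
are merged in reports the choice does not move the three-way split.
Percentages are computed over all cells with retained tracks; cells tracked
for only part of the video contribute their fragment (their VSL is a rate,
so fragment length mostly cancels).

Concentration estimation follows the counting protocol: the mean number of
distinct tracked cells over the first 10 frames (averaged over two
recordings when both chambers of a slide are filmed) is mapped through an
OLS line `concentration = slope * count + intercept` fitted on a dilution
series with reference (hemocytometer) concentrations. Counts may be
fractional and are never rounded before the affine map; estimates are
floored at zero.

## Agreement statistics

`fit_linear_calibration()` fits `reference = slope * model + intercept` on
paired single-cell values — the direction matters: the model output is
corrected toward the reference method. `apply_calibration()` maps profiles
affinely, leaves non-reported BCF missing, and by default calibrates LIN
directly like every other parameter (recomputing it from calibrated
VSL/VCL is available via `lin_mode = "recompute"`; the two differ only
through the regression residuals). R^2^ is the squared Pearson correlation,
which for simple OLS with intercept equals the regression R^2^, so the
distinction is moot here. `bland_altman()` uses the sample SD (n-1) of the
differences; the default limit multiplier is 1.96, with small-n studies
often preferring the two-sided 97.5% t-quantile (2.12 at n = 16) — both are
supported via `multiplier`. Repeatability of duplicate measurements uses
the symmetric percentage difference `100 |m1 - m2| / mean(m1, m2)`,
aggregated at full precision before any rounding.

## The simulator: what it does and does not emulate

`simulate_cells()` draws cells per requested grade with uniformly
distributed motion parameters (progressive speed 27--60, 6--24, 0.5--4.5
um/s for rapid/slow/non-progressive; lateral amplitude 0.3--3.5 um; beat
frequency 3--10 Hz; occasional path curvature, including the tight circles
of poorly progressive cells), rejection-sampling until the realised true
VSL falls inside the requested grade interval, and places each cell so its
whole trajectory stays in the field with a minimum start separation.
Motion is a smooth average path (straight or constant-curvature arc
traversed at constant speed) plus a pure sinusoidal lateral head
oscillation — chosen because it yields closed-form ground truth: ALH~max~
equals the amplitude, the crossing rate equals twice the beat frequency,
VAP equals the progressive speed, VSL comes from the closed-form endpoints
and VCL from dense quadrature (10x oversampling by default; 10x and 100x
agree to 0.1%).

`render_video()` draws each head as an isotropic Gaussian blob (no tail:
the tracker follows head centroids, and tails would only matter for a
detector that keys on them), adds low-contrast slowly drifting debris
blobs as confusers for the corner detector, additive Gaussian noise, and
8-bit quantisation — 8 bits makes brightness saturation well defined for
the perturbation operator. Camera bit depth and noise statistics of real
recorders are not published for the reference datasets, so the defaults
(background 15, head amplitude 140--180, noise SD 5) are declared choices,
not inferences. The simulator does not attempt photorealistic phase
contrast, flagellar hydrodynamics, three-dimensional motion, or
cell-cell hydrodynamic interactions; passing its tests demonstrates
correctness of the measurement chain on well-specified motion under
realistic contrast and noise, not performance on any particular clinical
recorder.

Determinism is strict: the same `sim_config()` (including `rng_seed`)
yields bit-identical videos and ground truth, and the analysis pipeline
itself is RNG-free, so repeated runs of `run_pipeline()` are byte-identical.

## Validation scales used by the test suite

The test suite validates on scenes small enough to run in minutes on one
core: unit scenes of 120 x 120 um with ~8 cells and 1 s of video; a
kinematic-recovery panel of 100 motile cells at 60 fps for 2 s (median
absolute relative error of VSL/VCL/VAP below 5%, ALH~max~ within 15%, BCF
within 1 Hz of twice the beat frequency); and one full-scale robustness
scene of 200 cells at 60 fps for 2 s in the 666 um field, analysed
unmodified, at +10% brightness, and mirrored, where the mean percentage
difference across concentration and the three grade percentages stays
below 2%. The same robustness computation, preceded by an 11-point
simulated dilution series for the concentration calibration, is what
`scripts/acceptance.R` reruns end to end.

## Known limitations

* Identity switches between crossing cells at high density; mitigated but
  not eliminated by forward-backward checks and merge handling.
* ALH~max~ and VAP bias for tightly circling cells (average-path
  shrinkage).
* BCF is undefined above the Nyquist rate; 60 fps recording limits
  reportable beats to 30 Hz.
* AVI containers are not read; use multi-page TIFF or a frame directory.
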