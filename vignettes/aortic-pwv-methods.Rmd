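---
title: "Aortic pulse wave velocity: models, estimators and the synthetic validation cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aortic pulse wave velocity: models, estimators and the synthetic validation cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aortapwv)
```

## The measurement problem

Aortic pulse wave velocity (PWV) — the propagation speed of the systolic
pressure/flow wave front along the aorta — is the reference biomarker of
aortic stiffness. This package implements the foot-to-foot transit-time
estimation chain for three acquisition routes and the model that ties wave
speed to vessel compliance:

* **Catheter pullback (pressure).** An intravascular pressure catheter is
  withdrawn stepwise along the aorta, recording pressure at positions
  5.8 cm apart, at 2 kHz, over at least 10 cardiac cycles per position.
  PWV = $\Delta x / \Delta t$, with $\Delta t$ the transit time of the
  systolic wave front between sites.
* **Through-plane velocity-encoded MR.** One acquisition plane transects
  the ascending (site 1) and proximal descending (site 2) aorta; the
  maximal velocity-time curve in each lumen gives one onset per site and a
  two-site transit time.
* **In-plane velocity-encoded MR.** Two in-plane velocity components (AP
  and FH) are acquired over the arch. The lumen is contoured once, a
  centerline is extracted, 200 equidistant chords perpendicular to the
  centerline sample the velocity projected onto the local flow direction,
  and the 200 onset times are regressed on arc length; PWV is the inverse
  slope of that distance–time line.

The compliance model is the Bramwell–Hill relation

$$\mathrm{PWV} = (\rho \, D)^{-1/2}, \qquad
  D = \frac{\Delta A}{A_\mathrm{min}\,\Delta P},$$

with $\rho = 1059\ \mathrm{kg\,m^{-3}}$ the blood density, $\Delta A$ the
systolic–diastolic lumen area change, $A_\mathrm{min}$ the minimal area and
$\Delta P$ the local pulse pressure (1 mmHg = 133.322 Pa). The luminal-area
form substitutes area for volume per unit length; the package adopts it as
given. `distensibility()`, `theoretical_pwv()` and
`pulse_pressure_from_pwv()` implement the model and its algebraic inverse;
the three compose to an exact roundtrip, which the test suite checks to
1e-12 relative on 1000 random inputs.

## Onset ("foot") detection

The velocity foot is the intersection of two lines: a horizontal baseline
modelling the constant diastolic flow, and a least-squares line through the
systolic upslope samples whose values lie within 20% and 80% of the
trough-to-peak range. Decisions the published recipe leaves open, resolved
here as module policy:

* **Rising limb.** The cycle peak is found first (ties: earliest sample).
  The *pre-systolic trough* is operationalized as the last point at trough
  level (within 5% of the range) cyclically before the peak; the rising
  limb runs from there to the peak. Anchoring the limb at the last
  at-trough-level point rather than at the global minimum matters under
  noise: the global minimum of a noisy cycle can fall anywhere in diastole,
  and a limb started there can pull the baseline window into the decay.
* **Baseline.** Median of the samples in the cyclic window covering the
  final 20% of the R-R interval before the pre-systolic trough — a robust
  plateau estimate that ignores the dicrotic limb.
* **Band membership and threshold crossings.** The 20% and 80% threshold
  crossing times are found by linear interpolation and *included as fit
  points* together with the in-band samples. At 35 phases per cycle the
  band typically holds only two samples, so the crossings are what keep the
  fit determined (three or more points). A crossing is used only when its
  bracketing segment lies wholly on the upslope: the lower anchor must sit
  clearly above the diastolic plateau and the upper anchor must not be the
  limb's peak sample. Without this rule, a segment interpolated across the
  foot or peak corner biases the fitted line by about a millisecond at 35
  phases/cycle — and because that bias is a smooth function of where the
  foot falls relative to the phase grid, it varies systematically along the
  aorta and can rotate the 200-chord distance–time regression by more than
  10%. If the strict rules leave fewer than three points, the unrestricted
  crossings are re-admitted: a mildly biased foot is preferable to an
  undetectable one.
* **Sub-sample onsets** are real-valued; nothing is snapped to the grid.
* **Noise floor.** A cycle whose trough-to-peak range is below 5% of its
  absolute maximum is flat (`NoUpslopeError`).

The pressure foot is simpler: the minimum sample between cycle start and
the systolic peak (ties: earliest), matching the minimal-pressure-before-
upslope rule; it is therefore quantized to the 0.5 ms sampling grid. Per
site the per-cycle onsets are aggregated by their median (the recipe is
silent; the median is robust to an occasional mis-detected beat, and the
mean is available behind a flag).

## PWV estimators

`two_site_pwv()` is the plain quotient with a sign contract (the downstream
onset must lag the upstream one). `multi_site_pwv()` is the ordinary
least-squares fit of onset time on arc position with PWV = 1/slope —
weighted or robust variants are deliberately out of scope; chords whose
onset detection fails are excluded and counted. `pullback_pwv()` maps the
pullback recordings to these two estimators: regional mode snaps the two
requested sites to the nearest recordings (at most half a 5.8 cm step
away), local mode regresses over all recordings within 5.8 cm of the
requested center — an 11.6 cm trajectory containing three grid positions.
Whether the published local pressure PWV used the two outer pullback points
or all three is not stated; the regression over all in-window sites is the
default here, consistent with the multi-site treatment of the in-plane
data.

## Geometry

`centerline_from_contour()` rasterizes the lumen polygon at 0.5 mm,
weights each interior pixel by its exact Euclidean distance to the polygon
boundary, and finds the minimum-cost 8-connected path between the pixels
nearest the two endpoint hints with edge cost
$\text{step}/\bar d^{\,2}$ — the cheapest path rides the distance-transform
medial ridge. The path is smoothed (moving average, window 9, reflective
ends so the endpoints stay put) and resampled to uniform arc spacing;
tangents come from ±3-point central secants so isolated raster kinks do not
tilt the chords. On analytic shapes the result is accurate to a fraction of
a pixel: the midline of a 100 × 20 mm band to < 0.5 mm Hausdorff, the
medial arc of a 30/50 mm half-annulus to < 1 mm.

`sample_chords()` places *n* chords at arc fractions $k/(n-1)$ (endpoints
included; $n = 1$ degenerates to $s = 0$), each the maximal segment through
its centerline point perpendicular to the local tangent, clipped to the
polygon. `chord_velocity_curves()` samples both in-plane components at
0.5 mm steps along each chord by bilinear interpolation, projects onto the
chord's centerline direction (signed, so retrograde or aliased pixels are
not rectified into the maximum), and takes the per-phase maximum of the
signed projection. Contours, maps and chords share one planar mm frame with
the origin at the top-left pixel center, rows along AP, columns along FH.
Lumen areas are shoelace polygon areas per phase; the distension summary is
$\Delta A = A_{\max} - A_{\min}$ and $A_\mathrm{min}$.

## The synthetic cohort

`simulate_cohort()` generates the study the estimators are validated on —
17 subjects by default, with per-subject truths drawn around the
population scales of the emulated cohort: local PWV
$\mathcal N(7.0, 1.6^2)$ m/s truncated at 3 m/s, aortic pulse pressure
$\mathcal N(53, 15^2)$ mmHg truncated at 20 (129/76 mmHg brachial
pressures), minimal lumen area $\mathcal N(450, 80^2)$ mm² truncated at
200, R-R $\mathcal N(0.95, 0.08^2)$ s. The synthetic world is exactly
Bramwell–Hill-consistent: $D = 1/(\rho\,\mathrm{PWV}_\mathrm{local}^2)$ by
construction, so model-recovery error isolates pipeline error (a
`model_violation_sd` knob perturbs the generating $D$ multiplicatively when
realistic model scatter is wanted).

Design choices that deserve justification:

* **Waveform template.** The upstroke rises *linearly* from foot to unit
  peak over 0.10 R-R, so the whole 20–80% band lies on one straight line
  whose baseline intersection *is* the configured foot — foot detection is
  well posed and, in the noiseless limit, exact even at 35 phases/cycle.
  A raised-cosine upstroke would place the band-line's baseline
  intersection well after the true foot and make "truth" ill-defined. The
  decay is a raised cosine with a dicrotic bump; the pressure variant
  decays over the whole diastole and reaches the diastolic level exactly at
  the next foot, so the pre-upslope minimum falls at the foot as the
  pressure detector assumes.
* **Wavefront.** Onset times follow a piecewise-constant speed field:
  the regional (arch) speed up to the start of the 11.6 cm local
  trajectory, the local speed beyond it
  (`regional_local_pwv_ratio` = 0.95). Reference values for regional
  comparisons come from `true_onset_time()` / `true_two_site_pwv()`, not
  from the regional speed alone.
* **Beat-to-beat timing.** ECG triggers in the pressure recordings carry
  2% R-R variability (sinus arrhythmia) and each cycle's foot is jittered
  by `onset_jitter_sd_s` (2 ms, respiratory modulation of the ejection
  delay; a larger value is inconsistent with the emulated study's printed
  local correlation, since noise in the pressure reference alone caps the
  attainable r). The R-R variability also matters numerically: it guarantees the
  0.5 ms argmin quantization of the pressure foot dithers across the
  10 cycles, so the per-site median converges; a perfectly metronomic
  heart whose R-R is commensurate with the sampling grid would freeze the
  quantization error.
* **Velocity noise.** 0.015 m/s additive per sample (~1% of the 1.5 m/s
  encoding limit, typical phase-contrast noise at good SNR). An early
  draft used 0.05 m/s; at 35 phases/cycle that makes per-site onset noise
  comparable to half the arch transit time, two-site transit times change
  sign and the estimator diverges for much of the cohort — a degenerate
  world unlike the finite dispersion the method-comparison statistics of
  the emulated study report.
* **Cuff bias.** The brachial-cuff pulse pressure is drawn 8 mmHg *below*
  the aortic value (noise SD 4 mmHg). The sign follows the emulated
  study's finding: its modeled PWV from cuff pressures underestimated the
  pressure-assessed PWV more than the catheter-based one, and since the
  modeled PWV is strictly increasing in the pulse pressure plugged into
  the distensibility, that direction requires the cuff to under-read the
  central pulse pressure in this (older, cardiac) population.
* **Area series.** $A(t) = A_\mathrm{min}(1 + D\,\Delta P(t) \cdot
  133.322)$ with the distension waveform normalized to its sampled maximum
  and a flat zero diastole, so the emitted series attains both
  $A_\mathrm{min}$ and $A_\mathrm{min} + \Delta A$ exactly at sampled
  phases and the distensibility recovered from the series is exact in the
  noiseless limit rather than biased by phase-grid truncation.
* **Velocity amplitude** is 1.0 m/s scaled ±20% per subject; the
  foot-to-foot method is amplitude-scale invariant, and the suite verifies
  that.

`rasterize_maps()` additionally builds a pixel-level phantom — a
half-annulus arch (centerline radius 35 mm, lumen width 20 mm) joined to a
straight descending segment, parabolic cross-lumen profile, per-pixel
velocity along the local tangent with delay $s/\mathrm{PWV}$, split into
AP/FH components and clipped to venc = 1.5 m/s — to exercise the full
geometry pipeline from contours to PWV.

What the generator does *not* emulate: reflected-wave physics and
wave-reflection separation (the foot-to-foot method is chosen precisely for
its insensitivity to reflections), Windkessel or PDE hemodynamics, MR
k-space noise, phase aliasing, arrhythmia, and real contour-segmentation
error. Passing recovery tests therefore demonstrates correctness of the
estimation chain under the stated sampling and noise structure, not
clinical performance on real images.

## Validation summary and problem sizes

The acceptance script (`scripts/acceptance.R`) recomputes, from scratch at
a caller-supplied seed: the t-based 95% CI reconstruction from printed
summary statistics; the 1 µs foot-detection oracle on 100 cycles; noiseless
recovery on a 17-subject cohort (catheter pullback, local multi-site, and
the rasterized phantom end to end); the Bramwell–Hill roundtrip and
distensibility recovery; the agreement hand checks and Bland–Altman
coverage at n = 10 000; and a 50-cohort directional sweep (local in-plane
vs through-plane correlation ordering; cuff vs catheter underestimation
ordering). These sizes — 17 subjects, 10 pressure cycles at 2 kHz, 35 CMR
phases, 200 chords, 50 seeds — are the study conditions the generator
encodes; the whole script runs in a few minutes on one core.

Known limitations: the centerline is planar (the three-slice stack of the
emulated protocol is treated as one composite plane); onset detection at
35 phases has an irreducible quantization wiggle of order 1 ms for noisy
data; the pressure foot is grid-quantized by construction; `agreement()`
assumes one measurement per subject per method (no repeated-measures
extension); and no multiple-testing correction is applied anywhere, by
design.
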