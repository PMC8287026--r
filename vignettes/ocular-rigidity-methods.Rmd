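---
title: "Measuring ocular rigidity from dynamic OCT: models and methods"
author: "ocupulse authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring ocular rigidity from dynamic OCT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ocupulse)
```

## The measurement problem

With every heartbeat, pulsatile vascular filling transiently thickens the
choroid. On a dynamic OCT B-scan video of the optic nerve head this
appears as a periodic, micrometre-scale oscillation of the distance
between the posterior retinal pigment epithelium (RPE) and the
choroidal-scleral interface (CSI). Because most ocular blood flow passes
through the choroid, the amplitude of this oscillation — the mean
peak-to-valley choroidal thickness change, `delta-t` — is a usable proxy
for the pulsatile ocular volume change `dV`. Combined with the ocular
pulse amplitude (OPA) and diastolic IOP from dynamic contour tonometry,
Friedenwald's empirical pressure-volume relation

    ln(IOP1) - ln(IOP2) = k * dV,   IOP1 = IOP + OPA,  IOP2 = IOP

yields the ocular rigidity coefficient `k` (1/uL) without cannulating the
eye. `ocupulse` implements the full chain: segmentation, waveform
analysis, the biomechanical closed forms, and the cohort statistics,
together with a synthetic-data generator that provides ground truth for
every stage.

## Segmentation

Each frame is processed independently; the temporal structure is handled
later, in the waveform stage.

1. **RPE detection.** Per A-scan, the brightest band is located on a
   laterally (7 columns) and axially (5 px) smoothed copy; the posterior
   edge is the last pixel whose laterally-smoothed intensity stays within
   70% of the band peak measured above the column floor, so detection is
   invariant to intensity offsets. The edge profile is median-filtered
   across A-scans (window 15). Two usability guards reject frames: fewer
   than half the included columns showing a band, and an incoherent edge
   profile (median absolute change above 8 px between columns spaced one
   lateral window apart — pure-noise frames fail this even though their
   laterally-smoothed neighbours agree trivially).
2. **Flattening.** Each side of the optic-nerve gap is shifted per
   A-scan so its posterior RPE lands on that side's median reference row.
   The optic-nerve region itself is never detected; its bounds come from
   the acquisition sidecar and its pixel content never influences any
   result (lateral smoothing stops at the gap).
3. **Candidate nodes.** Along each A-scan below the RPE, candidates are
   the depths where the second difference of the Gaussian-smoothed
   (sigma 2 px) profile crosses from positive to negative with a positive
   first difference — the centre of a dark-to-bright transition, the
   signature of leaving a choroidal vessel for the sclera. Crossings that
   merely touch zero are kept (the sign is carried through exact-zero
   runs); gradients below `1e-7` of the frame's dynamic range are
   discarded as floating-point noise.
4. **Graph search.** One node per column is selected by a minimum-cost
   left-to-right dynamic program. Node cost is `2 - g + 1e-6` with `g`
   the min-max-normalized gradient, so strong boundaries are cheap;
   transitions with depth change above `maxJumpPx` (default 15 px,
   scaled by the gap width when columns are skipped) are forbidden.
   Columns whose candidates are all unreachable are dropped and bridged
   by linear interpolation — an isolated spurious candidate cannot drag
   the surface. On small instances the program provably returns the
   same cost as exhaustive path enumeration; the test suite checks this
   against an independent enumerator.
5. **Thickness.** ChT is the mean over included columns of
   `(CSI - RPE) * axial spacing`, in micrometres.

## Waveform analysis

The per-frame (time, ChT) series is irregular: the eye tracker pauses
acquisition when it loses the target. The processing chain is:

1. **Outlier removal**: points beyond 3 scaled MADs
   (1.4826 x median absolute deviation, the Gaussian-consistent scale)
   from the median are discarded. A zero-MAD series is left unchanged.
   The scaled form is a package choice; the raw-MAD variant corresponds
   to `nMads` about 4.4.
2. **Uniform resampling**: linear interpolation onto a grid at
   `max(4 x hiMult x hrMax, median input rate)` Hz, followed by a
   zero-phase (forward-backward) FIR low-pass, applied around the series
   mean with odd-reflection padding so record edges carry no transient.
   Zero-phase application is what makes the net group delay zero.
   Input gaps wider than 3x the median spacing are recorded: samples in
   them are interpolation, not observation.
3. **Heart rate**: the peak of a Hann-windowed, zero-padded periodogram
   within 0.7-2.0 Hz. A Bonferroni-corrected harmonic F-test of the
   best-fitting sinusoid at that frequency guards against flat spectra:
   on white noise the guard fires with ~95% probability, while genuine
   cardiac tones pass at astronomical significance. (A peak-versus-
   band-median rule was evaluated first and accepts pure white noise
   most of the time on 5 s records, which have only ~7 independent
   in-band Fourier bins; Fisher's g-test fails when the tone falls
   between bins. The F-test at the continuously-estimated frequency has
   neither defect.) An explicitly supplied heart rate always takes
   precedence, since the instrument that measured it is more reliable
   than any re-estimate.
4. **Band-pass**: the DFT coefficients outside 0.5-3.0x the heart rate
   (both frequency signs) are zeroed and the inverse transform taken,
   after removal of the series mean. By default no window is applied:
   the ideal mask is then exactly transparent for in-band content and
   annihilates out-of-band tones to numerical precision. An optional
   Tukey pre-window (`tukeyAlpha`) is available, but measurement showed
   it *introduces* in-band leakage from large low-frequency drift
   (about 4 um rms for a 20 um drift tone at these record lengths)
   while improving nothing else, so transparency won.
5. **Peak-to-valley**: local extrema are found, oscillations smaller
   than 25% of the filtered signal's standard deviation are merged away,
   and `delta-t` is the mean of (peak minus following valley) over
   complete cycles. Cycles are excluded when they overlap (a) an input
   gap longer than a quarter cardiac period, dilated by half a period to
   cover the ideal-mask filter's ringing, or (b) the record edges
   (a quarter period, plus the taper zone if a window was used). This
   exclusion matters: a single 0.5 s tracker pause, linearly
   interpolated, otherwise flattens one to two cardiac cycles and biases
   `delta-t` downward by ~14%; with the exclusion the bias is below 5%.
   A trailing peak without a following valley is likewise excluded.
   When the exclusion would leave no complete cycle at all (short
   records with several pauses), the estimator degrades gracefully —
   first dropping the gap exclusion, then the edge exclusion — and
   records which level was applied in the result's parameters
   (`cycleExclusion`), so downstream users can treat such estimates
   with appropriate caution.

## Biomechanical closed forms

- `dV = 4 pi R^2 dt` with `R = AL/2` (thin spherical shell) is the
  default; the exact two-sphere difference
  `(4/3) pi ((R+dt)^3 - R^3)` is selectable (`volumeModel = "exact"`).
  At physiological scales they differ by well under 0.1%.
- `k = log1p(OPA/IOP) / dV`.
- Corneal and scleral stiffness from air-puff deformation exports:
  `SP-A1 = (AP1_adj - bIOP) / dA1` and
  `SP-HC = (AP1_adj - bIOP) / (dHC - dA1)`.
- `P/V = IOP / ACV`.
- Axial length, when not measured, comes from a simplified paraxial
  schematic eye: corneal power `(n - 1)/r` with `n = 4/3` from the
  measured radius, a thin internal lens (21.76 D, 5.70 mm behind the
  cornea), and the axial-ametropia assumption that the far-point
  vergence equals the spherical-equivalent refraction. The constants
  live in one configuration block (`schematicEyeConstants()`), and the
  chain carries an additive calibration so the emmetropic reference eye
  (r = 7.80 mm) returns exactly 23.89 mm. Only the calibration anchor
  and the monotonicities (myopes longer, steep corneas shorter) are
  relied on; derived lengths are a fallback, flagged `schematic_eye` in
  the output. The single `delta-t` from one B-scan is applied globally —
  the spherical-shell simplification inherent to the method.

## The synthetic-data generator

`simulateBScans()` emulates the acquisition: 599 frames over a nominal
4-7 s (default 6 s), layered A-scans (dark vitreous, retina, bright RPE
band, mid-dark choroid with smooth vessel texture, brighter sclera), a
choroid pulsating as `baseline + A sin(2 pi HR t) + drift`, a linear RPE
tilt, an unlayered central band standing in for the optic nerve head
(bounds written to the sidecar, exactly as the clinical protocol masks
rather than detects it), tracker pauses, and multiplicative log-normal
speckle. Defaults: 300 um baseline, 5 um pulse amplitude at 1.2 Hz
(so the true peak-to-valley is 10 um), 2 um drift at 0.1 Hz, tilt
0.05 px/A-scan, speckle sigma 0.3, axial spacing 3.87 um/px (a
configurable assumption, not an asserted device constant). The vessel
field is generated once per sequence — vessels are anatomy, and
re-randomizing them per frame would inject thickness jitter no real
acquisition has. Ground truth records the noise-free ChT per frame, the
exact depth maps, and the mean peak-to-valley of the noise-free
pulsatile signal evaluated on a dense grid (exactly `2A` for a pure
sinusoid).

What the generator does *not* model: physically realistic OCT speckle
statistics, eye-motion artifacts other than pauses and tilt, and
peripapillary atrophy. Passing the recovery tests therefore shows the
pipeline is correct under idealized optics and stationarity; it does not
certify performance on pathological clinical scans.

`simulateCohort()` draws `(k, AL, ACV, OPA, SP-A1, SP-HC)` per subject
from a multivariate Gaussian whose means, SDs and correlation structure
default to the published control/glaucoma cohort characteristics, and
back-computes `delta-t` from the exact Friedenwald relation so that
recomputing `k` from the table reproduces the generating value to
floating precision. Drawing OPA (rather than `delta-t`) from the joint
distribution is what lets the full 6x6 target correlation matrix be
honoured while keeping the algebraic round-trip exact. Corvis quantities
are constructed to be internally consistent with the drawn stiffness
parameters. Physiological floor guards (`k >= 0.002`, `OPA >= 0.2` mmHg,
...) sit several SDs from the means and leave the correlation structure
intact.

## Statistics

Group comparisons use the two-sided Mann-Whitney U test (exact by
enumeration when both groups have at most 8 observations and no ties;
otherwise the normal approximation with tie and continuity corrections),
normality the Shapiro-Wilk test, paired agreement the paired t-test and
Bland-Altman limits `bias +/- 1.96 sd`, and associations Pearson
correlation with the two-sided t-transform p-value. Missing values are
deleted listwise per statistic and the per-cell n is always reported. No
multiple-testing correction is applied by default, matching per-variable
uncorrected reporting; `statsControl(adjust = "holm")` enables Holm
adjustment.

## Numerical choices and degenerate inputs

- Coordinates are 0-based with depth increasing away from the vitreous;
  column intervals are half-open `[lo, hi)`, shared with the JSON
  sidecar format.
- Constant series: zero MAD keeps all points; zero variance is an error
  for correlation, paired t and Shapiro-Wilk.
- A frame with no detectable bright band, no feasible CSI path, or no
  column carrying both depths is dropped with a logged reason; fewer
  than two usable frames aborts the pipeline.
- Ties in the graph search are broken by the `1e-6` cost floor plus the
  order of dynamic-programming minima, which is deterministic.
- Configuration parsing is strict: unknown keys are an error, so the
  pinned constants (3 MADs, 0.5-3x heart rate, thin-shell `dV`) cannot
  drift silently through typos.

## Problem sizes used by the test-suite and acceptance script

Unit tests run on stacks of 2-20 frames (100-120 columns); recovery
checks use 100-150 frames over 4-5 s, and the end-to-end study simulates
50 subjects at 100 frames each plus a 500-subject tabular cohort. These
sizes give sub-pixel segmentation error and stable `delta-t` statistics
while keeping a full run in a few minutes on one CPU; the method's
accuracy does not improve materially with larger frames because the
per-frame ChT error is already dominated by axial quantization.

## Known limitations

- The rigidity estimate inherits every simplification of the chain:
  spherical eye, global `delta-t`, choroidal volume change as the whole
  ocular volume change.
- The heart-rate estimator assumes a single dominant cardiac tone;
  arrhythmia or strong harmonics favour supplying the rate explicitly.
- The segmentation targets the peripapillary geometry the simulator
  emulates: one RPE band, one CSI, moderate tilt. Macular scans, strong
  curvature, or atrophic disruption are out of scope.
- The graph search optimizes per-frame; it does not enforce temporal
  smoothness of the CSI across frames (by design — the temporal
  filtering happens in the waveform domain).
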