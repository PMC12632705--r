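---
title: "Methods: autonomous Doppler tracking, envelope extraction and monitoring analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: autonomous Doppler tracking, envelope extraction and monitoring analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetodoppler)
```

This vignette documents the models, conventions and numerical choices behind
`fetodoppler`, in the spirit of a methods section: what each stage assumes,
which parameters matter, and what the built-in simulator does and does not
emulate.

## The synthetic duplex scene

The simulator works in the reconstructed image domain: each frame is a pair
of co-registered grids, a B-mode greyscale image and a colour-Doppler
velocity map. Radio-frequency simulation, beamforming and plane-wave
compounding are deliberately out of scope — the tracking algorithm consumes
images, so images are what the simulator produces.

The scene contains a pulsatile artery and a steady vein, a rigid pair moving
through the field. Conventions, stated once and used everywhere:

* lateral = mm from the left field edge, axial = depth in mm from the
  transducer face, both at pixel centres with 0-based indexing;
* flow toward the transducer is positive; colour velocities alias (wrap) at
  the configured Nyquist velocity;
* sound speed fixed at 1540 m/s, the soft-tissue convention;
* default acquisition constants: carrier 2.5 MHz, PRF 3000 Hz, 2-mm sample
  gate, 20 frames/s. The Nyquist velocity at these constants and zero
  insonation angle is `nyquist_velocity(3000, 2.5)` = 46.2 cm/s. The duplex
  frame rate is a free parameter; 20 frames/s is a realistic default for a
  wide-view colour acquisition.

The umbilical-artery waveform is a periodic cycle with a raised-cosine
systolic upstroke (30% of the cycle by default) and a shifted-exponential
diastolic decay (rate 3). Two properties are enforced by construction: the
per-cycle maximum equals the specified PSV and the cycle-end value equals
the specified EDV exactly (the nearest samples are pinned to the analytic
extrema), so downstream estimators can be scored against exact ground
truth. The upstroke of each beat rises from the *previous* beat's EDV, so
the waveform is continuous across beats even when individual beats carry
absent (0) or reversed (negative) end-diastolic flow. With the default
shape, an S/D ratio of 2.61 implies RI 0.617 and PI 1.033 — the
internally consistent triple for a healthy third-trimester profile.
Absent-EDV beats are assigned deterministically: exactly
`round(fraction * n)` beats, chosen by a seeded draw.

The B-mode channel is gamma-distributed speckle with darker vessel lumina;
colour pixels carry the instantaneous waveform velocity (artery), a
constant opposite-sign velocity (vein), or zero-mean Gaussian noise
(background, default SD 2 cm/s). What the simulator does **not** emulate:
anatomical clutter, maternal tissue layers, attenuation with depth,
wall-filter artefacts, out-of-plane motion, or uterine contractions. Tests
passing on these scenes therefore demonstrate the algorithmic contract —
variance-based segmentation finds a pulsatile target among non-pulsatile
structures, and the envelope chain inverts the simulator's own spectral
model — not performance on clinical images.

One user-facing seed drives everything; per-stage sub-seeds are derived
deterministically from it, so identical seed + configuration reproduces all
arrays and CSV artifacts byte for byte.

## Autonomous tracking

The tracker exploits the one physical invariant that separates an artery
from everything else in colour Doppler: its pixel intensities pulse at the
cardiac frequency. Per pixel, the population variance of `|v|` is computed
over a sliding window of consecutive frames (default 10 frames = 0.5 s at
20 frames/s — at least one cardiac cycle for FHR ≥ 120 bpm). The magnitude
is used so that alias-induced sign flips still register as pulsatile
motion of the spectrum, not as cancellation.

The variance map is binarised, connected components are labelled
(8-connected by default), regions smaller than 20 px are discarded, and the
largest region is the primary one (ties: higher mean variance, then
shallower centroid). Its unweighted pixel centroid, converted to mm, is the
sample gate.

**Threshold policy.** Otsu's method on the variance map is the default. A
fraction-of-maximum policy (0.3) is also implemented, but it proved brittle
in exactly the regime the tracker exists for: when the vessel moves, pixels
at the lumen rim alternate between arterial velocity and background and
their temporal variance can exceed the lumen variance several-fold, so a
cut referenced to the map maximum floats above the lumen itself and the
target is lost intermittently. Otsu separates the (large, low-variance)
background population from the (small, high-variance) vessel population
regardless of the rim amplitude. Both policies are exposed and tested.

When no region survives, the tracker holds the last valid gate and flags
the frame `"lost"`, resuming on reacquisition — mirroring a
track-then-acquire duty cycle in which spectral acquisition happens at a
fixed gate between tracking updates.

Because the variance is computed over a trailing window, the gate estimates
the dwell-time-average vessel position across that window; against
per-frame ground truth this contributes a lag of at most half a window
(≤ 0.5 mm at the 2 mm/s motion cap used in the validation scenes).

## Envelope extraction and beat detection

The spectrogram synthesizer places a Gaussian ridge (broadening SD in cm/s)
at the alias-wrapped instantaneous velocity in each time column (default
column spacing 2 ms, 513 velocity bins so that zero velocity is a bin
centre), plus an optional constant noise floor and multiplicative speckle.

The envelope is traced per column as the velocity bin at which cumulative
above-floor power, accumulated from zero velocity outward on the
flow-direction side, reaches `power_fraction` (default 0.95) of that side's
total — a percentile-of-power rule that is invariant to uniform gain. The
flow side is the side holding the majority of above-floor power across the
run; columns whose power sits mostly on the opposite side (reversed or
aliased flow) are traced there with negative sign. Columns
indistinguishable from noise are flagged and set to zero. A moving median
(3 bins) suppresses isolated bin flips; the window is kept short because a
longer median visibly erodes the systolic peak.

Beats are delimited by systolic peaks (prominence-based picking, minimum
separation 60/FHR_max s, default band 60–240 bpm; out-of-band beats are
rejected). Per beat, PSV is the cycle maximum and EDV is the envelope value
at the *foot of the next systolic upstroke* rather than the cycle minimum —
robust to dicrotic notches and the correct end-diastolic instant. EDV at or
below 2 cm/s is flagged absent; negative EDV reversed. Absent-EDV beats
keep their RI (which is 1 at EDV = 0) but are excluded from S/D averages,
whose ratio is undefined there; this convention is what makes a cohort's
mean S/D and mean RI mutually consistent when a fraction of beats has no
end-diastolic flow.

FHR accelerations follow the standard cardiotocography definition — at
least 15 bpm above a rolling-median baseline (10-min window) sustained for
at least 15 s — since no alternative definition is standard for Doppler-
derived heart rate.

## Monitoring analytics

Beat streams are segmented into consecutive 10-minute intervals from the
record start; an incomplete trailing interval is dropped (a ~70-minute
recording yields exactly 7 segments). FHR variability is the within-segment
SD of per-beat FHR; alternatives (range, short-term variation) can be
layered on the per-beat table. Stratified condition summaries report
median, 25th/75th and 5th/95th percentiles with R's type-7 quantile rule
(linear interpolation between closest ranks), recorded in the output
metadata because percentile conventions differ across ecosystems. The
FHR-vs-PI association uses Spearman rank correlation with a seeded
permutation p-value, avoiding any normality assumption on per-segment
summaries.

## Agreement statistics

Bland–Altman limits use the sample SD (n−1) of the differences — the
convention of the original method — and 95% limits at ±1.96 SD. Replicated
pairs are pooled by default; a `by =` argument averages within subject
first for the conservative variant. Gate discrepancy applies the 2-mm
clinical criterion per axis (lateral, axial), with the Euclidean criterion
reported alongside as the stricter optional reading.

## QA and acoustic-output conventions

* Pixel spacing: extent divided by (pixel count − 1), per direction.
* FWHM: background defaults to the median of the outer 20% of the profile
  tails; crossings are linearly interpolated between samples; profiles with
  two separated equal maxima are rejected rather than guessed.
* CNR is computed on displayed (log-compressed) intensities, as phantom
  protocols specify for display-domain measurements.
* Dynamic range fits grey value against nominal contrast (grey-on-contrast)
  and reads the contrast span between extrapolated grey 255 and grey 0,
  i.e. 255/slope dB.
* Hydrophone sensitivity: `10^((M_dB + 120)/20)` V/Pa; loaded sensitivity
  applies the preamplifier gain (20 dB default) and the capacitive divider
  `C_H/(C_H + C_A + C_C)` with 70/7/1.6 pF defaults.
* Pulse duration for I_sppa is `1.25 × (t90 − t10)` of the cumulative
  pulse-intensity integral — the regulatory convention for "the interval
  containing 90% of the pulse energy", and the only reading under which a
  continuous wave has duty factor exactly 1 (so I_sppa = I_spta).
* Derating: 0.3 dB/(cm·MHz), the soft-tissue convention; pressures scale by
  `10^(−A/20)`, intensities by `10^(−A/10)`.
* Acoustic power integrates intensity over pixels within −26.2 dB of the
  plane peak (the beam cross-section definition used with hydrophone plane
  scans), times pixel area.

Thermal indices are intentionally not computed: they depend on standards-
body models whose inputs (beam geometry factors, bone models) are outside
this package's scope; only the acoustic-power input to them is provided.

## Fetal weight estimation

The Hadlock four-parameter regression is linear in `log10` of the weight in
grams; the package evaluates the polynomial, reports it as `log_weight`,
and exponentiates to grams. The printed coefficients (intercept 1.3596,
femur-length slope 0.174, ...) are the published log10-scale coefficients —
evaluating them at plausible biometry (BPD 8.5, HC 31, AC 30, FL 6.5 cm)
gives log-weight 3.364 and EFW ≈ 2311 g, a sensible third-trimester weight,
which would be nonsensical if the right-hand side were grams directly.

## Problem sizes and numerical tolerances

The test-suite and acceptance computations use sizes chosen to exercise
every code path while remaining quick to reproduce on a laptop: 10-second
waveforms at 500 Hz; spectrograms of 513 velocity bins × 2-ms columns;
scenes of 80 × 120 px (40 × 60 mm at 0.5 mm pitch) × 100 frames; ten seeded
sequences for the tracking-floor checks; and a 3 × 3 × 2 grid of FHR
(110/140/180 bpm) × S/D (2.0/2.6/5.1) × SNR (20/10 dB) for end-to-end
parameter recovery (S/D within 10%, RI within 0.05, FHR within 2 bpm).
Waveform generators pin per-cycle extrema exactly; identity-type invariants
(RI = 1 − 1/(S/D), sensitivity round-trips, variance-map equality with a
two-pass oracle) are asserted at 1e−10–1e−12; envelope accuracy is asserted
at the velocity-bin width, its natural resolution. Velocities stay below
the 46.2 cm/s Nyquist in spectral test scenarios unless aliasing itself is
the behaviour under test.

## Known limitations

* The simulator's cylindrical vessels and uniform lumen velocities are far
  simpler than clinical anatomy; tracking performance on these scenes is an
  upper bound, not a clinical claim.
* Continuous re-tracking *during* spectral acquisition is not modelled; the
  tracker holds the gate between updates.
* The envelope's percentile rule reads the upper edge of the spectral
  ridge; with heavy intrinsic broadening it overestimates PSV and EDV by
  ~1.6 × the broadening SD, which partially cancels in RI but not in S/D.
* Gestational-age reference percentiles for the indices are not bundled;
  stratified summaries are descriptive only.
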