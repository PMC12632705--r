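# fetodoppler

Continuous fetal monitoring with a wearable duplex-ultrasound patch needs
software that can (i) find and follow the umbilical artery in colour-Doppler
image sequences without a sonographer, (ii) turn spectral-Doppler
spectrograms into per-beat hemodynamics, and (iii) summarise hours of
recordings into clinically interpretable statistics. `fetodoppler` implements
that computational chain in R, together with a seeded simulator of duplex
scenes and umbilical-artery waveforms that provides ground truth for every
stage. It is aimed at researchers prototyping autonomous Doppler monitoring
pipelines and at anyone needing reference implementations of the associated
validation, quality-assurance and acoustic-output calculations.

## What it computes

**Autonomous vessel tracking.** Arterial pixels pulse over the cardiac cycle
while venous and background pixels do not. The tracker computes, per pixel,
the temporal variance of colour-Doppler intensity `|v|` over a sliding window
of consecutive frames, segments the pulsatile regions (Otsu threshold,
8-connected components), selects the primary (largest) region, and registers
its spatial centroid as the 2-mm spectral sample gate.

**Envelope and beats.** From a time × velocity power spectrogram the
maximum-velocity envelope is traced per time bin as the velocity at which the
cumulative above-floor power (from 0 outward on the flow-direction side)
reaches a configurable fraction (0.95). Systolic peaks give beats; each beat
yields PSV, EDV (envelope at the foot of the next systolic upstroke), TAV
(cycle mean) and FHR = 60/interval.

**Doppler indices.** For each beat,

    S/D = PSV / EDV        (flagged, not computed, when EDV <= 0)
    RI  = (PSV - EDV) / PSV
    PI  = (PSV - EDV) / TAV
    CPR = PI_MCA / PI_UA

and Hadlock-IV estimated fetal weight from biometry (cm):

    log10 EFW = 1.3596 - 0.00386 AC·FL + 0.0064 HC + 0.00061 BPD·AC
                + 0.0424 AC + 0.174 FL

**Monitoring analytics.** 10-minute segmentation with per-segment means,
FHR variability (within-segment SD), absent-EDV fraction, FHR-acceleration
detection (≥15 bpm over a rolling-median baseline for ≥15 s), and
condition-stratified box statistics (median, IQR, 5th/95th percentiles).

**Validation statistics.** Bland–Altman mean difference, SD and 1.96-SD
limits of agreement; per-axis sample-gate discrepancy with within-2-mm
fractions.

**QA and acoustic output.** Pixel spacing, FWHM resolution with sub-sample
interpolation, contrast-to-noise ratio, dynamic range from greyscale
targets, Doppler velocity accuracy; hydrophone sensitivity conversions
(dB re 1 V/µPa → V/Pa, capacitive loading), pulse-intensity metrics
(I_sppa, I_spta, peak rarefactional pressure), FDA-style derating
(0.3 dB/cm/MHz), mechanical index `MI = p_r/√f`, and acoustic power from a
plane scan integrated over the −26.2 dB beam cross-section.

## Worked example

A noise-free synthetic umbilical-artery waveform with S/D ratio 2.61 is run
through the full spectral chain, and a moving artery + vein scene through
the tracker:

```r
library(fetodoppler)

wave <- waveform_spec(fhr = 140, psv = 40, edv = 40 / 2.61, duration = 10)
wf   <- generate_waveform(wave, seed = 1)
spg  <- synthesize_spectrogram(wf, broadening_sd = 0, noise_floor = 0)
beats <- detect_beats(extract_envelope(spg))
bi   <- doppler_indices(beats)
sprintf("%d beats | mean FHR %.1f bpm | S/D %.2f | PI %.2f | RI %.2f",
        nrow(bi), mean(bi$fhr), mean(bi$sd_ratio), mean(bi$pi), mean(bi$ri))
#> "22 beats | mean FHR 140.0 bpm | S/D 2.61 | PI 1.03 | RI 0.62"

sc <- scene_spec(trajectory = list(type = "random_walk", max_speed = 2), seed = 0)
fr <- render_sequence(sc, waveform_spec(psv = 39, edv = 15, duration = 5), seed = 0)
tr <- track_sequence(fr)
gate_discrepancy(tr, fr$truth[tr$frame, ])
#> Sample-gate discrepancy (threshold 2 mm, n = 91)
#>   within, lateral:   100%
#>   within, axial:     100%
#>   within, euclidean: 100%

hadlock_efw(bpd = 8.5, hc = 31, ac = 30, fl = 6.5)
#> # A tibble: 1 × 2
#>   log_weight efw_g
#>        <dbl> <dbl>
#> 1       3.36 2311.
```

The recovered indices match the construction: RI = 1 − 1/2.61 ≈ 0.62, and
every autonomously registered gate falls within the 2-mm clinical criterion
of the ground-truth artery centroid. Each result object has `tidy()`,
`glance()` and `autoplot()`/`plot_*()` methods for tabular and graphical
inspection.

A thin command-line wrapper over the same pipeline lives in
`inst/cli/fetodoppler.R`:

```sh
Rscript inst/cli/fetodoppler.R simulate,track,spectra --config run.yaml --out out/
```

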