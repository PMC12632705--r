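Package: fetodoppler
Title: Autonomous Vessel Tracking and Doppler Analytics for Continuous Fetal Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational core of a wearable duplex-ultrasound fetal monitor:
    seeded simulation of moving pulsatile-artery duplex scenes and umbilical
    artery spectral-Doppler data; autonomous sample-gate tracking from the
    temporal variance of colour-Doppler intensity; maximum-velocity envelope
    extraction with per-beat peak systolic velocity, end diastolic velocity and
    fetal heart rate; clinical Doppler indices (S/D ratio, pulsatility index,
    resistance index, cerebroplacental ratio) and Hadlock-IV fetal weight
    estimation; continuous-monitoring segmentation and condition-stratified
    summaries; Bland-Altman agreement and gate-discrepancy statistics; and
    image quality-assurance and acoustic-output calculators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
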