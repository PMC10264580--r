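Package: flashvep
Title: Flash Visual Evoked Potential Waveform Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for flash visual evoked potentials (VEPs)
    recorded from rodents: simulation of epoched VEP cohorts with known
    ground-truth component latencies, sweep averaging, zero-phase bandpass
    and notch filtering, automated detection of the P1, N1 and P2
    components with implicit-time (inter-peak latency) computation,
    longitudinal percent-change-from-baseline endpoints with eye-level
    stratification by early latency delay, and a nonparametric
    group-comparison battery (D'Agostino-Pearson normality screen,
    Kruskal-Wallis with Dunn's post-hoc test, paired t contrasts).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
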