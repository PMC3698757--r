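Package: telemetrybp
Title: Circadian Blood-Pressure Telemetry Analysis for Radiotelemetered Rats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of continuous arterial-pressure telemetry in
    rats: systolic-peak beat detection on pulsatile waveforms, telemetry-cadence
    circadian binning and 12-hour dark/light summaries, dipper/nondipper rhythm
    classification, Welch spectral estimation of beat-to-beat systolic pressure
    with low-frequency (Mayer-wave) and high-frequency band power as a vasomotor
    sympathetic index, spontaneous baroreflex gain by the sequence method
    (positive slopes only), and the normality/variance-gated statistical decision
    tree (factorial ANOVA with Tukey or Bonferroni post hoc, Kruskal-Wallis with
    Steel-Dwass post hoc). Includes a seeded synthetic-cohort generator with
    known ground truth (strain presets, baroreflex coupling, light/dark
    schedules, dose-escalating drug effects) for pipeline validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    emmeans,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo: Rcpp
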