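Package: sleepalpha
Title: Prefrontal EEG Low-Alpha Biomarkers of Sleep Quality
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for two-channel prefrontal resting-state EEG
    and Pittsburgh Sleep Quality Index (PSQI) scores in a longitudinal
    cohort design. Provides multitaper (DPSS) power spectral density
    estimation, relative band power, decomposition of spectra into an
    aperiodic 1/f-like component and a periodic residual, sub-alpha band
    (low/medium/high alpha) quantification, frequency-resolved and band-level
    Pearson correlation against PSQI, paired eyes-open/eyes-closed tests,
    and a matched-pairs noncentral-t sample-size calculator. Includes a
    seeded synthetic-cohort generator (participation design, latent
    sleep-quality traits, ordinal PSQI scores, and raw or spectrum-level
    EEG) so that every stage of the analysis is testable end to end without
    access to recordings, plus EDF and CSV input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'cohort-design.R'
    'simulate-psqi.R'
    'simulate-eeg.R'
    'simulate-cohort.R'
    'io-edf.R'
    'io-csv.R'
    'io-results.R'
    'preprocess.R'
    'spectral.R'
    'specfit.R'
    'stats.R'
    'pipeline.R'
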