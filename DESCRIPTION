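Package: earauth
Title: Passthought Authentication Analysis for In-Ear EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for brain-based ("passthought")
    authentication with in-ear EEG. Synthesizes multi-subject, multi-task
    EEG corpora with controllable subject and task structure; extracts
    windowed Fourier power-spectrum features over configurable electrode
    montages; trains per-(subject, task) gradient-boosted binary
    authenticators under four factor-isolating negative-example schemes;
    and evaluates false acceptance, false rejection, half total error rate
    and accuracy, including leave-one-out robustness, imposter spoofing
    attacks, alpha-attenuation quality control and a 32 Hz high-pass
    muscle-artifact control analysis. Recordings are read and written as
    EDF or CSV with a corpus manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    xgboost,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'taskBattery.R'
    'generatorConfig.R'
    'synthetic.R'
    'io-csv.R'
    'io-edf.R'
    'io-corpus.R'
    'montage.R'
    'features.R'
    'authentication.R'
    'evaluation.R'
    'attack.R'
    'qc.R'
    'reproduce.R'
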