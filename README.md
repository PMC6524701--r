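# earauth

Passthought authentication analysis for in-ear EEG.

A *passthought* is a secret mental task — relaxed breathing, imagining a
song, picturing a chosen face — whose neural expression authenticates a
person in a single step: the task content is a knowledge factor
(something you know) and the individuality of its EEG expression is an
inherence factor (something you are); a custom-fit earpiece adds
possession. `earauth` implements the full analysis pipeline for such a
system, aimed at researchers in EEG biometrics and brain-computer
interfaces who want a tested, reproducible reference implementation:

* **Synthetic corpora** — multichannel in-ear EEG (left/right concha,
  canal-front, canal-back, Fp1, right mastoid, referenced at the left
  mastoid; 200 Hz) for a nine-task battery, 10 trials x 10 s per
  (subject, task), with controllable subject fingerprints (per-channel,
  per-band gains and stable narrowband peaks), eyes-closed alpha
  elevation, a 40 Hz auditory steady-state component for the listen
  task, per-task secret signatures and optional >32 Hz EMG
  contamination. Raw in-ear EEG of this kind is rarely shareable, so
  every downstream stage is testable without any download.
* **Features** — consecutive 100-sample (500 ms) windows, one-sided FFT
  power spectrum per electrode, concatenated over a montage
  (`left3`, `right3`, `both6`, `all`, `fp1`, `single:<label>`); no
  dimensionality reduction. Stored as a `SummarizedExperiment`
  subclass with full per-window provenance.
* **Authentication** — one gradient-boosted binary classifier (xgboost,
  logistic loss, shallow trees) per (subject, task) pair, with a third
  of the data withheld for testing and four factor-isolating
  negative-example schemes: `default` (P_i, T_*), `inherence_only`
  (P_i, T_c), `knowledge_only` (P_c, T_i), `combined`.
* **Evaluation** — false acceptance and rejection rates from attempt
  counts,

  FAR = FA_S / FA, FRR = TA_U / TA, HTER = (FAR + FRR)/2,
  ACC = 100 (1 − HTER),

  per-task and per-montage aggregation, best-task selection,
  leave-one-out robustness (each other subject excluded from the
  negative pool in turn) and the four-scheme factor analysis.
* **Attack simulation** — inside and outside imposters with a
  configurable knowledge level (0 = no knowledge, 1 = the target's full
  secret list) replayed against a target's nine classifiers, 200
  attempts each.
* **Quality control** — the eyes-closed/eyes-open alpha (8–12 Hz)
  attenuation check and the 32 Hz high-pass control analysis showing
  authentication is not driven by muscle artifacts.
* **I/O** — EDF and lossless CSV recordings plus corpus manifests.

## Worked example

```r
library(earauth)

## three synthetic participants, full protocol (10 x 10 s per task)
profiles <- lapply(1:3, function(i)
  makeSubjectProfile(i, subjectId = sprintf("P%d", i)))
corpus <- synthesizeCorpus(profiles, seed = 1)
corpus
#> EEGCorpus: 270 recordings, 3 subjects, 9 tasks
#>   protocol: 10 trials x 10 s @ 200 Hz per (subject, task)

fm <- buildFeatures(corpus, "left3")   # 3 electrodes x 51 bins = 153 features
dim(fm)
#> [1]   153 5400

## authenticate P1 by the song passthought
ls <- assembleTrainingSet(fm, "P1", "song", scheme = "default", seed = 7)
clf <- trainAuthenticator(ls, authParams(cvRounds = 0), seed = 7)
evaluateClassifier(clf, ls = ls)
#> EvalReport
#>   FA=1200 FAS=0 TA=60 TAU=0
#>   FAR=0.00000 FRR=0.00000 HTER=0.00000 ACC=100.00%
```

The report counts 1200 false attempts (imposter windows) with none
accepted and 60 true attempts with none rejected: this subject's song
expression is perfectly separated from two other subjects at the 0.5
decision threshold. `runFullGrid()` repeats this for every (subject,
task) pair and `selectBestTasks()` reduces the grid to each subject's
best passthought and the headline accuracy.

## Vignette

`vignettes/earauth-methods.Rmd` documents the generative model, the
training schemes, the evaluation identities, the attack protocol and
every calibration choice, with the assumptions and limitations spelled
out.
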