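---
title: "Passthought authentication with in-ear EEG: models and methods"
author: "earauth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Passthought authentication with in-ear EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(earauth)
```

## The problem

Brain-based ("passthought") authentication verifies a person from the
EEG expression of a secret mental task. Two factors act at once: *what*
is thought (knowledge) and *how* the individual's brain expresses it
(inherence); a custom-fit earpiece recording from inside the ear canal
adds possession. The analysis questions are: how well can per-person,
per-task binary classifiers separate the legitimate user from everyone
else (FAR/FRR), how much does each factor contribute, how robust is the
decision to the enrolled population (leave-one-out), and does an
imposter who knows the secret get in (spoofing)?

Raw in-ear EEG of this kind is rarely shareable. The package therefore
ships a synthetic-data generator whose outputs have the statistical
structure the analysis relies on, so the entire pipeline is exercised
end to end by code alone. This vignette documents the generative model,
the analysis choices, and what the synthetic results do and do not say
about real recordings.

## The recording model

Eight channels are emulated — left and right concha, canal-front and
canal-back electrodes, Fp1, and the right mastoid — already referenced
at the left mastoid (the reference itself is not emitted;
`rereference()` can re-reference to the recorded right mastoid). The
protocol records, for each of nine tasks, 10 trials of 10 s at 200 Hz:
100 s per (subject, task), which tiles exactly into 200 windows of 100
samples (500 ms).

Each trial is a sum of:

* a **1/f background**: random-phase spectrum with amplitude
  proportional to `backgroundAmp / f` (power 1/f²), high-passed at
  0.5 Hz, multiplied inside each classical band (delta 1–4, theta 4–8,
  alpha 8–12, beta 12–30, gamma 30–50 Hz) by a baseline shape
  (`bandBase`) times the subject's gain for that channel and band;
* **stable narrowband peaks** — the deterministic part of the
  fingerprint, analogous to the individual alpha peak frequency and
  site-specific spectral idiosyncrasies. Peak frequencies are drawn per
  channel and band on the 2 Hz grid of the 500 ms analysis windows
  (delta and theta one peak, alpha and beta two peaks per channel), so
  their window power is phase-invariant and stable. Amplitude is
  `peakAmp` times the band baseline times the subject's gain;
* an **alpha attenuation** factor in (0, 1] applied to the alpha band
  (background and peaks) whenever the task is performed with eyes open;
* a **40 Hz steady-state component** during the listen task, with a
  subject-specific amplitude (0.8–1.5 µV);
* a **secret signature** for the six tasks that involve a chosen
  secret: two sinusoidal components with on-grid center frequencies in
  6–28 Hz and amplitudes 0.5–1.2 µV. The *expression* of a secret is
  deliberately personal: each component's amplitude rides on the
  performer's own band gain, and its realized frequency shifts by a
  subject-specific on-grid style offset (±6 Hz), reflected back into
  range. Content and expression are distinct objects — an imposter can
  acquire the content, never the expression;
* optional **EMG-like contamination**: flat band-limited noise in
  35–80 Hz with configurable RMS, off by default; a `discriminative`
  switch scales it by a subject-specific gain (used only to validate
  that the 32 Hz control analysis *would* detect such leakage);
* **white sensor noise** (0.6 µV), multiplied by a `fitNoise` factor
  ≥ 1 that models a badly fitting earpiece.

### Fingerprint spread

Subject gains are log-normal: `exp(gainSpreadLog * bandSpreadScale[b] *
z)` with standard normal `z` per channel and band. `gainSpreadLog`
(default 1.2) is the subject-separability knob; `bandSpreadScale`
(delta 0.25, theta 0.4, alpha 0.4, beta 1, gamma 1) encodes that slow
rhythms vary much less between individuals than the alpha/beta range.
The bounded delta spread also keeps delta leakage (rectangular windows,
no taper) from contaminating the 8–12 Hz band used by the alpha QC
check. The alpha scale keeps eyes-closed alpha universally present, so
the attenuation check is meaningful for every subject.

No effect sizes exist to copy for these choices: real studies report
rates, not generative parameters. The defaults were calibrated once, as
a set, to place the system in the regime the analysis is designed for —
authentication learnable from 500 ms windows but not trivial
(per-window background power is still exponentially distributed), with
the inherence factor dominating the knowledge factor. They were then
frozen; the structural properties below hold across independent master
seeds under these defaults.

## Features

`slice_windows → power_spectrum → concatenate` with no dimensionality
reduction: consecutive non-overlapping 100-sample windows (remainders
discarded; windows never span trials), a one-sided squared-magnitude
FFT spectrum per electrode (rectangular window, no detrending; DC and
Nyquist included once, interior bins doubled, normalized by window
length so the bins sum to the window's time-domain energy — Parseval is
tested against a brute-force oracle), concatenated over the montage in
order. `left3` gives 3 × 51 = 153 features per window; bin width is
2 Hz. DC/Nyquist inclusion is configurable (`dropDC`, `dropNyquist`).
`highpassFeatures(fm, 32)` *removes* every bin at or below 32 Hz
(34 of 51 bins remain per electrode), for the EMG control analysis.

## Classifiers and training schemes

Positives are all windows of the target (subject, task). Negatives come
from one of four factor-isolating pools: `default` — other subjects,
any task; `inherence_only` — other subjects, same task;
`knowledge_only` — same subject, other tasks; `combined` — the union.
Negatives are drawn without replacement up to `negRatio` times the
positive count. Two choices deserve comment:

* **negRatio = 20.** With 10:1 the negative sample covers too little of
  the pool (2 000 of 10 800 windows at default size) and the false
  acceptance rate of retrained classifiers fluctuated with the draw;
  20:1 covers enough that retraining is stable. The draw is additionally
  round-robin-stratified over (subject, task) cells so no negative
  source is missed.
* **Split unit: trials.** One third of the data is withheld for
  testing, at trial granularity — all 20 windows of a trial fall on the
  same side, so within-trial autocorrelation cannot leak across the
  split. `splitBy = "window"` provides the permissive alternative.

The classifier is a gradient-boosted ensemble of depth-3 trees with
logistic loss (xgboost), `eta = 0.1`, 300 rounds, and
`colsample_bytree = 0.05`. The aggressive column subsampling is the
open-set hardening of the model: boosting on its own concentrates on
the few most discriminative frequency bins and only ever learns
one-sided "power above threshold" splits there (no training negative is
high at the target's peak bins, so no upper bound is ever needed to fit
the data), which lets an unseen identity with *stronger* peaks at the
same bins walk through. Restricting each tree to a random handful of
features (about 8 of 153) turns the ensemble into a conjunction of many
weak checks across almost all identity coordinates — acceptance then
requires matching the target nearly everywhere, which no other
identity, enrolled or not, does. A window is accepted iff its score
strictly exceeds 0.5 (a score of exactly 0.5 is rejected). When
`cvRounds > 0`, the boosting-round count is chosen from
`candidateNrounds` by repeated shuffled splits of the training portion
(default 100 repetitions), scored by the plain binary error rate; the
withheld test third is never touched. The grids in the test-suite and
acceptance runs fix the round count (`cvRounds = 0`) — the selection
machinery is exercised separately — keeping a full grid, leave-one-out
and factor analysis run in minutes on one CPU.

## Evaluation

All rates reduce to attempt counts: over `FA` false attempts with
`FA_S` wrongly accepted and `TA` true attempts with `TA_U` wrongly
rejected,

FAR = FA_S/FA, FRR = TA_U/TA, HTER = (FAR + FRR)/2,
ACC = 100 (1 − HTER),

and the binary error rate ε = (FA_S + TA_U)/(FA + TA). These identities
are validated on every emitted report and against a per-instance
oracle. Table-style reports round half away from zero to five decimals
(`aggregateMean`); figure-style montage summaries use mean ± sd/√n.
Best-task selection minimizes FAR, breaking ties by lower FRR and then
battery order. The leave-one-out protocol retrains the target's
classifier once per excluded subject and recomputes the FAR each time.

## Attack protocol

`makeImposterProfile` builds an attacker: a different neural identity
(own gains, peaks, style — never copied), with task secrets
interpolating between independent draws (`knowledgeLevel = 0`) and the
target's exact content (`knowledgeLevel = 1`). `runSpoofAttack` replays
the imposter's windows, task by task, against the target's nine
classifiers — 200 attempts per classifier, 1 800 total; a success is a
score above threshold. `runOutsideAttack` synthesizes a full session
for an identity absent from the enrolled corpus. An inside imposter is
an enrolled subject's identity (`base =`) performing the target's
secrets. `fitNoise > 1` degrades the attacker's recordings, modeling a
stolen earpiece that does not fit.

Because secret expression is personal (amplitude and frequency style),
full knowledge of the secret list does not reproduce the owner's
feature pattern: under the default conditions both inside and outside
knowledge-level-1 attacks yield zero successes in 1 800 attempts, and
knowledge-level-0 attackers are statistically just another stranger.

## Quality control

`alphaAttenuationCheck` compares 8–12 Hz power between eyes-closed and
eyes-open breathing, per subject and channel; the generator forces a
closed/open ratio well above 1 on ear channels. `emgControlAnalysis`
retrains the grid on >32 Hz features only and compares the holdout
error with the base-rate error of the same test sets; "at chance" is
operationalized as within 5 percentage points. With the default
generator every discriminative component lies below 32 Hz (≥95% of
non-DC power), so the control sits at chance; with
`emg = list(enabled = TRUE, discriminative = TRUE)` it correctly drops
below chance.

## Problem sizes

The acceptance runs use the study-scale default: 7 subjects × 9 tasks ×
10 × 10 s, left-ear montage (63 classifiers; 42 leave-one-out
retrainings; 3 600 spoof attempts). The scheme-ordering replication
uses 4-subject corpora over 5 master seeds. Unit tests use 3-subject
corpora with 3 × 2.5 s trials, where only mechanical properties — not
population-level statistics — are asserted; the statistical invariants
need the default corpus size to hold and are asserted there.

## What passing tests do and do not show

The generator reproduces the *structure* the analysis assumes —
individual spectral fingerprints, task-secret content vs. personal
expression, alpha reactivity, a 40 Hz steady-state response, sub-32 Hz
cortical support — not the biophysics of real in-ear EEG: no volume
conduction, electrode drift, ocular artifacts, impedance variation,
session-to-session nonstationarity, or realistic between-subject
overlap. Synthetic results demonstrate that the pipeline measures what
it claims to measure and recovers planted structure; they do not
predict field accuracy of any physical system. Known limitations:
identity is stationary (no enrollment drift), secrets are stationary
sinusoidal signatures, and the stable-peak model makes per-window
identity evidence stronger than short real windows typically provide.
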