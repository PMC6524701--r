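## Shared fixtures, built once per test run and cached. Small corpora use
## short trials (2.5 s) and few trials so the whole non-acceptance suite
## stays fast; the protocol-scale checks live in the synthetic tests and
## the acceptance suite.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

smallProtocol <- function() protocolConfig(nTrials = 3L, trialDurationS = 2.5)

smallCorpus <- function(nSubjects = 3L) {
  fixture(paste0("corpus", nSubjects), function() {
    profs <- lapply(seq_len(nSubjects), function(i)
      makeSubjectProfile(i, subjectId = sprintf("P%d", i)))
    synthesizeCorpus(profs, smallProtocol(), seed = 42)
  })
}

smallFeatures <- function(nSubjects = 3L, montage = "left3") {
  fixture(paste0("features", nSubjects, montage), function()
    buildFeatures(smallCorpus(nSubjects), montage))
}

fastParams <- function() {
  authParams(nrounds = 60L, cvRounds = 0L, colsampleBytree = 0.3)
}

earLabels <- function() {
  c("L_concha", "L_front", "L_back", "R_concha", "R_front", "R_back")
}

## Mean band power of a recording on one channel, via the package's own
## windowed spectra (the band-power oracle used by generator tests).
bandPower <- function(rec, channel, lo, hi, windowLen = 100L) {
  wins <- sliceWindows(rec, windowLen)
  mean(vapply(wins, function(w) {
    sp <- powerSpectrum(w[channel, ], samplingRate(rec))
    f <- as.numeric(names(sp))
    sum(sp[f >= lo & f <= hi])
  }, numeric(1)))
}
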