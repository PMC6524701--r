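#' SubjectProfile: a synthetic participant's neural identity
#'
#' Holds everything that makes one synthetic participant's EEG their own:
#' per-channel, per-band spectral gains (the biometric "fingerprint"),
#' eyes-open alpha attenuation, the amplitude of the 40 Hz auditory
#' steady-state response, and per-task secret signatures (center
#' frequencies, amplitudes and channel weights) for tasks that involve a
#' chosen secret.
#'
#' @slot subjectId character scalar.
#' @slot fingerprintGains channels x bands matrix of strictly positive
#'   relative power gains (dimensionless).
#' @slot peakAmps channels x peaks matrix of per-peak amplitude
#'   multipliers (log-normal): even subjects sharing a peak frequency
#'   express it with their own strength.
#' @slot alphaOpenAttenuation factor in (0, 1] applied to the alpha-band
#'   gain when a task is performed with eyes open.
#' @slot assrAmplitude amplitude (microvolt) of the 40 Hz steady-state
#'   component expressed during the listen task.
#' @slot peakFreqs channels x bands matrix of the subject's stable
#'   oscillatory peak frequencies (Hz; e.g. the individual alpha peak and
#'   channel-specific spectral idiosyncrasies), drawn on the analysis
#'   frequency grid; bands above the beta range carry no stable peak (NA).
#' @slot emgGain subject-specific multiplier for the optional EMG band
#'   (only used when the generator's EMG component is discriminative).
#' @slot taskSecrets named list (by task) of lists with elements `freqs`
#'   (Hz), `amps` (microvolt) and `weights` (per-channel); present only for
#'   tasks with a secret.
#' @slot secretStyle named list (by secret task) of on-grid frequency
#'   offsets (Hz), one per secret component: the personal "accent" with
#'   which this subject expresses a secret. Part of the expression, not
#'   the secret — it is never transferred to an imposter, however much
#'   they know.
#' @slot fitNoise earpiece-fit noise multiplier (>= 1); 1 means the
#'   intended owner's fit.
#' @slot seed integer seed the profile was drawn from.
#' @export
setClass("SubjectProfile", representation(
  subjectId = "character",
  fingerprintGains = "matrix",
  peakFreqs = "matrix",
  peakAmps = "matrix",
  alphaOpenAttenuation = "numeric",
  assrAmplitude = "numeric",
  emgGain = "numeric",
  taskSecrets = "list",
  secretStyle = "list",
  fitNoise = "numeric",
  seed = "integer"
))

setValidity("SubjectProfile", function(object) {
  msg <- character()
  g <- object@fingerprintGains
  if (!is.numeric(g) || any(!is.finite(g)) || any(g <= 0))
    msg <- c(msg, "fingerprintGains must be finite and strictly positive")
  if (length(object@alphaOpenAttenuation) != 1L ||
      object@alphaOpenAttenuation <= 0 || object@alphaOpenAttenuation > 1)
    msg <- c(msg, "alphaOpenAttenuation must lie in (0, 1]")
  if (object@assrAmplitude <= 0)
    msg <- c(msg, "assrAmplitude must be strictly positive")
  if (object@emgGain <= 0)
    msg <- c(msg, "emgGain must be strictly positive")
  if (object@fitNoise < 1)
    msg <- c(msg, "fitNoise must be >= 1")
  if (length(msg)) msg else TRUE
})

#' EEGRecording: one trial's multichannel EEG
#'
#' A channels x samples matrix in microvolts with its sampling rate,
#' ordered channel labels and (subject, task, trial) identity. Channels are
#' referenced at the left mastoid.
#'
#' @slot data channels x samples numeric matrix (microvolt).
#' @slot fs sampling rate in Hz.
#' @slot channelLabels ordered channel labels, one per data row.
#' @slot subjectId,taskName identity labels.
#' @slot trialIndex zero-based trial index.
#' @export
setClass("EEGRecording", representation(
  data = "matrix",
  fs = "numeric",
  channelLabels = "character",
  subjectId = "character",
  taskName = "character",
  trialIndex = "integer"
))

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (nrow(object@data) != length(object@channelLabels))
    msg <- c(msg, "data row count must equal channelLabels length")
  if (nrow(object@data) < 1L)
    msg <- c(msg, "recording must have at least one channel")
  if (any(!is.finite(object@data)))
    msg <- c(msg, "data must contain no non-finite values")
  if (length(object@fs) != 1L || object@fs <= 0)
    msg <- c(msg, "fs must be a positive scalar")
  if (object@trialIndex < 0L)
    msg <- c(msg, "trialIndex must be >= 0")
  if (anyDuplicated(object@channelLabels))
    msg <- c(msg, "channelLabels must be unique")
  if (length(msg)) msg else TRUE
})

#' EEGCorpus: a labeled collection of recordings
#'
#' Recordings following the acquisition protocol (trials per task, trial
#' duration, sampling rate), with a subject/task registry. The
#' (subject, task, trial) triple of every recording is unique.
#'
#' @slot recordings list of [EEGRecording-class].
#' @slot protocol list with `nTrials`, `trialDurationS`, `fs`.
#' @export
setClass("EEGCorpus", representation(
  recordings = "list",
  protocol = "list"
))

setValidity("EEGCorpus", function(object) {
  msg <- character()
  if (!all(vapply(object@recordings, is, logical(1), "EEGRecording")))
    msg <- c(msg, "all elements must be EEGRecording objects")
  else {
    keys <- vapply(object@recordings, function(r)
      paste(r@subjectId, r@taskName, r@trialIndex, sep = "\r"), character(1))
    if (anyDuplicated(keys))
      msg <- c(msg, "duplicate (subject, task, trial) triples")
  }
  if (length(msg)) msg else TRUE
})

#' AuthFeatureSet: windowed power-spectrum features
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' whose single assay `"power"` holds features x windows: each column is one
#' 500 ms window, each row one frequency bin of one electrode, concatenated
#' in montage order. `colData` carries per-window provenance (subject, task,
#' trial, window index); `rowData` carries electrode and bin center
#' frequency; `metadata` carries `binHz`, `nBinsPerElectrode`, `montage`,
#' `windowLen` and `fs`.
#'
#' @export
#' @import SummarizedExperiment
setClass("AuthFeatureSet", contains = "SummarizedExperiment")

setValidity("AuthFeatureSet", function(object) {
  msg <- character()
  if (!"power" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'power' is required")
  else if (any(SummarizedExperiment::assay(object, "power") < 0))
    msg <- c(msg, "all power values must be >= 0")
  cd <- SummarizedExperiment::colData(object)
  need <- c("subjectId", "taskName", "trialIndex", "windowIndex")
  if (!all(need %in% colnames(cd)))
    msg <- c(msg, paste("colData must contain", paste(need, collapse = ", ")))
  md <- S4Vectors::metadata(object)
  ne <- length(md$montage$labels %||% character())
  nb <- md$nBinsPerElectrode %||% NA_integer_
  if (is.na(nb) || nrow(object) != ne * nb)
    msg <- c(msg, "feature count must equal n_electrodes * n_bins_per_electrode")
  if (length(msg)) msg else TRUE
})

#' AuthClassifier: a fitted per-(subject, task) authenticator
#'
#' A gradient-boosted binary classifier (shallow trees, logistic loss) for
#' one target (subject, task) pair, with its decision threshold and
#' training metadata. The booster is stored as a raw serialized blob so
#' fitted classifiers survive `saveRDS()`/`readRDS()` for attack replay.
#'
#' @slot booster raw vector, the serialized xgboost model.
#' @slot featureNames training feature names (dimension check at predict).
#' @slot threshold decision cut; a window is accepted iff score > threshold.
#' @slot subjectId,taskName the authentication target.
#' @slot scheme negative-example scheme name.
#' @slot params training parameter list.
#' @slot nrounds boosting rounds actually used in the final fit.
#' @slot seed integer training seed.
#' @export
setClass("AuthClassifier", representation(
  booster = "raw",
  featureNames = "character",
  threshold = "numeric",
  subjectId = "character",
  taskName = "character",
  scheme = "character",
  params = "list",
  nrounds = "integer",
  seed = "integer"
))

#' EvalReport: attempt counts and error rates for one authenticator
#'
#' Counts false (imposter) attempts `FA` with `FAS` wrongly accepted, true
#' attempts `TA` with `TAU` wrongly rejected, and the derived rates:
#' FAR = FAS/FA, FRR = TAU/TA, HTER = (FAR + FRR)/2, ACC = 100 (1 - HTER),
#' plus the plain binary error rate epsilon = (FAS + TAU)/(FA + TA).
#'
#' @slot FA,FAS,TA,TAU attempt counts.
#' @slot FAR,FRR,HTER numeric rates in [0, 1]; ACC percent in [0, 100].
#' @slot ACC numeric, percent.
#' @slot epsilon binary classification error rate.
#' @slot context named list of labels (subject, task, montage, scheme, ...).
#' @export
setClass("EvalReport", representation(
  FA = "numeric", FAS = "numeric", TA = "numeric", TAU = "numeric",
  FAR = "numeric", FRR = "numeric", HTER = "numeric", ACC = "numeric",
  epsilon = "numeric",
  context = "list"
))

setValidity("EvalReport", function(object) {
  msg <- character()
  tol <- 1e-12
  with_slots <- function(nm) slot(object, nm)
  if (object@FA < object@FAS || object@FAS < 0 ||
      object@TA < object@TAU || object@TAU < 0)
    msg <- c(msg, "counts must satisfy FA >= FAS >= 0 and TA >= TAU >= 0")
  if (abs(object@FAR * object@FA - object@FAS) > tol * max(1, object@FA))
    msg <- c(msg, "FAR * FA must equal FAS")
  if (abs(object@FRR * object@TA - object@TAU) > tol * max(1, object@TA))
    msg <- c(msg, "FRR * TA must equal TAU")
  if (abs(object@HTER - (object@FAR + object@FRR) / 2) > tol)
    msg <- c(msg, "HTER must equal (FAR + FRR)/2")
  if (abs(object@ACC - 100 * (1 - object@HTER)) > 1e-9)
    msg <- c(msg, "ACC must equal 100 * (1 - HTER)")
  if (object@FAR < 0 || object@FAR > 1 || object@FRR < 0 || object@FRR > 1)
    msg <- c(msg, "rates must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

## ---- accessors & show methods ----

#' @rdname recording-accessors
setMethod("subjectId", "EEGRecording", function(x) x@subjectId)
#' @rdname recording-accessors
setMethod("taskName", "EEGRecording", function(x) x@taskName)
#' @rdname recording-accessors
setMethod("trialIndex", "EEGRecording", function(x) x@trialIndex)
#' @rdname recording-accessors
setMethod("samplingRate", "EEGRecording", function(x) x@fs)
#' @rdname recording-accessors
setMethod("channelLabels", "EEGRecording", function(x) x@channelLabels)
#' @rdname recording-accessors
setMethod("subjectId", "SubjectProfile", function(x) x@subjectId)

#' @describeIn EEGCorpus-class list of member recordings.
setMethod("recordings", "EEGCorpus", function(x) x@recordings)

#' @describeIn EEGCorpus-class number of recordings.
#' @param x an EEGCorpus.
#' @export
setMethod("length", "EEGCorpus", function(x) length(x@recordings))

#' Subjects and tasks present in a corpus
#' @param corpus an [EEGCorpus-class].
#' @return character vector of unique ids, in first-appearance order.
#' @export
corpusSubjects <- function(corpus) {
  unique(vapply(recordings(corpus), subjectId, character(1)))
}

#' @rdname corpusSubjects
#' @export
corpusTasks <- function(corpus) {
  unique(vapply(recordings(corpus), taskName, character(1)))
}

setMethod("show", "SubjectProfile", function(object) {
  cat("SubjectProfile", object@subjectId,
      sprintf("(seed %d)\n", object@seed))
  cat("  fingerprint gains:", nrow(object@fingerprintGains), "channels x",
      ncol(object@fingerprintGains), "bands\n")
  cat(sprintf("  alpha eyes-open attenuation: %.3f; 40 Hz ASSR: %.2f uV\n",
              object@alphaOpenAttenuation, object@assrAmplitude))
  cat("  secret tasks:", paste(names(object@taskSecrets), collapse = ", "),
      "\n")
})

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording %s / %s / trial %d: %d channels x %d samples @ %g Hz\n",
              object@subjectId, object@taskName, object@trialIndex,
              nrow(object@data), ncol(object@data), object@fs))
})

setMethod("show", "EEGCorpus", function(object) {
  cat(sprintf("EEGCorpus: %d recordings, %d subjects, %d tasks\n",
              length(object), length(corpusSubjects(object)),
              length(corpusTasks(object))))
  p <- object@protocol
  cat(sprintf("  protocol: %d trials x %g s @ %g Hz per (subject, task)\n",
              p$nTrials, p$trialDurationS, p$fs))
})

setMethod("show", "AuthClassifier", function(object) {
  cat(sprintf("AuthClassifier for (%s, %s), scheme '%s'\n",
              object@subjectId, object@taskName, object@scheme))
  cat(sprintf("  %d features, %d boosting rounds, threshold %g\n",
              length(object@featureNames), object@nrounds, object@threshold))
})

setMethod("show", "EvalReport", function(object) {
  ctx <- object@context
  if (length(ctx))
    cat("EvalReport [", paste(names(ctx), unlist(ctx), sep = "=",
                              collapse = ", "), "]\n", sep = "")
  else cat("EvalReport\n")
  cat(sprintf("  FA=%g FAS=%g TA=%g TAU=%g\n",
              object@FA, object@FAS, object@TA, object@TAU))
  cat(sprintf("  FAR=%.5f FRR=%.5f HTER=%.5f ACC=%.2f%%\n",
              object@FAR, object@FRR, object@HTER, object@ACC))
})
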