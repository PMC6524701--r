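#' @import methods
NULL

#' Accessors for recording identity and geometry
#'
#' @param x an object with recording metadata.
#' @return `subjectId`, `taskName` return character scalars; `trialIndex`
#'   an integer; `samplingRate` a numeric (Hz); `channelLabels` a character
#'   vector in acquisition order.
#' @name recording-accessors
#' @aliases subjectId taskName trialIndex samplingRate channelLabels
NULL

#' @rdname recording-accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname recording-accessors
#' @export
setGeneric("taskName", function(x) standardGeneric("taskName"))

#' @rdname recording-accessors
#' @export
setGeneric("trialIndex", function(x) standardGeneric("trialIndex"))

#' @rdname recording-accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname recording-accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' @rdname EEGCorpus-class
#' @export
setGeneric("recordings", function(x) standardGeneric("recordings"))

#' Re-reference a recording to one of its channels
#'
#' Subtracts the chosen channel from every channel and drops it (it would be
#' identically zero). Mirrors the standard EEG practice of re-referencing a
#' mastoid-referenced montage to the contralateral mastoid.
#'
#' @param x an [EEGRecording-class].
#' @param refLabel label of the channel to use as the new reference; must be
#'   present in `channelLabels(x)`.
#' @return an [EEGRecording-class] with one fewer channel.
#' @export
setGeneric("rereference", function(x, refLabel) standardGeneric("rereference"))

#' Slice a recording into fixed-length windows
#'
#' Cuts each channel into consecutive, non-overlapping windows of
#' `windowLen` samples; remainder samples are discarded. Windows never span
#' trials because each recording is a single trial.
#'
#' @param x an [EEGRecording-class].
#' @param windowLen window length in samples (default 100, about 500 ms at
#'   200 Hz).
#' @return a list of channels x windowLen matrices (possibly empty).
#' @export
setGeneric("sliceWindows", function(x, windowLen = 100L) {
  standardGeneric("sliceWindows")
})
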