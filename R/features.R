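#' @describeIn rereference subtracts `refLabel` from every channel and
#'   drops it.
setMethod("rereference", "EEGRecording", function(x, refLabel) {
  i <- match(refLabel, x@channelLabels)
  if (is.na(i)) stop("unknown reference label: '", refLabel, "'")
  ref <- x@data[i, ]
  dat <- sweep(x@data[-i, , drop = FALSE], 2L, ref, "-")
  new("EEGRecording", data = dat, fs = x@fs,
      channelLabels = x@channelLabels[-i], subjectId = x@subjectId,
      taskName = x@taskName, trialIndex = x@trialIndex)
})

#' @describeIn sliceWindows non-overlapping windows; remainder discarded.
setMethod("sliceWindows", "EEGRecording", function(x, windowLen = 100L) {
  windowLen <- as.integer(windowLen)
  if (windowLen < 2L) stop("windowLen must be >= 2")
  n <- ncol(x@data)
  nWin <- n %/% windowLen
  if (nWin == 0L) {
    message("recording shorter than one window (", n, " < ", windowLen,
            " samples); zero windows")
    return(list())
  }
  lapply(seq_len(nWin), function(w) {
    x@data[, ((w - 1L) * windowLen + 1L):(w * windowLen), drop = FALSE]
  })
})

#' One-sided power spectrum of a window
#'
#' Squared-magnitude Fourier spectrum of one electrode's window, folded to
#' one side (DC and Nyquist included once, interior bins doubled) and
#' normalized by the window length so that the bins sum to the time-domain
#' energy `sum(x^2)` (Parseval). No taper and no detrending are applied.
#'
#' @param x numeric vector, one window of raw samples.
#' @param fs sampling rate in Hz (names the bins).
#' @param dropDC,dropNyquist optionally exclude the DC / Nyquist bin.
#' @return named numeric vector of `floor(length(x)/2) + 1` power values
#'   (fewer if bins are dropped); names are bin center frequencies in Hz.
#' @examples
#' s <- powerSpectrum(sin(2 * pi * 10 * (0:99) / 200), fs = 200)
#' names(which.max(s))  # "10"
#' @export
powerSpectrum <- function(x, fs, dropDC = FALSE, dropNyquist = FALSE) {
  if (any(!is.finite(x))) stop("window contains non-finite values")
  n <- length(x)
  X <- stats::fft(x)
  half <- floor(n / 2)
  p <- Mod(X[seq_len(half + 1)])^2 / n
  ## fold: interior bins carry both halves of the spectrum
  interior <- 2:(half + if (n %% 2 == 0) 0 else 1)
  p[interior] <- 2 * p[interior]
  names(p) <- seq(0, half) * fs / n
  if (dropNyquist && n %% 2 == 0) p <- p[-length(p)]
  if (dropDC) p <- p[-1]
  p
}

#' Build the feature matrix for a corpus
#'
#' The classification features: each recording is cut into consecutive
#' `windowLen`-sample windows; a power spectrum is computed for every
#' selected electrode in every window; and the per-electrode spectra are
#' concatenated in montage order. No dimensionality reduction is applied.
#' Rows of the result are features, columns are windows ordered by
#' (subject, task, trial, window).
#'
#' @param corpus an [EEGCorpus-class].
#' @param montage a montage name or [montageSelection()].
#' @param windowLen window length in samples (default 100, about 500 ms at
#'   200 Hz).
#' @param dropDC,dropNyquist passed to [powerSpectrum()].
#' @return an [AuthFeatureSet-class].
#' @examples
#' corpus <- synthesizeCorpus(list(makeSubjectProfile(1)),
#'                            protocolConfig(nTrials = 1,
#'                                           trialDurationS = 1), seed = 1)
#' fm <- buildFeatures(corpus, "left3")
#' dim(fm)  # 153 features x 18 windows
#' @export
buildFeatures <- function(corpus, montage = "left3", windowLen = 100L,
                          dropDC = FALSE, dropNyquist = FALSE) {
  stopifnot(is(corpus, "EEGCorpus"))
  montage <- asMontage(montage)
  windowLen <- as.integer(windowLen)
  recs <- recordings(corpus)
  if (!length(recs)) stop("empty corpus")
  cols <- list(); meta <- list()
  for (rec in recs) {
    miss <- setdiff(montage$labels, rec@channelLabels)
    if (length(miss))
      stop("montage label '", miss[1], "' missing from recording ",
           rec@subjectId, "/", rec@taskName, "/", rec@trialIndex)
    wins <- suppressMessages(sliceWindows(rec, windowLen))
    if (!length(wins)) next
    rows <- match(montage$labels, rec@channelLabels)
    feat <- vapply(wins, function(w) {
      unlist(lapply(rows, function(r)
        powerSpectrum(w[r, ], rec@fs, dropDC, dropNyquist)),
        use.names = FALSE)
    }, numeric(length(montage$labels) *
                 nBinsFor(windowLen, dropDC, dropNyquist)))
    cols[[length(cols) + 1L]] <- feat
    meta[[length(meta) + 1L]] <- data.frame(
      subjectId = rec@subjectId, taskName = rec@taskName,
      trialIndex = rec@trialIndex,
      windowIndex = seq_along(wins) - 1L, stringsAsFactors = FALSE)
  }
  if (!length(cols)) stop("no recording produced any window")
  values <- do.call(cbind, cols)
  labels <- do.call(rbind, meta)
  fs <- recs[[1]]@fs
  nb <- nBinsFor(windowLen, dropDC, dropNyquist)
  binFreqs <- binCenters(windowLen, fs, dropDC, dropNyquist)
  rowdat <- S4Vectors::DataFrame(
    electrode = rep(montage$labels, each = nb),
    freqHz = rep(binFreqs, times = length(montage$labels)))
  rownames(values) <- paste0(rowdat$electrode, "_", rowdat$freqHz, "Hz")
  colnames(values) <- sprintf("%s|%s|%03d|%03d", labels$subjectId,
                              labels$taskName, labels$trialIndex,
                              labels$windowIndex)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(power = values),
    rowData = rowdat,
    colData = S4Vectors::DataFrame(labels, row.names = colnames(values)),
    metadata = list(binHz = fs / windowLen, nBinsPerElectrode = nb,
                    montage = unclass(montage), windowLen = windowLen,
                    fs = fs))
  new("AuthFeatureSet", se)
}

nBinsFor <- function(windowLen, dropDC = FALSE, dropNyquist = FALSE) {
  nb <- windowLen %/% 2L + 1L
  if (dropNyquist && windowLen %% 2L == 0L) nb <- nb - 1L
  if (dropDC) nb <- nb - 1L
  nb
}

binCenters <- function(windowLen, fs, dropDC = FALSE, dropNyquist = FALSE) {
  f <- seq(0, windowLen %/% 2L) * fs / windowLen
  if (dropNyquist && windowLen %% 2L == 0L) f <- f[-length(f)]
  if (dropDC) f <- f[-1]
  f
}

#' High-pass a feature matrix in the frequency domain
#'
#' Removes (does not merely zero) every bin whose center frequency is at or
#' below `cutoffHz` from every electrode block. Used for the muscle-artifact
#' control analysis: features above 32 Hz retain only non-cortical signal.
#'
#' @param fm an [AuthFeatureSet-class].
#' @param cutoffHz cutoff in Hz; must be below the Nyquist frequency.
#' @return an [AuthFeatureSet-class] with `nBinsPerElectrode` updated.
#' @export
highpassFeatures <- function(fm, cutoffHz = 32) {
  stopifnot(is(fm, "AuthFeatureSet"))
  md <- S4Vectors::metadata(fm)
  nyquist <- md$fs / 2
  if (cutoffHz >= nyquist)
    stop("cutoff (", cutoffHz, " Hz) must be below the Nyquist frequency (",
         nyquist, " Hz); no bins would remain")
  keep <- SummarizedExperiment::rowData(fm)$freqHz > cutoffHz
  out <- fm[keep, ]
  S4Vectors::metadata(out)$nBinsPerElectrode <-
    sum(keep) %/% length(md$montage$labels)
  new("AuthFeatureSet", out)
}
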