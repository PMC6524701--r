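## Minimal EDF (European Data Format) writer/reader: ASCII headers of 256
## bytes plus 256 per signal, then data records of 16-bit little-endian
## integers, one sequence per signal per record. Physical unit is uV.
## Identity labels are stashed in the 80-char "local recording
## identification" field as "subject=..;task=..;trial=..".

padField <- function(x, width) {
  s <- substr(as.character(x), 1L, width)
  formatC(s, width = width, flag = "-")
}

writeRecordingEDF <- function(rec, path, physRange = c(-400, 400)) {
  stopifnot(is(rec, "EEGRecording"))
  if (diff(physRange) <= 0) stop("invalid EDF physical range")
  ns <- nrow(rec@data)
  n <- ncol(rec@data)
  fs <- rec@fs
  ## 1 s records when the sample count allows it, else one full-length record
  if (fs == round(fs) && n %% fs == 0) {
    spr <- as.integer(fs); nrec <- n %/% spr; recDur <- 1
  } else {
    spr <- n; nrec <- 1L; recDur <- n / fs
  }
  digMin <- -32768; digMax <- 32767
  scale <- (digMax - digMin) / diff(physRange)
  clipped <- pmin(pmax(rec@data, physRange[1]), physRange[2])
  if (!isTRUE(all.equal(clipped, rec@data, tolerance = 0)))
    warning("EDF write: samples outside the physical range were clipped")
  dig <- round((clipped - physRange[1]) * scale + digMin)
  storage.mode(dig) <- "integer"

  con <- file(path, "wb")
  on.exit(close(con))
  ## pads each element of x to `width` bytes and writes the concatenation
  wf <- function(x, width) {
    s <- paste(padField(x, width), collapse = "")
    writeChar(s, con, nchars = nchar(s, type = "bytes"), eos = NULL)
  }
  recInfo <- sprintf("subject=%s;task=%s;trial=%d", rec@subjectId,
                     rec@taskName, rec@trialIndex)
  wf("0", 8)                                  # version
  wf(rec@subjectId, 80)                       # patient id
  wf(recInfo, 80)                             # recording id
  wf("01.01.26", 8); wf("00.00.00", 8)        # start date/time
  wf(256 * (1 + ns), 8)                       # header bytes
  wf("", 44)                                  # reserved
  wf(nrec, 8)
  wf(format(recDur, digits = 8), 8)
  wf(ns, 4)
  wf(rec@channelLabels, 16)                   # per-signal fields
  wf(rep("AgCl electrode", ns), 80)
  wf(rep("uV", ns), 8)
  wf(rep(format(physRange[1]), ns), 8)
  wf(rep(format(physRange[2]), ns), 8)
  wf(rep(digMin, ns), 8)
  wf(rep(digMax, ns), 8)
  wf(rep("", ns), 80)                         # prefiltering
  wf(rep(spr, ns), 8)
  wf(rep("", ns), 32)                         # reserved
  for (r in seq_len(nrec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (s in seq_len(ns))
      writeBin(dig[s, idx], con, size = 2L, endian = "little")
  }
  invisible(path)
}

readRecordingEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  ver <- rd(8)
  patient <- rd(80)
  recInfo <- rd(80)
  rd(8); rd(8)
  headerBytes <- as.integer(rd(8))
  rd(44)
  nrec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  vapply(seq_len(ns), function(i) rd(80), character(1))
  vapply(seq_len(ns), function(i) rd(8), character(1))
  physMin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  physMax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  digMin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  digMax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  vapply(seq_len(ns), function(i) rd(80), character(1))
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  vapply(seq_len(ns), function(i) rd(32), character(1))
  if (length(unique(spr)) != 1L)
    stop("EDF with per-signal sampling rates is not supported")
  n <- nrec * spr[1]
  dat <- matrix(0, ns, n)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[1], size = 2L, signed = TRUE,
                     endian = "little")
      dat[s, idx] <- physMin[s] + (dig - digMin[s]) *
        (physMax[s] - physMin[s]) / (digMax[s] - digMin[s])
    }
  }
  meta <- parseEdfRecInfo(recInfo, fallbackSubject = patient)
  new("EEGRecording", data = dat, fs = spr[1] / recDur,
      channelLabels = labels, subjectId = meta$subject,
      taskName = meta$task, trialIndex = meta$trial)
}

parseEdfRecInfo <- function(recInfo, fallbackSubject = "unknown") {
  get1 <- function(key, default) {
    m <- regmatches(recInfo,
                    regexec(paste0(key, "=([^;]*)"), recInfo))[[1]]
    if (length(m) == 2L) m[2] else default
  }
  list(subject = get1("subject", fallbackSubject),
       task = get1("task", "unknown"),
       trial = as.integer(get1("trial", "0")))
}

#' EDF quantization step
#'
#' The worst-case absolute round-trip error of the 16-bit EDF encoding over
#' a physical range is half the quantization step.
#'
#' @param physRange length-2 physical range in microvolt.
#' @return the step size (microvolt).
#' @export
edfQuantStep <- function(physRange = c(-400, 400)) {
  diff(physRange) / (32767 - (-32768))
}
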