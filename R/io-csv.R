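## CSV dialect: comma-separated, '.' decimal, UTF-8, one header line of
## channel labels, one sample per row, values printed with 17 significant
## digits so the round trip is lossless. Identity and sampling rate live in
## a JSON sidecar "<path>.meta.json".

#' Write / read one recording
#'
#' `writeRecording` writes a single trial to disk as EDF (16-bit European
#' Data Format, physical unit microvolt) or CSV (lossless text, with a JSON
#' metadata sidecar). `readRecording` reads either format back, never
#' reordering channels.
#'
#' @param rec an [EEGRecording-class].
#' @param path destination file.
#' @param format `"EDF"` or `"CSV"` (default guessed from the extension on
#'   read).
#' @param physRange EDF physical range in microvolt; samples are quantized
#'   to 16 bits over this range, so the round-trip error is bounded by
#'   `diff(physRange) / (2^16 - 1)`.
#' @return `writeRecording` returns `path` invisibly; `readRecording`
#'   returns an [EEGRecording-class].
#' @export
writeRecording <- function(rec, path, format = c("CSV", "EDF"),
                           physRange = c(-400, 400)) {
  stopifnot(is(rec, "EEGRecording"))
  format <- match.arg(toupper(format), c("CSV", "EDF"))
  if (format == "CSV") writeRecordingCSV(rec, path)
  else writeRecordingEDF(rec, path, physRange = physRange)
  invisible(path)
}

#' @rdname writeRecording
#' @export
readRecording <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "EDF" else "CSV"
  }
  format <- match.arg(toupper(format), c("CSV", "EDF"))
  if (format == "CSV") readRecordingCSV(path) else readRecordingEDF(path)
}

writeRecordingCSV <- function(rec, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(rec@channelLabels, collapse = ","), con)
  ## samples as rows, channels as columns
  m <- t(rec@data)
  lines <- apply(m, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = ","))
  writeLines(lines, con)
  meta <- list(fs = rec@fs, channel_labels = as.list(rec@channelLabels),
               subject_id = rec@subjectId, task_name = rec@taskName,
               trial_index = rec@trialIndex)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

readRecordingCSV <- function(path) {
  metaPath <- paste0(path, ".meta.json")
  if (!file.exists(metaPath))
    stop("missing CSV metadata sidecar: ", metaPath)
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  tab <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                         colClasses = "numeric")
  labels <- colnames(tab)
  if (!identical(labels, as.character(meta$channel_labels)))
    stop("CSV header does not match sidecar channel labels")
  new("EEGRecording", data = t(as.matrix(tab)), fs = as.numeric(meta$fs),
      channelLabels = labels,
      subjectId = as.character(meta$subject_id),
      taskName = as.character(meta$task_name),
      trialIndex = as.integer(meta$trial_index))
}
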