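## Corpus manifests: a flat TSV (one row per recording file) with a
## format_version header line, so a corpus written to a directory can be
## reloaded with all labels attached.

MANIFEST_VERSION <- "1"

#' Write / read a corpus with its manifest
#'
#' `writeCorpus` writes every recording to `dir` (one file per trial,
#' `<subject>_<task>_<trial>.<ext>`) plus a `manifest.tsv` listing file
#' path, subject, task, trial, sampling rate and channel count.
#' `readCorpus` loads a manifest and all referenced recordings; it fails
#' with the offending entry named if a file is missing or a
#' (subject, task, trial) triple is duplicated.
#'
#' @param corpus an [EEGCorpus-class].
#' @param dir destination directory (created if needed).
#' @param format `"CSV"` or `"EDF"`.
#' @param physRange EDF physical range (microvolt), passed to the writer.
#' @return `writeCorpus` returns the manifest path invisibly; `readCorpus`
#'   returns an [EEGCorpus-class].
#' @export
writeCorpus <- function(corpus, dir, format = c("CSV", "EDF"),
                        physRange = c(-400, 400)) {
  stopifnot(is(corpus, "EEGCorpus"))
  format <- match.arg(toupper(format), c("CSV", "EDF"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "EDF") "edf" else "csv"
  rows <- lapply(recordings(corpus), function(rec) {
    fn <- sprintf("%s_%s_%03d.%s", rec@subjectId, rec@taskName,
                  rec@trialIndex, ext)
    writeRecording(rec, file.path(dir, fn), format = format,
                   physRange = physRange)
    data.frame(path = fn, subject_id = rec@subjectId,
               task_name = rec@taskName, trial_index = rec@trialIndex,
               fs = rec@fs, n_channels = nrow(rec@data),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  manifestPath <- file.path(dir, "manifest.tsv")
  con <- file(manifestPath, "w")
  writeLines(paste0("# format_version: ", MANIFEST_VERSION), con)
  close(con)
  suppressWarnings(utils::write.table(manifest, manifestPath, sep = "\t",
                                      row.names = FALSE, quote = FALSE,
                                      append = TRUE))
  invisible(manifestPath)
}

#' @rdname writeCorpus
#' @param manifestPath path to a `manifest.tsv` written by `writeCorpus`.
#' @param protocol optional [protocolConfig()] to attach; inferred from the
#'   first recording when NULL.
#' @export
readCorpus <- function(manifestPath, protocol = NULL) {
  if (!file.exists(manifestPath)) stop("manifest not found: ", manifestPath)
  first <- readLines(manifestPath, n = 1L)
  ver <- sub("^#\\s*format_version:\\s*", "", first)
  if (!startsWith(first, "#") || !identical(ver, MANIFEST_VERSION))
    stop("unsupported manifest format_version: ", ver)
  manifest <- utils::read.table(manifestPath, sep = "\t", header = TRUE,
                                skip = 1L, stringsAsFactors = FALSE)
  need <- c("path", "subject_id", "task_name", "trial_index")
  if (!all(need %in% colnames(manifest)))
    stop("manifest lacks required columns")
  key <- paste(manifest$subject_id, manifest$task_name,
               manifest$trial_index)
  if (anyDuplicated(key))
    stop("duplicate (subject, task, trial) in manifest: ",
         key[duplicated(key)][1])
  dir <- dirname(manifestPath)
  recs <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    f <- file.path(dir, manifest$path[i])
    if (!file.exists(f))
      stop("manifest entry refers to a missing file: ", manifest$path[i],
           " (subject ", manifest$subject_id[i], ", task ",
           manifest$task_name[i], ", trial ", manifest$trial_index[i], ")")
    rec <- readRecording(f)
    ## labels in the manifest are authoritative
    rec@subjectId <- as.character(manifest$subject_id[i])
    rec@taskName <- as.character(manifest$task_name[i])
    rec@trialIndex <- as.integer(manifest$trial_index[i])
    recs[[i]] <- rec
  }
  if (is.null(protocol)) {
    r1 <- recs[[1]]
    nTrials <- max(manifest$trial_index) + 1L
    protocol <- list(nTrials = nTrials,
                     trialDurationS = ncol(r1@data) / r1@fs, fs = r1@fs)
  }
  new("EEGCorpus", recordings = recs, protocol = unclass(protocol))
}
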