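#' The nine-task authentication battery
#'
#' Returns the default battery of nine mental tasks with their attributes:
#' whether the task involves an external stimulus, whether it involves a
#' personally chosen secret, its imagery type, and whether it is performed
#' with eyes open. Tasks span relaxed breathing (eyes closed and open),
#' imagined sport, imagined song (eyes closed and open), imagined speech,
#' listening to 40 Hz amplitude-modulated noise, imagining a chosen face,
#' and a cued face/number/word sequence.
#'
#' @return a data.frame with columns `task`, `description`, `has_stimulus`,
#'   `has_secret`, `imagery` (one of none/motor/aural/visual) and
#'   `eyes_open`, one row per task in canonical battery order.
#' @examples
#' taskBattery()
#' @export
taskBattery <- function() {
  data.frame(
    task = c("breathe", "breathe_open", "sport", "song", "song_open",
             "speech", "listen", "face", "sequence"),
    description = c(
      "Relaxed breathing",
      "Relaxed breathing with eyes open",
      "Imagine attempting a chosen physical activity",
      "Imagine hearing a song",
      "Song task, with eyes open",
      "Imagine a chosen spoken phrase",
      "Listen to noise modulated at 40 Hz",
      "Imagine a chosen person's face",
      "Imagine a face, number, and word on cues with eyes open"),
    has_stimulus = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE,
                     FALSE, TRUE),
    has_secret = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE,
                   TRUE),
    imagery = c("none", "none", "motor", "aural", "aural", "aural",
                "none", "visual", "visual"),
    eyes_open = c(FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
                  TRUE),
    stringsAsFactors = FALSE
  )
}

## Resolve a task name to its battery row; errors on unknown names.
taskSpec <- function(name, battery = taskBattery()) {
  i <- match(name, battery$task)
  if (is.na(i)) stop("unknown task name: '", name, "'")
  battery[i, , drop = FALSE]
}
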