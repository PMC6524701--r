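#' Electrode configurations (montages)
#'
#' Named subsets of the channel set used for feature extraction:
#' `left3` (left concha, canal-front, canal-back), `right3` (right ear
#' analog), `both6` (all six ear electrodes), `all` (both ears plus Fp1;
#' the mastoid is excluded by default), `fp1` (the scalp validation
#' electrode alone) and `single:<label>` for any single channel.
#'
#' @param name montage name, see above.
#' @param includeMastoid include `R_mastoid` in the `all` montage.
#' @return a list of class `earauth_montage` with `name` and the ordered
#'   `labels`.
#' @examples
#' montageSelection("left3")$labels
#' montageSelection("single:L_front")
#' @export
montageSelection <- function(name = "left3", includeMastoid = FALSE) {
  labels <- if (startsWith(name, "single:")) {
    lab <- sub("^single:", "", name)
    if (!lab %in% allChannels())
      stop("unknown channel label in montage: '", lab, "'")
    lab
  } else {
    switch(name,
           left3 = c("L_concha", "L_front", "L_back"),
           right3 = c("R_concha", "R_front", "R_back"),
           both6 = earChannels(),
           all = c(earChannels(), "Fp1",
                   if (includeMastoid) "R_mastoid"),
           fp1 = "Fp1",
           stop("unknown montage name: '", name, "'"))
  }
  structure(list(name = name, labels = labels),
            class = c("earauth_montage", "list"))
}

asMontage <- function(m) {
  if (inherits(m, "earauth_montage")) m else montageSelection(m)
}
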