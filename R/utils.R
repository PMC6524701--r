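## Internal helpers shared across modules.

## Canonical channel order: three electrodes per earpiece (concha,
## canal-front, canal-back), a frontal scalp validation site and the right
## mastoid kept for re-referencing. Signals are already referenced at the
## left mastoid; that reference channel is not emitted.
earChannels <- function() {
  c("L_concha", "L_front", "L_back", "R_concha", "R_front", "R_back")
}

allChannels <- function() {
  c(earChannels(), "Fp1", "R_mastoid")
}

## Classical EEG frequency bands (Hz), used for subject fingerprints.
eegBands <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 12),
       beta = c(12, 30), gamma = c(30, 50))
}

#' @importFrom stats rnorm runif predict
NULL

## Deterministic seed derivation: fold integer components into [1, 2^31-2]
## so every stage can own an independent stream derived from one master seed.
deriveSeed <- function(...) {
  parts <- c(...)
  stopifnot(length(parts) >= 1L, all(is.finite(parts)))
  h <- 104729
  m <- 2147483587  # prime below 2^31
  for (p in as.numeric(parts)) {
    h <- (h * 7919 + (abs(p) %% m)) %% m
  }
  as.integer(h + 1)
}

## Round half away from zero (report formatting for rate tables).
roundHalfUp <- function(x, digits = 5L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Hash a character string to an integer (stable across sessions).
stringSeed <- function(s) {
  deriveSeed(utf8ToInt(paste(s, collapse = "")))
}
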