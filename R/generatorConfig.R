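#' Generator configuration
#'
#' Settings that govern the synthetic EEG generator: band edges, the
#' between-subject spread of band gains, eyes-open alpha attenuation, the
#' 40 Hz steady-state amplitude, secret-signature ranges, sensor noise and
#' the optional EMG contamination band. Defaults are chosen so that the
#' subject fingerprint dominates the task secrets (authentication is
#' learnable but not trivial) and, with EMG disabled, essentially all
#' discriminative structure lies below 32 Hz.
#'
#' @param bands named list of c(lo, hi) band edges in Hz.
#' @param bandBase baseline relative amplitude multiplier per band (the
#'   population-average spectral shape on top of the 1/f background).
#' @param backgroundAmp overall amplitude scale of the 1/f background
#'   (microvolt-Hz units; sets the broadband RMS).
#' @param slope exponent of the background amplitude rolloff (amplitude
#'   proportional to f^-slope, i.e. power f^-2*slope).
#' @param gainSpreadLog standard deviation of per-channel, per-band log
#'   gains between subjects; the subject-separability knob.
#' @param bandSpreadScale per-band multiplier on `gainSpreadLog`:
#'   low-frequency rhythms vary much less between individuals than the
#'   alpha/beta range, and a bounded delta spread also keeps its spectral
#'   leakage from swamping the alpha band in short windows.
#' @param peakAmp amplitude scale (microvolt) of each subject's stable
#'   narrowband oscillatory peaks (one per band up to beta; the analog of
#'   the individual alpha peak); per-channel amplitudes ride on the
#'   fingerprint gains.
#' @param peakGridHz frequency grid the stable peaks are drawn on (Hz);
#'   matches the 2 Hz bin spacing of 500 ms analysis windows so peak power
#'   is stable across windows.
#' @param peakAmpJitterLog standard deviation of per-peak log amplitude
#'   multipliers: subjects sharing a peak frequency still express it with
#'   individual strength.
#' @param alphaOpenAttenuation length-2 range from which each subject's
#'   eyes-open alpha attenuation factor is drawn (values in (0, 1]).
#' @param assrAmplitude length-2 range (microvolt) for the 40 Hz
#'   steady-state response amplitude during the listen task.
#' @param secretFreqRange,secretAmpRange ranges for secret-signature center
#'   frequencies (Hz) and amplitudes (microvolt). Kept below 32 Hz so the
#'   high-pass control analysis has no secret signal to find.
#' @param nSecretComponents sinusoidal components per task secret.
#' @param noiseSd white sensor-noise standard deviation (microvolt).
#' @param mastoidScale multiplier for neural content on the right mastoid
#'   (a mastoid picks up little cortical signal).
#' @param emg list: `enabled` (add >32 Hz EMG-like contamination),
#'   `amplitude` (microvolt), `band` (Hz), `discriminative` (scale the EMG
#'   amplitude by a subject-specific gain; used only as a control of the
#'   EMG control analysis).
#' @return a validated list of class `earauth_config`.
#' @examples
#' cfg <- generatorConfig(gainSpreadLog = 0.5)
#' @export
generatorConfig <- function(bands = eegBands(),
                            bandBase = c(delta = 0.8, theta = 0.8,
                                         alpha = 3, beta = 0.6,
                                         gamma = 0.12),
                            backgroundAmp = 1800,
                            slope = 1,
                            gainSpreadLog = 1.2,
                            bandSpreadScale = c(delta = 0.25, theta = 0.4,
                                                alpha = 0.4, beta = 1,
                                                gamma = 1),
                            peakAmp = 2,
                            peakGridHz = 2,
                            peakAmpJitterLog = 0.5,
                            alphaOpenAttenuation = c(0.35, 0.6),
                            assrAmplitude = c(0.8, 1.5),
                            secretFreqRange = c(6, 28),
                            secretAmpRange = c(0.5, 1.2),
                            nSecretComponents = 2L,
                            noiseSd = 0.6,
                            mastoidScale = 0.2,
                            emg = list(enabled = FALSE, amplitude = 4,
                                       band = c(35, 80),
                                       discriminative = FALSE)) {
  cfg <- list(bands = bands, bandBase = bandBase,
              backgroundAmp = backgroundAmp, slope = slope,
              gainSpreadLog = gainSpreadLog,
              bandSpreadScale = bandSpreadScale,
              peakAmp = peakAmp, peakGridHz = peakGridHz,
              peakAmpJitterLog = peakAmpJitterLog,
              alphaOpenAttenuation = alphaOpenAttenuation,
              assrAmplitude = assrAmplitude,
              secretFreqRange = secretFreqRange,
              secretAmpRange = secretAmpRange,
              nSecretComponents = as.integer(nSecretComponents),
              noiseSd = noiseSd, mastoidScale = mastoidScale,
              emg = utils::modifyList(
                list(enabled = FALSE, amplitude = 4, band = c(35, 80),
                     discriminative = FALSE), emg))
  validateGeneratorConfig(cfg)
  class(cfg) <- c("earauth_config", "list")
  cfg
}

validateGeneratorConfig <- function(cfg) {
  pos <- function(x) all(is.finite(x)) && all(x > 0)
  if (!pos(cfg$backgroundAmp) || !pos(cfg$bandBase) || !pos(cfg$noiseSd) ||
      !pos(cfg$assrAmplitude) || !pos(cfg$secretAmpRange) ||
      !pos(cfg$secretFreqRange) || !pos(cfg$mastoidScale))
    stop("generator configuration error: amplitudes, gains and ranges must be strictly positive")
  if (cfg$gainSpreadLog < 0)
    stop("generator configuration error: gainSpreadLog must be >= 0")
  if (!pos(cfg$peakAmp) || !pos(cfg$peakGridHz))
    stop("generator configuration error: peakAmp and peakGridHz must be strictly positive")
  if (cfg$peakAmpJitterLog < 0)
    stop("generator configuration error: peakAmpJitterLog must be >= 0")
  if (any(cfg$alphaOpenAttenuation <= 0) || any(cfg$alphaOpenAttenuation > 1))
    stop("generator configuration error: alphaOpenAttenuation range must lie in (0, 1]")
  for (b in cfg$bands)
    if (length(b) != 2L || b[1] >= b[2] || b[1] < 0)
      stop("generator configuration error: invalid band edges")
  if (!setequal(names(cfg$bandBase), names(cfg$bands)))
    stop("generator configuration error: bandBase names must match bands")
  if (!setequal(names(cfg$bandSpreadScale), names(cfg$bands)) ||
      any(cfg$bandSpreadScale < 0))
    stop("generator configuration error: bandSpreadScale must be non-negative and match bands")
  if (cfg$emg$amplitude <= 0 || diff(cfg$emg$band) <= 0)
    stop("generator configuration error: invalid EMG settings")
  invisible(TRUE)
}

#' Acquisition protocol configuration
#'
#' The protocol collects, for every subject and every task, `nTrials`
#' trials of `trialDurationS` seconds at `fs` Hz (default 10 x 10 s at
#' 200 Hz, i.e. 100 s per (subject, task) and exactly 200 windows of 100
#' samples).
#'
#' @param nTrials trials per (subject, task); acquired as two sets of
#'   nTrials/2.
#' @param trialDurationS trial duration in seconds.
#' @param fs sampling rate in Hz.
#' @return a list of class `earauth_protocol`.
#' @export
protocolConfig <- function(nTrials = 10L, trialDurationS = 10, fs = 200) {
  if (nTrials < 1L) stop("nTrials must be >= 1")
  if (trialDurationS <= 0) stop("trial duration must be positive")
  if (fs < 100) stop("fs must be >= 100 Hz")
  structure(list(nTrials = as.integer(nTrials),
                 trialDurationS = trialDurationS, fs = fs),
            class = c("earauth_protocol", "list"))
}
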