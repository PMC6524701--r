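#' Draw a synthetic participant profile
#'
#' Creates a synthetic participant: per-channel, per-band log-normal
#' spectral gains (the subject fingerprint), an eyes-open alpha
#' attenuation factor, a 40 Hz steady-state amplitude, and secret
#' signatures for every task of the battery that involves a chosen secret.
#' Deterministic for a given (seed, config).
#'
#' @param seed non-negative integer.
#' @param config a [generatorConfig()].
#' @param subjectId subject identifier (default `"S<seed>"`).
#' @param battery task battery; secrets are drawn only for rows with
#'   `has_secret`.
#' @return a [SubjectProfile-class].
#' @examples
#' p <- makeSubjectProfile(1)
#' p@fingerprintGains[1:2, ]
#' @export
makeSubjectProfile <- function(seed, config = generatorConfig(),
                               subjectId = sprintf("S%d", seed),
                               battery = taskBattery()) {
  if (length(seed) != 1L || !is.finite(seed) || seed < 0 ||
      seed != round(seed))
    stop("seed must be a non-negative integer")
  validateGeneratorConfig(config)
  set.seed(deriveSeed(seed, 11L))
  chans <- allChannels()
  bands <- names(config$bands)
  z <- matrix(rnorm(length(chans) * length(bands)), length(chans),
              length(bands), dimnames = list(chans, bands))
  ## band-dependent identity spread: slow rhythms are far more uniform
  ## across people than the alpha/beta range (and a bounded delta keeps
  ## its leakage out of the alpha measurement band)
  z <- sweep(z, 2L, config$bandSpreadScale[bands], "*")
  gains <- exp(config$gainSpreadLog * z)
  ## stable oscillatory peaks per channel and band up to the beta range
  ## (the analog of the individual alpha peak frequency plus site-specific
  ## spectral idiosyncrasy), on the analysis frequency grid; the wide,
  ## information-rich alpha and beta ranges carry two distinct peaks per
  ## channel
  peakable <- names(config$bands)[vapply(config$bands, function(b)
    b[1] < 30, logical(1))]
  nPeaks <- ifelse(peakable %in% c("alpha", "beta"), 2L, 1L)
  cols <- unlist(lapply(seq_along(peakable), function(i)
    paste0(peakable[i], seq_len(nPeaks[i]))))
  peaks <- matrix(NA_real_, length(chans), length(cols),
                  dimnames = list(chans, cols))
  alphaRange <- config$bands[["alpha"]]
  for (i in seq_along(peakable)) {
    b <- peakable[i]
    grid <- peakGrid(config$bands[[b]], config$peakGridHz)
    ## peaks of neighbouring bands stay out of the alpha range so the
    ## eyes-closed/eyes-open alpha contrast is not diluted by
    ## un-attenuated theta or beta peaks on the band boundary
    if (b != "alpha" && !is.null(alphaRange))
      grid <- setdiff(grid, seq(alphaRange[1], alphaRange[2],
                                by = config$peakGridHz))
    if (!length(grid))
      grid <- peakGrid(config$bands[[b]], config$peakGridHz)
    k <- min(nPeaks[i], length(grid))
    for (ch in seq_along(chans)) {
      draw <- grid[sample.int(length(grid), k)]
      peaks[ch, paste0(b, seq_len(k))] <- draw
    }
  }
  peakAmps <- matrix(exp(config$peakAmpJitterLog *
                           rnorm(length(peaks))),
                     nrow(peaks), ncol(peaks), dimnames = dimnames(peaks))
  secretGrid <- peakGrid(config$secretFreqRange, config$peakGridHz)
  secrets <- list(); style <- list()
  styleSteps <- config$peakGridHz * (-3:3)
  for (i in seq_len(nrow(battery))) {
    if (!battery$has_secret[i]) next
    secrets[[battery$task[i]]] <- list(
      freqs = secretGrid[sample.int(length(secretGrid),
                                    config$nSecretComponents)],
      amps = runif(config$nSecretComponents, config$secretAmpRange[1],
                   config$secretAmpRange[2]),
      weights = stats::setNames(runif(length(chans), 0.3, 1), chans))
    style[[battery$task[i]]] <- styleSteps[sample.int(
      length(styleSteps), config$nSecretComponents, replace = TRUE)]
  }
  new("SubjectProfile",
      subjectId = subjectId,
      fingerprintGains = gains,
      peakFreqs = peaks,
      peakAmps = peakAmps,
      alphaOpenAttenuation = runif(1, config$alphaOpenAttenuation[1],
                                   config$alphaOpenAttenuation[2]),
      assrAmplitude = runif(1, config$assrAmplitude[1],
                            config$assrAmplitude[2]),
      emgGain = exp(config$gainSpreadLog * rnorm(1)),
      taskSecrets = secrets,
      secretStyle = style,
      fitNoise = 1,
      seed = as.integer(seed))
}

#' Derive an imposter profile from a target
#'
#' Models a spoofing attacker: a different neural identity (fingerprint
#' gains drawn independently, never copied) whose task secrets interpolate
#' between independent draws (`knowledgeLevel = 0`) and the target's exact
#' secrets (`knowledgeLevel = 1`, the "leaked passthought list" scenario).
#' An optional `fitNoise > 1` models the degraded electrode fit of wearing
#' someone else's earpiece.
#'
#' @param target the targeted [SubjectProfile-class].
#' @param knowledgeLevel fraction in [0, 1].
#' @param seed seed for the imposter's own identity.
#' @param config a [generatorConfig()].
#' @param base optional [SubjectProfile-class] supplying the imposter's
#'   identity (an "inside" imposter drawn from the enrolled pool); when
#'   NULL a fresh identity is drawn from `seed`.
#' @param fitNoise sensor-noise multiplier (>= 1).
#' @param subjectId identifier for the imposter.
#' @return a [SubjectProfile-class].
#' @export
makeImposterProfile <- function(target, knowledgeLevel, seed,
                                config = generatorConfig(), base = NULL,
                                fitNoise = 1,
                                subjectId = sprintf("imposter_%s_%d",
                                                    target@subjectId, seed)) {
  if (length(knowledgeLevel) != 1L || !is.finite(knowledgeLevel) ||
      knowledgeLevel < 0 || knowledgeLevel > 1)
    stop("knowledgeLevel must lie in [0, 1]")
  own <- base %||% makeSubjectProfile(seed, config, subjectId = subjectId)
  if (identical(unname(own@fingerprintGains),
                unname(target@fingerprintGains)))
    stop("imposter identity must differ from the target's; use a different seed or base")
  k <- knowledgeLevel
  secrets <- own@taskSecrets
  for (tn in names(secrets)) {
    tgt <- target@taskSecrets[[tn]]
    if (is.null(tgt)) next
    secrets[[tn]] <- list(
      freqs = (1 - k) * secrets[[tn]]$freqs + k * tgt$freqs,
      amps = (1 - k) * secrets[[tn]]$amps + k * tgt$amps,
      weights = (1 - k) * secrets[[tn]]$weights + k * tgt$weights)
  }
  new("SubjectProfile",
      subjectId = subjectId,
      fingerprintGains = own@fingerprintGains,
      peakFreqs = own@peakFreqs,
      peakAmps = own@peakAmps,
      alphaOpenAttenuation = own@alphaOpenAttenuation,
      assrAmplitude = own@assrAmplitude,
      emgGain = own@emgGain,
      taskSecrets = secrets,
      secretStyle = own@secretStyle,
      fitNoise = fitNoise,
      seed = as.integer(seed))
}

## Frequencies of the analysis grid strictly inside a range.
peakGrid <- function(range, gridHz) {
  g <- seq(ceiling(range[1] / gridHz) * gridHz,
           floor(range[2] / gridHz) * gridHz, by = gridHz)
  if (!length(g)) stop("no grid frequency inside range [",
                       range[1], ", ", range[2], "]")
  g
}

## Reflect a frequency back into [lo, hi] (stays on the grid when the
## inputs are).
reflectIntoRange <- function(f, range) {
  if (f > range[2]) f <- range[2] - (f - range[2])
  if (f < range[1]) f <- range[1] + (range[1] - f)
  min(max(f, range[1]), range[2])
}

## Band containing a frequency (NA when outside every band).
bandOf <- function(f, bands) {
  for (b in names(bands))
    if (f >= bands[[b]][1] && f < bands[[b]][2]) return(b)
  NA_character_
}

## Amplitude spectrum (per rFFT bin) for one channel under one task state.
## Background: backgroundAmp / f^slope, high-passed at 0.5 Hz, multiplied
## inside each band by bandBase * fingerprint gain (alpha additionally
## attenuated with eyes open); a small flat tail multiplier beyond gamma.
channelAmplitudeSpectrum <- function(freqs, profile, channel, config,
                                     eyesOpen) {
  amp <- config$backgroundAmp / pmax(freqs, 1)^config$slope
  amp[freqs < 0.5] <- 0
  mult <- rep(0.05, length(freqs))  # out-of-band tail
  for (b in names(config$bands)) {
    rng <- config$bands[[b]]
    inb <- freqs >= rng[1] & freqs < rng[2]
    g <- config$bandBase[[b]] * profile@fingerprintGains[channel, b]
    if (b == "alpha" && eyesOpen) g <- g * profile@alphaOpenAttenuation
    mult[inb] <- g
  }
  amp * mult
}

#' Synthesize one trial of multichannel EEG
#'
#' Generates a single trial for one subject and task: a 1/f background of
#' band-limited noise components scaled by the subject's fingerprint gains
#' (alpha attenuated with eyes open), a 40 Hz steady-state component for
#' the listen task, the subject's secret signature for tasks with a chosen
#' secret, optional >32 Hz EMG-like contamination, and white sensor noise.
#' All channels are emitted already referenced at the left mastoid.
#' Deterministic per seed.
#'
#' @param profile a [SubjectProfile-class].
#' @param task a task name from the battery (or one battery row).
#' @param protocol a [protocolConfig()].
#' @param trialIndex zero-based trial index.
#' @param seed integer RNG seed for this trial.
#' @param config a [generatorConfig()].
#' @return an [EEGRecording-class] of `length(allChannels())` channels by
#'   `round(trialDurationS * fs)` samples, in microvolts.
#' @examples
#' rec <- synthesizeTrial(makeSubjectProfile(1), "breathe",
#'                        protocolConfig(trialDurationS = 2), seed = 7)
#' @export
synthesizeTrial <- function(profile, task, protocol = protocolConfig(),
                            trialIndex = 0L, seed = 1L,
                            config = generatorConfig()) {
  spec <- if (is.data.frame(task)) task else taskSpec(task)
  if (protocol$trialDurationS <= 0) stop("trial duration must be positive")
  if (protocol$fs < 100) stop("fs must be >= 100 Hz")
  n <- round(protocol$trialDurationS * protocol$fs)
  fs <- protocol$fs
  set.seed(seed)
  chans <- allChannels()
  nyq <- floor(n / 2)
  freqs <- seq_len(nyq) * fs / n
  tt <- seq_len(n) / fs
  dat <- matrix(0, length(chans), n, dimnames = list(chans, NULL))

  ## shared per-trial phases so peaks/secrets/ASSR are coherent across
  ## channels
  assrPhase <- runif(1, 0, 2 * pi)
  pk <- profile@peakFreqs
  peakPhase <- matrix(runif(length(pk), 0, 2 * pi), nrow(pk), ncol(pk),
                      dimnames = dimnames(pk))
  secret <- profile@taskSecrets[[spec$task]]
  if (!is.null(secret)) {
    secPhase <- runif(length(secret$freqs), 0, 2 * pi)
    secJitter <- runif(1, 0.9, 1.1)
  }

  for (ci in seq_along(chans)) {
    ch <- chans[ci]
    amp <- channelAmplitudeSpectrum(freqs, profile, ch, config,
                                    spec$eyes_open)
    if (config$emg$enabled) {
      inb <- freqs >= config$emg$band[1] & freqs <= config$emg$band[2]
      eamp <- config$emg$amplitude
      if (config$emg$discriminative) eamp <- eamp * profile@emgGain
      ## flat band-limited component with time-domain RMS = eamp
      amp[inb] <- amp[inb] + eamp * n / sqrt(2 * sum(inb))
    }
    if (ch == "R_mastoid") amp <- amp * config$mastoidScale
    ## random-phase spectrum -> real signal via inverse FFT
    re <- rnorm(nyq); im <- rnorm(nyq)
    if (n %% 2 == 0) im[nyq] <- 0  # Nyquist bin must be real
    X <- complex(real = amp * re, imaginary = amp * im) / sqrt(2)
    full <- complex(real = rep(0, n))
    full[2:(nyq + 1)] <- X
    conjIdx <- seq(n, nyq + 2)
    full[conjIdx] <- Conj(X[seq_len(length(conjIdx))])
    x <- Re(stats::fft(full, inverse = TRUE)) / n
    neuralScale <- if (ch == "R_mastoid") config$mastoidScale else 1
    ## stable narrowband peaks: the deterministic part of the fingerprint
    for (b in colnames(pk)) {
      if (is.na(pk[ch, b])) next
      parent <- sub("[0-9]+$", "", b)
      g <- config$bandBase[[parent]] * profile@fingerprintGains[ch, parent] *
        profile@peakAmps[ch, b]
      if (parent == "alpha" && spec$eyes_open)
        g <- g * profile@alphaOpenAttenuation
      x <- x + neuralScale * config$peakAmp * g *
        sin(2 * pi * pk[ch, b] * tt + peakPhase[ch, b])
    }
    if (spec$task == "listen")
      x <- x + neuralScale * profile@assrAmplitude *
        sin(2 * pi * 40 * tt + assrPhase)
    if (!is.null(secret)) {
      ## a secret's neural expression is entangled with the subject's own
      ## fingerprint: component frequencies shift by the subject's
      ## personal style offset and amplitudes ride on the channel's band
      ## gain, so knowing the secret's content does not reproduce how the
      ## owner expresses it
      style <- profile@secretStyle[[spec$task]] %||%
        rep(0, length(secret$freqs))
      for (j in seq_along(secret$freqs)) {
        fj <- reflectIntoRange(secret$freqs[j] + style[j],
                               config$secretFreqRange)
        bnd <- bandOf(fj, config$bands)
        expr <- if (is.na(bnd)) 1 else profile@fingerprintGains[ch, bnd]
        x <- x + neuralScale * secret$weights[[ch]] * secret$amps[j] *
          expr * secJitter * sin(2 * pi * fj * tt + secPhase[j])
      }
    }
    x <- x + rnorm(n, 0, config$noiseSd * profile@fitNoise)
    dat[ci, ] <- x
  }
  new("EEGRecording", data = dat, fs = fs, channelLabels = chans,
      subjectId = profile@subjectId, taskName = spec$task,
      trialIndex = as.integer(trialIndex))
}

#' Synthesize a full corpus
#'
#' Runs the acquisition protocol for every profile: all nine battery tasks
#' times `protocol$nTrials` trials each. Trial seeds are derived from the
#' master seed, so identical inputs give bit-identical corpora.
#'
#' @param profiles list of [SubjectProfile-class] with unique subject ids.
#' @param protocol a [protocolConfig()].
#' @param seed master integer seed.
#' @param config a [generatorConfig()].
#' @param battery task battery (default the nine-task battery).
#' @return an [EEGCorpus-class] with
#'   `length(profiles) * nrow(battery) * protocol$nTrials` recordings.
#' @examples
#' corpus <- synthesizeCorpus(list(makeSubjectProfile(1)),
#'                            protocolConfig(nTrials = 1,
#'                                           trialDurationS = 1),
#'                            seed = 1)
#' length(corpus)  # 9 recordings
#' @export
synthesizeCorpus <- function(profiles, protocol = protocolConfig(),
                             seed = 1L, config = generatorConfig(),
                             battery = taskBattery()) {
  if (length(profiles) < 1L) stop("need at least one profile")
  ids <- vapply(profiles, subjectId, character(1))
  if (anyDuplicated(ids))
    stop("duplicate subject ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  recs <- vector("list", length(profiles) * nrow(battery) * protocol$nTrials)
  k <- 1L
  for (pi_ in seq_along(profiles)) {
    for (ti in seq_len(nrow(battery))) {
      for (tr in seq_len(protocol$nTrials) - 1L) {
        trialSeed <- deriveSeed(seed, pi_, ti, tr)
        recs[[k]] <- synthesizeTrial(profiles[[pi_]],
                                     battery[ti, , drop = FALSE],
                                     protocol, trialIndex = tr,
                                     seed = trialSeed, config = config)
        k <- k + 1L
      }
    }
  }
  new("EEGCorpus", recordings = recs, protocol = unclass(protocol))
}
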