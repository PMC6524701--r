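#' Run configuration for a full reproduction
#'
#' A persisted RunConfig fully determines every output artifact: generator
#' settings, protocol, montages, schemes, classifier parameters and the
#' master seed. Configurations can be written to and loaded from YAML (or
#' JSON) files.
#'
#' @param nSubjects number of synthetic participants.
#' @param generator a [generatorConfig()] (or a list of overrides).
#' @param protocol a [protocolConfig()] (or a list of overrides).
#' @param montages montage names for the grid.
#' @param schemes scheme names for the grid.
#' @param params an [authParams()] list (or overrides).
#' @param negRatio maximum negatives per positive.
#' @param attemptsPerClassifier spoof attempts per task classifier.
#' @param seed master seed; every stage derives its own stream from it.
#' @return a list of class `earauth_run_config`.
#' @export
runConfig <- function(nSubjects = 7L, generator = list(),
                      protocol = list(), montages = "left3",
                      schemes = "default", params = list(), negRatio = 20,
                      attemptsPerClassifier = 200L, seed = 1L) {
  gen <- if (inherits(generator, "earauth_config")) generator else
    do.call(generatorConfig, generator)
  prot <- if (inherits(protocol, "earauth_protocol")) protocol else
    do.call(protocolConfig, protocol)
  par <- do.call(authParams, params)
  structure(list(nSubjects = as.integer(nSubjects), generator = gen,
                 protocol = prot, montages = montages, schemes = schemes,
                 params = par, negRatio = negRatio,
                 attemptsPerClassifier = as.integer(attemptsPerClassifier),
                 seed = as.integer(seed)),
            class = c("earauth_run_config", "list"))
}

#' @rdname runConfig
#' @param path a YAML (or JSON) file of `runConfig` fields.
#' @export
loadRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(runConfig, raw)
}

#' Reproduce the full analysis from one configuration
#'
#' Drives the pipeline end to end: synthesize the corpus, extract
#' features, train and evaluate the grid over the configured montages and
#' schemes, reshape the per-task FAR/FRR tables, select best tasks and the
#' headline accuracy, run the leave-one-out protocol on each subject's
#' best task, run the four-scheme factor analysis, the alpha-attenuation
#' and EMG control checks, and an inside plus an outside spoof attack on
#' the last subject. All artifacts are written to `outDir` (delimited
#' tables plus a JSON summary) with a manifest; reruns with the same
#' config are identical.
#'
#' @param config an `earauth_run_config` (or path to one).
#' @param outDir output directory.
#' @return invisibly, a list with the in-memory results and the manifest.
#' @export
reproduceStudy <- function(config = runConfig(), outDir) {
  if (is.character(config)) config <- loadRunConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  profiles <- lapply(seq_len(config$nSubjects), function(i)
    makeSubjectProfile(deriveSeed(seed, 5L, i), config$generator,
                       subjectId = sprintf("P%d", i)))
  corpus <- synthesizeCorpus(profiles, config$protocol,
                             seed = deriveSeed(seed, 7L),
                             config = config$generator)
  cache <- stats::setNames(lapply(config$montages, function(m)
    buildFeatures(corpus, m)), config$montages)

  grid <- runFullGrid(corpus, config$montages, config$schemes,
                      config$params, seed = deriveSeed(seed, 9L),
                      negRatio = config$negRatio, featureCache = cache)
  rep1 <- grid$reports[grid$reports$montage == config$montages[1] &
                         grid$reports$scheme == config$schemes[1], ]
  farTab <- tableByTask(rep1, "FAR")
  frrTab <- tableByTask(rep1, "FRR")
  best <- selectBestTasks(rep1)
  fmMain <- cache[[config$montages[1]]]
  ## the leave-one-out protocol needs a third subject to leave out
  loo <- if (config$nSubjects >= 3L) {
    out <- lapply(seq_len(nrow(best$best)), function(i)
      leaveOneOutFar(fmMain, best$best$subject[i], best$best$task[i],
                     scheme = config$schemes[1], params = config$params,
                     seed = deriveSeed(seed, 13L),
                     negRatio = config$negRatio))
    stats::setNames(out, best$best$subject)
  } else list()
  factors <- factorAnalysis(corpus, config$montages[1], config$params,
                            seed = deriveSeed(seed, 17L),
                            negRatio = config$negRatio,
                            featureCache = cache[config$montages[1]])
  alpha <- alphaAttenuationCheck(corpus)
  emg <- emgControlAnalysis(fmMain, config$params,
                            seed = deriveSeed(seed, 19L),
                            negRatio = config$negRatio)

  target <- utils::tail(corpusSubjects(corpus), 1)
  targetProfile <- profiles[[length(profiles)]]
  clfs <- trainTargetClassifiers(fmMain, target, params = config$params,
                                 seed = deriveSeed(seed, 23L),
                                 negRatio = config$negRatio)
  insideImposter <- makeImposterProfile(
    targetProfile, knowledgeLevel = 1, seed = deriveSeed(seed, 29L),
    config = config$generator, base = profiles[[1]],
    subjectId = paste0(subjectId(profiles[[1]]), "_as_", target))
  insideSession <- synthesizeCorpus(list(insideImposter), config$protocol,
                                    seed = deriveSeed(seed, 31L),
                                    config = config$generator)
  attackIn <- runSpoofAttack(clfs, buildFeatures(insideSession,
                                                 config$montages[1]),
                             attemptsPerClassifier =
                               config$attemptsPerClassifier,
                             attackerKind = "inside", truncate = TRUE)
  outsider <- makeImposterProfile(targetProfile, knowledgeLevel = 1,
                                  seed = deriveSeed(seed, 37L),
                                  config = config$generator,
                                  subjectId = "PX")
  attackOut <- runOutsideAttack(corpus, target, outsider,
                                montage = config$montages[1],
                                params = config$params,
                                seed = deriveSeed(seed, 41L),
                                config = config$generator,
                                classifiers = clfs,
                                attemptsPerClassifier =
                                  config$attemptsPerClassifier)

  ## ---- write artifacts ----
  wrote <- character(0)
  putCsv <- function(df, name) {
    p <- file.path(outDir, name)
    utils::write.csv(df, p, row.names = FALSE)
    wrote <<- c(wrote, name)
  }
  putJson <- function(x, name) {
    p <- file.path(outDir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    wrote <<- c(wrote, name)
  }
  putCsv(grid$reports, "grid_reports.csv")
  putCsv(cbind(task = rownames(farTab), farTab), "far_by_task.csv")
  putCsv(cbind(task = rownames(frrTab), frrTab), "frr_by_task.csv")
  putCsv(summarizeByMontage(grid$reports), "montage_summary.csv")
  putCsv(best$best, "best_tasks.csv")
  putCsv(factors, "factor_analysis.csv")
  putCsv(alpha, "alpha_attenuation.csv")
  putCsv(emg$perTarget, "emg_control.csv")
  putJson(list(headline = best$headline,
               leave_one_out_far = loo,
               emg = list(meanError = emg$meanError,
                          meanChance = emg$meanChance),
               attack_inside = attackIn[c("target_subject", "attacker_id",
                                          "attacker_kind", "total_attempts",
                                          "total_successes")],
               attack_outside = attackOut[c("target_subject", "attacker_id",
                                            "attacker_kind",
                                            "total_attempts",
                                            "total_successes")],
               seed = seed), "summary.json")
  putJson(list(artifacts = wrote, nSubjects = config$nSubjects,
               montages = config$montages, schemes = config$schemes,
               seed = seed), "manifest.json")

  invisible(list(grid = grid, far = farTab, frr = frrTab, best = best,
                 loo = loo, factors = factors, alpha = alpha, emg = emg,
                 attackInside = attackIn, attackOutside = attackOut,
                 manifest = wrote))
}
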