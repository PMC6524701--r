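#' Train a target's nine task classifiers
#'
#' One authenticator per battery task for a single target subject; these
#' are the classifiers an imposter attacks.
#'
#' @param fm an [AuthFeatureSet-class] built from the enrolled corpus.
#' @param targetSubject the target.
#' @param scheme scheme name (default `"default"`).
#' @param params an [authParams()] list.
#' @param seed integer seed.
#' @param negRatio maximum negatives per positive.
#' @return named list of [AuthClassifier-class], one per task.
#' @export
trainTargetClassifiers <- function(fm, targetSubject, scheme = "default",
                                   params = authParams(), seed = 1L,
                                   negRatio = 20) {
  tasks <- unique(SummarizedExperiment::colData(fm)$taskName)
  stats::setNames(lapply(tasks, function(tk) {
    trainAndEvaluate(fm, targetSubject, tk, scheme, params,
                     seed = deriveSeed(seed, stringSeed(tk)),
                     negRatio = negRatio)$classifier
  }), tasks)
}

#' Replay a spoof attack against a target's classifiers
#'
#' For each task classifier of the target, scores the imposter's windows
#' of the matching task (the "correct passthought" scenario when the
#' imposter was built with `knowledgeLevel = 1`); the first
#' `attemptsPerClassifier` windows are the attempts and a window is a
#' successful attack iff its score exceeds the decision threshold.
#'
#' @param targetClassifiers named list of [AuthClassifier-class] by task
#'   (e.g. from [trainTargetClassifiers()]).
#' @param imposterFeatures an [AuthFeatureSet-class] of the imposter's
#'   session, extracted with the same montage.
#' @param attemptsPerClassifier attempts per task classifier (default
#'   200).
#' @param attackerKind `"inside"` (attacker appears in the enrolled
#'   corpus) or `"outside"`.
#' @param truncate if TRUE, use all available windows when fewer than
#'   `attemptsPerClassifier`; otherwise error.
#' @return a list of class `earauth_attack_report`: per-classifier
#'   attempts/successes, `total_attempts`, `total_successes`,
#'   `target_subject`, `attacker_id`, `attacker_kind`.
#' @export
runSpoofAttack <- function(targetClassifiers, imposterFeatures,
                           attemptsPerClassifier = 200L,
                           attackerKind = c("inside", "outside"),
                           truncate = FALSE) {
  attackerKind <- match.arg(attackerKind)
  stopifnot(is(imposterFeatures, "AuthFeatureSet"))
  if (ncol(imposterFeatures) == 0L) stop("empty imposter feature set")
  cd <- SummarizedExperiment::colData(imposterFeatures)
  attackerId <- unique(cd$subjectId)
  if (length(attackerId) != 1L)
    stop("imposter features must come from a single attacker")
  targets <- unique(vapply(targetClassifiers, function(c) c@subjectId,
                           character(1)))
  if (length(targets) != 1L)
    stop("classifiers must share one target subject")
  if (attackerId == targets)
    stop("imposter subject must differ from the target subject")
  X <- t(SummarizedExperiment::assay(imposterFeatures, "power"))
  rows <- lapply(names(targetClassifiers), function(tk) {
    idx <- which(cd$taskName == tk)
    if (length(idx) < attemptsPerClassifier) {
      if (!truncate)
        stop("imposter has ", length(idx), " windows for task '", tk,
             "' but ", attemptsPerClassifier, " attempts were requested ",
             "(set truncate = TRUE to use all available)")
    } else idx <- idx[seq_len(attemptsPerClassifier)]
    pred <- predict(targetClassifiers[[tk]], X[idx, , drop = FALSE])
    data.frame(task = tk, attempts = length(idx),
               successes = sum(pred$decisions), stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  structure(list(target_subject = targets, attacker_id = attackerId,
                 attacker_kind = attackerKind, per_classifier = per,
                 total_attempts = sum(per$attempts),
                 total_successes = sum(per$successes)),
            class = c("earauth_attack_report", "list"))
}

#' @export
print.earauth_attack_report <- function(x, ...) {
  cat(sprintf("Spoof attack (%s imposter %s vs %s): %d/%d successful attempts\n",
              x$attacker_kind, x$attacker_id, x$target_subject,
              x$total_successes, x$total_attempts))
  invisible(x)
}

#' Outside-imposter attack, end to end
#'
#' Synthesizes a full nine-task session for an outsider profile whose
#' subject id does not appear in the enrolled corpus, extracts features
#' with the target's montage, and replays [runSpoofAttack()] against the
#' target's classifiers.
#'
#' @param corpus the enrolled [EEGCorpus-class].
#' @param targetSubject the attacked subject.
#' @param outsiderProfile a [SubjectProfile-class]; its id must not
#'   collide with any corpus subject.
#' @param montage montage name.
#' @param params an [authParams()] list.
#' @param seed integer seed (session synthesis and training).
#' @param config [generatorConfig()] for the outsider's session.
#' @param classifiers optional pretrained target classifiers; trained from
#'   the corpus when NULL.
#' @param attemptsPerClassifier attempts per task classifier.
#' @return an `earauth_attack_report` with `attacker_kind = "outside"`.
#' @export
runOutsideAttack <- function(corpus, targetSubject, outsiderProfile,
                             montage = "left3", params = authParams(),
                             seed = 1L, config = generatorConfig(),
                             classifiers = NULL,
                             attemptsPerClassifier = 200L) {
  if (outsiderProfile@subjectId %in% corpusSubjects(corpus))
    stop("outsider id '", outsiderProfile@subjectId,
         "' collides with an enrolled subject")
  protocol <- do.call(protocolConfig, corpus@protocol)
  session <- synthesizeCorpus(list(outsiderProfile), protocol,
                              seed = deriveSeed(seed, 4242L),
                              config = config)
  imposterFm <- buildFeatures(session, montage)
  if (is.null(classifiers)) {
    fm <- buildFeatures(corpus, montage)
    classifiers <- trainTargetClassifiers(fm, targetSubject,
                                          params = params, seed = seed)
  }
  runSpoofAttack(classifiers, imposterFm,
                 attemptsPerClassifier = attemptsPerClassifier,
                 attackerKind = "outside")
}
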