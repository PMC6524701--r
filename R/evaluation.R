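#' Error rates from attempt counts
#'
#' Given `FA` false (imposter) attempts of which `FAS` were wrongly
#' accepted and `TA` true attempts of which `TAU` were wrongly rejected,
#' computes FAR = FAS/FA, FRR = TAU/TA, HTER = (FAR + FRR)/2,
#' ACC = 100 (1 - HTER), and the plain binary error rate
#' epsilon = (FAS + TAU)/(FA + TA).
#'
#' @param FA,FAS,TA,TAU non-negative counts with `FA >= FAS`, `TA >= TAU`
#'   and both denominators positive.
#' @param context optional named list of labels attached to the report.
#' @return an [EvalReport-class].
#' @examples
#' computeRates(FA = 200, FAS = 2, TA = 80, TAU = 0)  # FAR = 0.01
#' @export
computeRates <- function(FA, FAS, TA, TAU, context = list()) {
  if (FA <= 0 || TA <= 0)
    stop("FA and TA must be positive (rates are undefined otherwise)")
  if (FAS < 0 || TAU < 0 || FAS > FA || TAU > TA)
    stop("counts must satisfy FA >= FAS >= 0 and TA >= TAU >= 0")
  FAR <- FAS / FA
  FRR <- TAU / TA
  acc <- computeAccuracy(FAR, FRR)
  new("EvalReport", FA = FA, FAS = FAS, TA = TA, TAU = TAU,
      FAR = FAR, FRR = FRR, HTER = acc$HTER, ACC = acc$ACC,
      epsilon = (FAS + TAU) / (FA + TA), context = context)
}

#' Half total error rate and accuracy
#'
#' HTER = (FAR + FRR)/2; ACC = 100 (1 - HTER), on the percent scale.
#'
#' @param FAR,FRR rates in [0, 1].
#' @return list with `HTER` (rate) and `ACC` (percent).
#' @examples
#' computeAccuracy(0, 0.0036)$ACC  # 99.82
#' @export
computeAccuracy <- function(FAR, FRR) {
  if (FAR < 0 || FAR > 1 || FRR < 0 || FRR > 1)
    stop("FAR and FRR must lie in [0, 1]")
  HTER <- (FAR + FRR) / 2
  list(HTER = HTER, ACC = 100 * (1 - HTER))
}

#' Evaluate a classifier on labeled features
#'
#' Scores every instance and counts decisions: negatives are false
#' attempts (accepted ones are FAS), positives are true attempts (rejected
#' ones are TAU).
#'
#' @param clf an [AuthClassifier-class].
#' @param X windows x features matrix (defaults to the labeled set's
#'   holdout when `ls` is given).
#' @param y 0/1 labels for the rows of `X`.
#' @param ls optionally, an `earauth_labeled_set`; its withheld test third
#'   is used.
#' @param context labels to attach to the report.
#' @return an [EvalReport-class].
#' @export
evaluateClassifier <- function(clf, X = NULL, y = NULL, ls = NULL,
                               context = list()) {
  if (!is.null(ls)) { X <- ls$testX; y <- ls$testY }
  if (is.null(X) || is.null(y)) stop("provide X and y, or ls")
  if (length(unique(y)) < 2L)
    stop("test set must contain both classes")
  pred <- predict(clf, X)
  neg <- y == 0L; pos <- y == 1L
  computeRates(FA = sum(neg), FAS = sum(pred$decisions[neg]),
               TA = sum(pos), TAU = sum(!pred$decisions[pos]),
               context = context)
}

#' Mean of per-participant rates, report-rounded
#'
#' Arithmetic mean of a vector of rates; the report value is rounded half
#' away from zero to `digits` decimals, matching the formatting of the
#' result tables.
#'
#' @param values rates in [0, 1].
#' @param digits decimals for the report value; `NULL` returns the raw
#'   mean.
#' @return the (rounded) mean rate.
#' @examples
#' aggregateMean(c(0, 0.0125, 0, 0.0125, 0.0125, 0.0250, 0))  # 0.00893
#' @export
aggregateMean <- function(values, digits = 5L) {
  if (!length(values)) stop("empty rate list")
  if (any(values < 0 | values > 1)) stop("rates must lie in [0, 1]")
  m <- mean(values)
  if (is.null(digits)) m else roundHalfUp(m, digits)
}

## Shared worker: assemble, train, evaluate one (subject, task) target.
trainAndEvaluate <- function(fm, subject, task, scheme, params, seed,
                             negRatio = 20, excludeSubjects = character(),
                             context = list()) {
  ls <- assembleTrainingSet(fm, subject, task, scheme = scheme,
                            negRatio = negRatio, seed = seed,
                            excludeSubjects = excludeSubjects)
  clf <- trainAuthenticator(ls, params, seed = deriveSeed(seed, 977L))
  rep <- evaluateClassifier(clf, ls = ls, context = context)
  list(classifier = clf, report = rep, labeledSet = ls)
}

reportRow <- function(rep) {
  ctx <- rep@context
  data.frame(subject = ctx$subject %||% NA_character_,
             task = ctx$task %||% NA_character_,
             montage = ctx$montage %||% NA_character_,
             scheme = ctx$scheme %||% NA_character_,
             FA = rep@FA, FAS = rep@FAS, TA = rep@TA, TAU = rep@TAU,
             FAR = rep@FAR, FRR = rep@FRR, HTER = rep@HTER, ACC = rep@ACC,
             epsilon = rep@epsilon, stringsAsFactors = FALSE)
}

#' Run the full authentication grid
#'
#' Trains and evaluates one authenticator per (subject, task, montage,
#' scheme) combination and returns a tidy table of attempt counts and
#' rates, one row per report.
#'
#' @param corpus an [EEGCorpus-class].
#' @param montages character vector of montage names.
#' @param schemes character vector of scheme names.
#' @param params an [authParams()] list.
#' @param seed master integer seed.
#' @param negRatio maximum negatives per positive.
#' @param keepClassifiers also return the fitted classifiers (named
#'   `subject|task|montage|scheme`).
#' @param featureCache optional named list of prebuilt
#'   [AuthFeatureSet-class] objects keyed by montage name, to avoid
#'   re-extracting features.
#' @return a list of class `earauth_grid` with elements `reports` (tidy
#'   data.frame) and optionally `classifiers`.
#' @export
runFullGrid <- function(corpus, montages = "left3", schemes = "default",
                        params = authParams(), seed = 1L, negRatio = 20,
                        keepClassifiers = FALSE, featureCache = NULL) {
  stopifnot(is(corpus, "EEGCorpus"))
  subjects <- corpusSubjects(corpus)
  if (length(subjects) < 2L) stop("need at least two subjects")
  tasks <- corpusTasks(corpus)
  rows <- list(); clfs <- list()
  for (m in montages) {
    fm <- featureCache[[m]] %||% buildFeatures(corpus, m)
    for (sch in schemes) {
      for (s in subjects) {
        for (tk in tasks) {
          fit <- trainAndEvaluate(
            fm, s, tk, sch, params,
            seed = deriveSeed(seed, stringSeed(m), stringSeed(sch)),
            negRatio = negRatio,
            context = list(subject = s, task = tk, montage = m,
                           scheme = sch))
          rows[[length(rows) + 1L]] <- reportRow(fit$report)
          if (keepClassifiers)
            clfs[[paste(s, tk, m, sch, sep = "|")]] <- fit$classifier
        }
      }
    }
  }
  out <- list(reports = do.call(rbind, rows))
  if (keepClassifiers) out$classifiers <- clfs
  structure(out, class = c("earauth_grid", "list"))
}

#' Task-by-subject rate matrix (result-table shape)
#'
#' Reshapes a tidy grid report into a task x subject matrix of one metric
#' with a final `Mean` column, rounded half away from zero to 5 decimals.
#'
#' @param reports the `reports` data.frame of an `earauth_grid`.
#' @param metric `"FAR"` or `"FRR"`.
#' @return a data.frame, tasks as rows.
#' @export
tableByTask <- function(reports, metric = c("FAR", "FRR")) {
  metric <- match.arg(metric)
  subjects <- unique(reports$subject)
  tasks <- unique(reports$task)
  m <- sapply(subjects, function(s)
    vapply(tasks, function(tk) {
      v <- reports[reports$subject == s & reports$task == tk, metric]
      if (length(v) != 1L) NA_real_ else v
    }, numeric(1)))
  m <- matrix(m, nrow = length(tasks),
              dimnames = list(tasks, subjects))
  out <- as.data.frame(m)
  out$Mean <- vapply(seq_len(nrow(m)), function(i)
    aggregateMean(m[i, ]), numeric(1))
  out
}

#' Per-montage FAR/FRR summary (figure shape)
#'
#' Mean and standard error (sample SD / sqrt(n)) of FAR and FRR across all
#' (subject, task) reports, by montage.
#'
#' @param reports the `reports` data.frame of an `earauth_grid`.
#' @return a data.frame, one row per montage.
#' @export
summarizeByMontage <- function(reports) {
  do.call(rbind, lapply(split(reports, reports$montage), function(d) {
    n <- nrow(d)
    data.frame(montage = d$montage[1], n = n,
               FAR_mean = mean(d$FAR), FAR_se = stats::sd(d$FAR) / sqrt(n),
               FRR_mean = mean(d$FRR), FRR_se = stats::sd(d$FRR) / sqrt(n),
               stringsAsFactors = FALSE)
  }))
}

#' Best task per subject and the headline accuracy
#'
#' For each subject, selects the task minimizing FAR, breaking ties by
#' lower FRR and then by battery order; the headline accuracy is
#' `computeAccuracy` of the mean best-task FAR and mean best-task FRR.
#'
#' @param reports the `reports` data.frame of an `earauth_grid`, covering
#'   every (subject, task) pair for one montage and scheme.
#' @return a list with `best` (data.frame: subject, task, FAR, FRR) and
#'   `headline` (list: FAR_mean, FRR_mean, HTER, ACC).
#' @export
selectBestTasks <- function(reports) {
  subjects <- unique(reports$subject)
  tasks <- unique(reports$task)
  order_ <- taskBattery()$task
  best <- do.call(rbind, lapply(subjects, function(s) {
    d <- reports[reports$subject == s, ]
    if (!all(tasks %in% d$task) || nrow(d) != length(tasks))
      stop("incomplete grid: subject ", s, " lacks some tasks")
    d <- d[order(d$FAR, d$FRR, match(d$task, order_)), ]
    data.frame(subject = s, task = d$task[1], FAR = d$FAR[1],
               FRR = d$FRR[1], stringsAsFactors = FALSE)
  }))
  fam <- mean(best$FAR); frm <- mean(best$FRR)
  acc <- computeAccuracy(fam, frm)
  list(best = best,
       headline = list(FAR_mean = fam, FRR_mean = frm, HTER = acc$HTER,
                       ACC = acc$ACC))
}

#' Leave-one-out false acceptance rates
#'
#' Robustness of one target's authenticator to the enrolled population:
#' for each other subject, the classifier is retrained with that subject
#' excluded from the negative pool and the FAR recomputed.
#'
#' @param fm an [AuthFeatureSet-class].
#' @param subject,task the target pair.
#' @param scheme scheme name.
#' @param params an [authParams()] list.
#' @param seed integer seed.
#' @param negRatio maximum negatives per positive.
#' @return named numeric vector of length `n_subjects - 1` (FAR with each
#'   other subject left out).
#' @export
leaveOneOutFar <- function(fm, subject, task, scheme = "default",
                           params = authParams(), seed = 1L,
                           negRatio = 20) {
  subjects <- unique(SummarizedExperiment::colData(fm)$subjectId)
  if (length(subjects) < 3L) stop("need at least 3 subjects")
  if (!subject %in% subjects) stop("unknown target subject: ", subject)
  others <- setdiff(subjects, subject)
  vapply(others, function(ex) {
    fit <- trainAndEvaluate(fm, subject, task, scheme, params,
                            seed = deriveSeed(seed, stringSeed(ex)),
                            negRatio = negRatio, excludeSubjects = ex,
                            context = list(subject = subject, task = task,
                                           leftOut = ex))
    fit$report@FAR
  }, numeric(1))
}

#' Factor-contribution analysis
#'
#' Mean FAR and FRR across all (subject, task) pairs for each of the four
#' negative-example schemes, in scheme order (default, inherence_only,
#' knowledge_only, combined). Comparing rows isolates what the inherence
#' and knowledge factors contribute.
#'
#' @param corpus an [EEGCorpus-class].
#' @param montage montage name.
#' @param params an [authParams()] list.
#' @param seed integer seed.
#' @param negRatio maximum negatives per positive.
#' @param featureCache optional prebuilt features for `montage`.
#' @return a data.frame with columns `scheme`, `FAR`, `FRR` (raw means)
#'   and the full per-pair `reports` as an attribute.
#' @export
factorAnalysis <- function(corpus, montage = "left3",
                           params = authParams(), seed = 1L,
                           negRatio = 20, featureCache = NULL) {
  grid <- runFullGrid(corpus, montages = montage, schemes = schemeNames(),
                      params = params, seed = seed, negRatio = negRatio,
                      featureCache = featureCache)
  rep <- grid$reports
  out <- do.call(rbind, lapply(schemeNames(), function(sch) {
    d <- rep[rep$scheme == sch, ]
    data.frame(scheme = sch, FAR = mean(d$FAR), FRR = mean(d$FRR),
               stringsAsFactors = FALSE)
  }))
  attr(out, "reports") <- rep
  out
}
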