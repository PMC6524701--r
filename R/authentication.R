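#' Negative-example training schemes
#'
#' Positive examples are always windows of the correct participant
#' performing the correct task (P_c, T_c). The four schemes differ in the
#' negative pool and isolate the authentication factors:
#' \describe{
#'   \item{default}{other participants, any task (P_i, T_*): both factors.}
#'   \item{inherence_only}{other participants, the correct task
#'     (P_i, T_c): only who you are separates classes.}
#'   \item{knowledge_only}{the correct participant, other tasks
#'     (P_c, T_i): only what you think separates classes.}
#'   \item{combined}{union of (P_i, T_*) and (P_c, T_i).}
#' }
#'
#' @param name one of `"default"`, `"inherence_only"`, `"knowledge_only"`,
#'   `"combined"`.
#' @return a list of class `earauth_scheme`.
#' @export
trainingScheme <- function(name = c("default", "inherence_only",
                                    "knowledge_only", "combined")) {
  name <- match.arg(name)
  structure(list(name = name), class = c("earauth_scheme", "list"))
}

#' @rdname trainingScheme
#' @export
schemeNames <- function() {
  c("default", "inherence_only", "knowledge_only", "combined")
}

negativeMask <- function(scheme, cd, targetSubject, targetTask) {
  switch(scheme,
         default = cd$subjectId != targetSubject,
         inherence_only = cd$subjectId != targetSubject &
           cd$taskName == targetTask,
         knowledge_only = cd$subjectId == targetSubject &
           cd$taskName != targetTask,
         combined = cd$subjectId != targetSubject |
           (cd$subjectId == targetSubject & cd$taskName != targetTask),
         stop("unknown scheme: ", scheme))
}

#' Assemble a labeled train/test set for one target
#'
#' Positives are all windows of (`targetSubject`, `targetTask`); negatives
#' are drawn without replacement from the scheme's pool, up to `negRatio`
#' times the positive count (all available if fewer). One third of the data
#' is withheld for testing, stratified by class. By default whole trials
#' (all 20 windows of a 10 s trial) are kept on the same side of the split,
#' so within-trial autocorrelation cannot leak across it;
#' `splitBy = "window"` gives the permissive window-level split.
#'
#' @param fm an [AuthFeatureSet-class].
#' @param targetSubject,targetTask the authentication target.
#' @param scheme a scheme name or [trainingScheme()].
#' @param negRatio maximum negatives per positive (default 20).
#' @param seed integer seed for sampling and splitting.
#' @param splitBy `"trial"` (default) or `"window"`.
#' @param excludeSubjects subjects removed from the negative pool before
#'   sampling (used by the leave-one-out protocol).
#' @return a list of class `earauth_labeled_set` with elements `trainX`,
#'   `trainY`, `testX`, `testY` (windows x features matrices and 0/1
#'   labels), window-id vectors `trainIds`/`testIds`, and metadata.
#' @export
assembleTrainingSet <- function(fm, targetSubject, targetTask,
                                scheme = "default", negRatio = 20,
                                seed = 1L, splitBy = c("trial", "window"),
                                excludeSubjects = character()) {
  stopifnot(is(fm, "AuthFeatureSet"))
  splitBy <- match.arg(splitBy)
  scheme <- if (inherits(scheme, "earauth_scheme")) scheme$name else
    trainingScheme(scheme)$name
  cd <- as.data.frame(SummarizedExperiment::colData(fm))
  pos <- which(cd$subjectId == targetSubject & cd$taskName == targetTask)
  if (!length(pos))
    stop("no windows for target (", targetSubject, ", ", targetTask, ")")
  negPool <- which(negativeMask(scheme, cd, targetSubject, targetTask) &
                     !(cd$subjectId %in% excludeSubjects))
  if (!length(negPool))
    stop("scheme '", scheme, "' has no eligible negative examples ",
         "(needs other subjects/tasks that do not exist in the corpus)")
  set.seed(deriveSeed(seed, stringSeed(targetSubject),
                      stringSeed(targetTask), stringSeed(scheme)))
  nNegMax <- floor(negRatio * length(pos))

  trialKey <- paste(cd$subjectId, cd$taskName, cd$trialIndex, sep = "|")
  if (splitBy == "trial") {
    ## draw whole trials, round-robin across (subject, task) cells so the
    ## negative pool covers every eligible source evenly, truncating the
    ## last trial to honour the cap exactly
    negKeys <- unique(trialKey[negPool])
    shuffled <- sample(negKeys)
    byCell <- split(shuffled, sub("\\|[^|]*$", "", shuffled))
    depth <- max(lengths(byCell))
    negTrials <- character(0)
    for (i in seq_len(depth)) {
      cells <- sample(names(byCell))
      picks <- vapply(cells, function(cl)
        if (length(byCell[[cl]]) >= i) byCell[[cl]][i] else NA_character_,
        character(1))
      negTrials <- c(negTrials, picks[!is.na(picks)])
    }
    neg <- integer(0)
    for (tk in negTrials) {
      idx <- negPool[trialKey[negPool] == tk]
      take <- min(length(idx), nNegMax - length(neg))
      neg <- c(neg, idx[seq_len(take)])
      if (length(neg) >= nNegMax) break
    }
    splitThird <- function(idx) {
      keys <- unique(trialKey[idx])
      nTest <- max(1L, round(length(keys) / 3))
      testKeys <- sample(keys, nTest)
      list(test = idx[trialKey[idx] %in% testKeys],
           train = idx[!trialKey[idx] %in% testKeys])
    }
  } else {
    neg <- sample(negPool, min(nNegMax, length(negPool)))
    splitThird <- function(idx) {
      nTest <- max(1L, round(length(idx) / 3))
      test <- sample(idx, nTest)
      list(test = test, train = setdiff(idx, test))
    }
  }
  sp <- splitThird(pos); sn <- splitThird(neg)
  if (!length(sp$train) || !length(sn$train))
    stop("degenerate split: a class has no training data")
  X <- t(SummarizedExperiment::assay(fm, "power"))
  ids <- colnames(fm)
  trainIdx <- c(sp$train, sn$train)
  testIdx <- c(sp$test, sn$test)
  structure(list(
    trainX = X[trainIdx, , drop = FALSE],
    trainY = as.integer(trainIdx %in% pos),
    testX = X[testIdx, , drop = FALSE],
    testY = as.integer(testIdx %in% pos),
    trainIds = ids[trainIdx], testIds = ids[testIdx],
    scheme = scheme, target = c(subject = targetSubject, task = targetTask),
    negRatio = negRatio, splitBy = splitBy, seed = as.integer(seed)),
    class = c("earauth_labeled_set", "list"))
}

#' Training parameters for the boosted authenticator
#'
#' @param nrounds boosting rounds for the final fit (used directly when
#'   `cvRounds = 0`).
#' @param maxDepth maximum tree depth (shallow trees).
#' @param eta learning rate.
#' @param cvRounds number of repeated shuffled model-selection splits of
#'   the training portion; each scores the binary error rate and the round
#'   count minimizing the mean error over `candidateNrounds` is kept.
#'   `0` skips selection and uses `nrounds` as given.
#' @param candidateNrounds candidate boosting-round counts for selection.
#' @param colsampleBytree fraction of features sampled per tree; values
#'   below 1 force the ensemble to spread its decision over many frequency
#'   bins instead of a few dominant ones, which hardens the boundary
#'   against imposters who happen to match those few bins.
#' @param threshold decision threshold; scores strictly greater are
#'   accepted.
#' @return a parameter list.
#' @export
authParams <- function(nrounds = 300L, maxDepth = 3L, eta = 0.1,
                       cvRounds = 100L,
                       candidateNrounds = c(100L, 200L, 300L),
                       colsampleBytree = 0.05, threshold = 0.5) {
  list(nrounds = as.integer(nrounds), maxDepth = as.integer(maxDepth),
       eta = eta, cvRounds = as.integer(cvRounds),
       candidateNrounds = sort(as.integer(candidateNrounds)),
       colsampleBytree = colsampleBytree, threshold = threshold)
}

xgbFit <- function(X, y, params, nrounds, seed) {
  dm <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = params$maxDepth,
                  eta = params$eta, nthread = 1, seed = seed,
                  colsample_bytree = params$colsampleBytree %||% 1,
                  eval_metric = "error"),
    data = dm, nrounds = nrounds, verbose = 0)
}

## Repeated shuffled splits of the training portion: pick the candidate
## round count with the lowest mean binary error. Never sees the holdout.
selectNrounds <- function(ls, params, seed) {
  cands <- params$candidateNrounds
  maxR <- max(cands)
  n <- nrow(ls$trainX)
  errs <- matrix(NA_real_, params$cvRounds, length(cands))
  for (r in seq_len(params$cvRounds)) {
    set.seed(deriveSeed(seed, 313L, r))
    val <- sample(n, max(1L, round(n / 3)))
    if (length(unique(ls$trainY[-val])) < 2L) next
    dtr <- xgboost::xgb.DMatrix(ls$trainX[-val, , drop = FALSE],
                                label = ls$trainY[-val], nthread = 1)
    dva <- xgboost::xgb.DMatrix(ls$trainX[val, , drop = FALSE],
                                label = ls$trainY[val], nthread = 1)
    bst <- xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = params$maxDepth, eta = params$eta,
                    nthread = 1, seed = seed,
                    colsample_bytree = params$colsampleBytree %||% 1,
                    eval_metric = "error"),
      data = dtr, nrounds = maxR, evals = list(val = dva), verbose = 0)
    log <- attributes(bst)$evaluation_log
    errs[r, ] <- log$val_error[cands]
  }
  mean_err <- colMeans(errs, na.rm = TRUE)
  cands[which.min(mean_err)]
}

#' Train one per-(subject, task) authenticator
#'
#' Fits a gradient-boosted ensemble of shallow trees with logistic loss on
#' the training portion of a labeled set. When `params$cvRounds > 0`, the
#' boosting-round count is first chosen by repeated shuffled splits of the
#' training portion scored with the binary error rate; the withheld test
#' third is never touched during training. Deterministic per seed.
#'
#' @param ls an `earauth_labeled_set` from [assembleTrainingSet()].
#' @param params an [authParams()] list.
#' @param seed integer seed.
#' @return an [AuthClassifier-class].
#' @export
trainAuthenticator <- function(ls, params = authParams(), seed = 1L) {
  stopifnot(inherits(ls, "earauth_labeled_set"))
  if (length(unique(ls$trainY)) < 2L)
    stop("training set must contain both classes")
  nrounds <- if (params$cvRounds > 0L) selectNrounds(ls, params, seed) else
    params$nrounds
  bst <- xgbFit(ls$trainX, ls$trainY, params, nrounds, seed)
  new("AuthClassifier",
      booster = xgboost::xgb.save.raw(bst),
      featureNames = colnames(ls$trainX),
      threshold = params$threshold,
      subjectId = unname(ls$target["subject"]),
      taskName = unname(ls$target["task"]),
      scheme = ls$scheme, params = params,
      nrounds = as.integer(nrounds), seed = as.integer(seed))
}

#' @describeIn AuthClassifier-class score feature windows and decide.
#'   Accepts a windows x features matrix or an [AuthFeatureSet-class];
#'   returns a list with `scores` in [0, 1] and logical `decisions`
#'   (`score > threshold`, strict, so a score of exactly 0.5 is rejected).
#' @param object an [AuthClassifier-class].
#' @param newdata matrix (windows x features) or [AuthFeatureSet-class].
#' @export
setMethod("predict", "AuthClassifier", function(object, newdata) {
  X <- if (is(newdata, "AuthFeatureSet"))
    t(SummarizedExperiment::assay(newdata, "power")) else newdata
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  if (ncol(X) != length(object@featureNames))
    stop("feature dimension mismatch: classifier expects ",
         length(object@featureNames), " features, got ", ncol(X))
  if (nrow(X) == 0L)
    return(list(scores = numeric(0), decisions = logical(0)))
  bst <- xgboost::xgb.load.raw(object@booster)
  scores <- predict(bst, xgboost::xgb.DMatrix(X, nthread = 1))
  list(scores = scores, decisions = scores > object@threshold)
})
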