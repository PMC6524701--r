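parseIds <- function(ids) {
  parts <- strsplit(ids, "|", fixed = TRUE)
  data.frame(subject = vapply(parts, `[`, "", 1),
             task = vapply(parts, `[`, "", 2),
             trial = vapply(parts, `[`, "", 3))
}

test_that("each scheme draws negatives from its own pool only", {
  fm <- smallFeatures()
  cases <- list(
    default = function(d) all(d$subject != "P1"),
    inherence_only = function(d) all(d$subject != "P1" & d$task == "breathe"),
    knowledge_only = function(d) all(d$subject == "P1" & d$task != "breathe"),
    combined = function(d) all(d$subject != "P1" |
                                 (d$subject == "P1" & d$task != "breathe")))
  for (sch in names(cases)) {
    ls <- assembleTrainingSet(fm, "P1", "breathe", scheme = sch, seed = 5)
    ids <- parseIds(c(ls$trainIds, ls$testIds))
    negIds <- ids[c(ls$trainY, ls$testY) == 0L, ]
    posIds <- ids[c(ls$trainY, ls$testY) == 1L, ]
    expect_true(cases[[sch]](negIds), label = paste("negatives for", sch))
    expect_true(all(posIds$subject == "P1" & posIds$task == "breathe"),
                label = paste("positives for", sch))
  }
})

test_that("schemes needing other subjects or tasks fail on degenerate corpora", {
  solo <- synthesizeCorpus(list(makeSubjectProfile(1, subjectId = "only")),
                           smallProtocol(), seed = 9)
  fmSolo <- buildFeatures(solo, "left3")
  expect_error(assembleTrainingSet(fmSolo, "only", "breathe",
                                   scheme = "inherence_only"),
               "no eligible negative")
  expect_error(assembleTrainingSet(fmSolo, "only", "breathe",
                                   scheme = "default"),
               "no eligible negative")
  ## knowledge_only still works: negatives are the same subject's other tasks
  expect_s3_class(assembleTrainingSet(fmSolo, "only", "breathe",
                                      scheme = "knowledge_only"),
                  "earauth_labeled_set")
})

test_that("train and test share no window and no trial", {
  fm <- smallFeatures()
  for (seed in 1:5) {
    ls <- assembleTrainingSet(fm, "P2", "song", seed = seed)
    expect_length(intersect(ls$trainIds, ls$testIds), 0L)
    trialOf <- function(ids) {
      d <- parseIds(ids)
      unique(paste(d$subject, d$task, d$trial))
    }
    expect_length(intersect(trialOf(ls$trainIds), trialOf(ls$testIds)), 0L)
    ## negative count bookkeeping
    nPos <- sum(c(ls$trainY, ls$testY) == 1L)
    nNeg <- sum(c(ls$trainY, ls$testY) == 0L)
    expect_lte(nNeg, 20 * nPos)
    ## one third of positive trials withheld
    posTest <- parseIds(ls$testIds[ls$testY == 1L])
    expect_equal(length(unique(posTest$trial)), 1L)  # round(3/3)
  }
  ## window-level split also keeps sets disjoint
  lsw <- assembleTrainingSet(fm, "P2", "song", seed = 1,
                             splitBy = "window")
  expect_length(intersect(lsw$trainIds, lsw$testIds), 0L)
  expect_equal(length(lsw$testIds),
               round(length(c(lsw$trainIds, lsw$testIds)) / 3),
               tolerance = 0.1)
})

toySet <- function(n = 60, sep = 10, seed = 1, permute = FALSE) {
  set.seed(seed)
  half <- n / 2
  X <- rbind(matrix(rnorm(half * 4), half, 4),
             matrix(rnorm(half * 4, mean = sep), half, 4))
  colnames(X) <- paste0("f", 1:4)
  y <- rep(c(0L, 1L), each = half)
  if (permute) y <- sample(y)
  idx <- sample(n)
  test <- idx[1:(n / 3)]
  train <- setdiff(seq_len(n), test)
  structure(list(trainX = X[train, ], trainY = y[train],
                 testX = X[test, ], testY = y[test],
                 trainIds = paste0("w", train), testIds = paste0("w", test),
                 scheme = "default",
                 target = c(subject = "toy", task = "toy"),
                 negRatio = 1, splitBy = "window", seed = seed),
            class = c("earauth_labeled_set", "list"))
}

test_that("a separable toy problem reaches zero holdout error", {
  ls <- toySet()
  clf <- trainAuthenticator(ls, fastParams(), seed = 2)
  rep <- evaluateClassifier(clf, ls = ls)
  expect_equal(rep@epsilon, 0)
  expect_equal(rep@FAR, 0)
  expect_equal(rep@FRR, 0)
})

test_that("permuted labels give holdout error near the base rate", {
  errs <- vapply(1:5, function(s) {
    ls <- toySet(n = 90, seed = s, permute = TRUE)
    clf <- trainAuthenticator(ls, fastParams(), seed = s)
    evaluateClassifier(clf, ls = ls)@epsilon
  }, numeric(1))
  base <- 0.5
  n <- 30
  ## binomial noise around the base rate (3 sigma on the mean of 5 runs)
  expect_lt(abs(mean(errs) - base), 3 * sqrt(base * (1 - base) / (5 * n)) + 0.1)
})

test_that("training is deterministic per seed", {
  ls <- toySet(n = 60, sep = 1.5)
  c1 <- trainAuthenticator(ls, fastParams(), seed = 7)
  c2 <- trainAuthenticator(ls, fastParams(), seed = 7)
  expect_identical(predict(c1, ls$testX)$scores,
                   predict(c2, ls$testX)$scores)
  ls2 <- toySet(n = 60, sep = 1.5)
  expect_identical(ls$trainX, ls2$trainX)
})

test_that("model selection picks a candidate round count without touching the holdout", {
  ls <- toySet(n = 90, sep = 2)
  pars <- authParams(cvRounds = 5L, candidateNrounds = c(5L, 20L))
  clf <- trainAuthenticator(ls, pars, seed = 3)
  expect_true(clf@nrounds %in% c(5L, 20L))
})

test_that("single-class training sets are rejected", {
  ls <- toySet()
  ls$trainY <- rep(0L, length(ls$trainY))
  expect_error(trainAuthenticator(ls, fastParams()), "both classes")
})

test_that("decisions follow the strict score threshold", {
  ls <- toySet(sep = 1)
  clf <- trainAuthenticator(ls, fastParams(), seed = 2)
  pred <- predict(clf, ls$testX)
  expect_type(pred$scores, "double")
  expect_true(all(pred$scores >= 0 & pred$scores <= 1))
  ## decisions recomputed from the returned scores match exactly
  expect_identical(pred$decisions, pred$scores > 0.5)
  ## scores exactly at the threshold are rejections by the strict rule
  expect_identical(c(0.49, 0.5, 0.51) > clf@threshold,
                   c(FALSE, FALSE, TRUE))
  empty <- predict(clf, ls$testX[0, , drop = FALSE])
  expect_length(empty$scores, 0L)
  expect_length(empty$decisions, 0L)
  expect_error(predict(clf, ls$testX[, 1:2]), "dimension mismatch")
})
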