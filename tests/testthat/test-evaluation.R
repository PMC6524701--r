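test_that("attempt counts map to rates exactly", {
  r <- computeRates(FA = 200, FAS = 0, TA = 80, TAU = 0)
  expect_equal(r@FAR, 0); expect_equal(r@FRR, 0); expect_equal(r@ACC, 100)
  expect_equal(computeRates(FA = 200, FAS = 2, TA = 80, TAU = 0)@FAR, 0.01)
  worst <- computeRates(FA = 100, FAS = 100, TA = 100, TAU = 100)
  expect_equal(worst@FAR, 1); expect_equal(worst@FRR, 1)
  expect_equal(worst@ACC, 0)
  expect_error(computeRates(0, 0, 10, 0), "positive")
  expect_error(computeRates(10, 11, 10, 0), "counts")
})

test_that("HTER and accuracy follow their defining identities", {
  acc <- computeAccuracy(0, 0.0036)
  expect_equal(acc$HTER, 0.0018)
  expect_equal(acc$ACC, 99.82)
  expect_equal(computeAccuracy(0, 0)$ACC, 100)
  expect_equal(computeAccuracy(0.5, 0.5)$ACC, 50)
  expect_error(computeAccuracy(-0.1, 0), "\\[0, 1\\]")
  expect_error(computeAccuracy(0, 1.1), "\\[0, 1\\]")
})

test_that("report identities hold over random count tuples", {
  set.seed(99)
  for (i in 1:1000) {
    FA <- sample(1:500, 1); FAS <- sample(0:FA, 1)
    TA <- sample(1:500, 1); TAU <- sample(0:TA, 1)
    r <- computeRates(FA, FAS, TA, TAU)
    expect_equal(r@FAR * r@FA, FAS)
    expect_equal(r@FRR * r@TA, TAU)
    expect_equal(r@HTER, (r@FAR + r@FRR) / 2)
    expect_equal(r@ACC, 100 * (1 - r@HTER))
    expect_equal(r@epsilon, (FAS + TAU) / (FA + TA))
    expect_true(r@FAR >= 0 && r@FAR <= 1 && r@FRR >= 0 && r@FRR <= 1)
  }
})

## Stub scorers for evaluation tests: any object with a predict method that
## returns scores and decisions can be evaluated.
setClass("ConstantScorer", representation(score = "numeric"))
setMethod("predict", "ConstantScorer", function(object, newdata) {
  s <- rep(object@score, nrow(newdata))
  list(scores = s, decisions = s > 0.5)
})
setClass("HashScorer", representation(seed = "numeric"))
setMethod("predict", "HashScorer", function(object, newdata) {
  ## deterministic pseudo-scores from the row sums
  s <- (sin(rowSums(newdata) + object@seed) + 1) / 2
  list(scores = s, decisions = s > 0.5)
})

test_that("stub classifiers give the degenerate rate patterns", {
  X <- matrix(rnorm(60), 30, 2)
  y <- rep(c(0L, 1L), 15)
  rejAll <- evaluateClassifier(new("ConstantScorer", score = 0), X, y)
  expect_equal(rejAll@FAR, 0); expect_equal(rejAll@FRR, 1)
  accAll <- evaluateClassifier(new("ConstantScorer", score = 1), X, y)
  expect_equal(accAll@FAR, 1); expect_equal(accAll@FRR, 0)
  ## a score of exactly 0.5 is a rejection
  border <- evaluateClassifier(new("ConstantScorer", score = 0.5), X, y)
  expect_equal(border@FRR, 1)
  expect_error(evaluateClassifier(new("ConstantScorer", score = 0), X,
                                  rep(1L, 30)), "both classes")
})

test_that("evaluation counts equal a brute-force per-instance loop", {
  set.seed(5)
  for (i in 1:10) {
    n <- sample(20:60, 1)
    X <- matrix(rnorm(n * 3), n, 3)
    y <- sample(c(0L, 1L), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
    clf <- new("HashScorer", seed = i)
    r <- evaluateClassifier(clf, X, y)
    ## oracle: instance-by-instance accounting
    FA <- 0; FAS <- 0; TA <- 0; TAU <- 0
    for (j in seq_len(n)) {
      d <- predict(clf, X[j, , drop = FALSE])$decisions
      if (y[j] == 0L) { FA <- FA + 1; if (d) FAS <- FAS + 1 }
      else { TA <- TA + 1; if (!d) TAU <- TAU + 1 }
    }
    expect_equal(c(r@FA, r@FAS, r@TA, r@TAU), c(FA, FAS, TA, TAU))
  }
})

test_that("mean rates are report-rounded half away from zero to 5 decimals", {
  expect_equal(aggregateMean(c(0, 0, 0, 0, 0.0002, 0.0004, 0)), 0.00009)
  expect_equal(aggregateMean(c(0, 0.0125, 0, 0.0125, 0.0125, 0.0250, 0)),
               0.00893)
  expect_equal(aggregateMean(c(0.0250, 0.0250, 0, 0.0125, 0.0375, 0.0125,
                               0.0125)), 0.01786)
  expect_equal(aggregateMean(c(0.0250, 0.0250, 0.0500, 0.0125, 0, 0, 0)),
               0.01607)
  expect_equal(aggregateMean(rep(0, 7)), 0)
  expect_equal(aggregateMean(c(0.1, 0.2), digits = NULL), 0.15)
  expect_error(aggregateMean(numeric(0)), "empty")
  expect_error(aggregateMean(c(0.5, 2)), "\\[0, 1\\]")
})

fakeReports <- function(far, frr, subjects = "P1",
                        tasks = taskBattery()$task) {
  expand <- expand.grid(task = tasks, subject = subjects,
                        stringsAsFactors = FALSE)
  expand$FAR <- far; expand$FRR <- frr
  expand$montage <- "left3"; expand$scheme <- "default"
  expand
}

test_that("best-task selection minimizes FAR with FRR and battery-order tie-breaks", {
  rep1 <- fakeReports(far = c(0.2, 0.1, 0, 0, 0.3, 0.1, 0.5, 0.2, 0.1),
                      frr = c(0, 0, 0.2, 0.1, 0, 0, 0, 0, 0))
  best <- selectBestTasks(rep1)
  ## two tasks tie at FAR 0; the lower FRR wins
  expect_equal(best$best$task, "song")
  ## full tie resolves by battery order
  rep2 <- fakeReports(far = rep(0, 9), frr = rep(0, 9))
  expect_equal(selectBestTasks(rep2)$best$task, "breathe")
  ## single subject, single task
  rep3 <- fakeReports(far = 0.1, frr = 0.2, tasks = "song")
  expect_equal(selectBestTasks(rep3)$best$task, "song")
  ## incomplete grids are rejected
  rep4 <- fakeReports(far = rep(0, 9), frr = rep(0, 9),
                      subjects = c("P1", "P2"))
  expect_error(selectBestTasks(rep4[-1, ]), "incomplete")
})

test_that("the headline accuracy comes from the mean best-task rates", {
  reps <- do.call(rbind, lapply(sprintf("P%d", 1:7), function(s) {
    r <- fakeReports(far = rep(0.5, 9), frr = rep(0.5, 9), subjects = s)
    r$FAR[3] <- 0
    r$FRR[3] <- 0.0036
    r
  }))
  out <- selectBestTasks(reps)
  expect_equal(out$headline$FAR_mean, 0)
  expect_equal(out$headline$FRR_mean, 0.0036)
  expect_equal(out$headline$ACC, 99.82)
})

test_that("the grid produces one report per subject-task-montage-scheme cell", {
  corpus <- smallCorpus(2)
  grid <- runFullGrid(corpus, montages = c("left3", "right3"),
                      schemes = "default", params = fastParams(), seed = 4)
  expect_equal(nrow(grid$reports), 2L * 9L * 2L)
  byM <- table(grid$reports$montage)
  expect_equal(unname(byM["left3"]), unname(byM["right3"]))
  expect_true(all(grid$reports$FAR >= 0 & grid$reports$FAR <= 1))
  ## identities hold on every emitted report
  with(grid$reports, {
    expect_equal(FAR * FA, FAS)
    expect_equal(FRR * TA, TAU)
    expect_equal(ACC, 100 * (1 - (FAR + FRR) / 2))
  })
  ## determinism under a fixed master seed
  grid2 <- runFullGrid(corpus, montages = c("left3", "right3"),
                       schemes = "default", params = fastParams(), seed = 4)
  expect_identical(grid$reports, grid2$reports)
  tab <- tableByTask(grid$reports[grid$reports$montage == "left3", ], "FRR")
  expect_equal(dim(tab), c(9L, 3L))  # 2 subjects + Mean
  sm <- summarizeByMontage(grid$reports)
  expect_equal(nrow(sm), 2L)
  expect_true(all(sm$FAR_se >= 0))
})

test_that("leave-one-out retrains once per excluded subject", {
  fm <- smallFeatures()
  loo <- leaveOneOutFar(fm, "P1", "breathe", params = fastParams(),
                        seed = 11)
  expect_length(loo, 2L)  # 3 subjects -> 2 exclusions
  expect_named(loo, c("P2", "P3"))
  expect_true(all(loo >= 0 & loo <= 1))
  expect_error(leaveOneOutFar(fm, "P9", "breathe", params = fastParams()),
               "unknown target")
  two <- buildFeatures(smallCorpus(2), "left3")
  expect_error(leaveOneOutFar(two, "P1", "breathe",
                              params = fastParams()), "at least 3")
})

test_that("factor analysis reports the four schemes in canonical order", {
  corpus <- smallCorpus(2)
  fa <- factorAnalysis(corpus, params = fastParams(), seed = 8)
  expect_equal(fa$scheme, c("default", "inherence_only", "knowledge_only",
                            "combined"))
  expect_equal(nrow(fa), 4L)
  expect_true(all(fa$FAR >= 0 & fa$FAR <= 1))
  reps <- attr(fa, "reports")
  expect_equal(nrow(reps), 4L * 2L * 9L)
})
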