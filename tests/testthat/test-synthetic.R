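test_that("profiles are deterministic per seed and differ across seeds", {
  p1a <- makeSubjectProfile(1)
  p1b <- makeSubjectProfile(1)
  expect_identical(p1a@fingerprintGains, p1b@fingerprintGains)
  expect_identical(p1a@taskSecrets, p1b@taskSecrets)
  p2 <- makeSubjectProfile(2)
  expect_false(isTRUE(all.equal(p1a@fingerprintGains, p2@fingerprintGains)))
  expect_error(makeSubjectProfile(-1), "non-negative")
  expect_error(generatorConfig(noiseSd = -1), "positive")
})

test_that("the default battery matches the nine tasks and their attributes", {
  b <- taskBattery()
  expect_equal(nrow(b), 9L)
  expect_equal(b$task[1], "breathe")
  expect_setequal(b$task[b$has_secret],
                  c("sport", "song", "song_open", "speech", "face",
                    "sequence"))
  expect_setequal(b$task[b$has_stimulus], c("listen", "sequence"))
  expect_setequal(b$task[b$eyes_open],
                  c("breathe_open", "song_open", "sequence"))
  expect_equal(b$imagery[b$task == "sport"], "motor")
  expect_equal(b$imagery[b$task == "face"], "visual")
  ## tasks without a secret carry no secret parameters
  p <- makeSubjectProfile(3)
  expect_null(p@taskSecrets[["breathe"]])
  expect_null(p@taskSecrets[["listen"]])
  expect_named(p@taskSecrets[["song"]], c("freqs", "amps", "weights"))
})

test_that("trial synthesis is deterministic, sized and labelled correctly", {
  p <- makeSubjectProfile(1)
  r1 <- synthesizeTrial(p, "breathe", protocolConfig(), seed = 5)
  r2 <- synthesizeTrial(p, "breathe", protocolConfig(), seed = 5)
  expect_identical(r1@data, r2@data)
  expect_equal(dim(r1@data), c(8L, 2000L))  # 10 s at 200 Hz
  expect_equal(r1@channelLabels[1:3], c("L_concha", "L_front", "L_back"))
  r3 <- synthesizeTrial(p, "breathe", protocolConfig(trialDurationS = 2.5),
                        seed = 5)
  expect_equal(ncol(r3@data), 500L)
  expect_true(all(is.finite(r1@data)))
  expect_error(synthesizeTrial(p, "daydream"), "unknown task")
  expect_error(protocolConfig(trialDurationS = 0), "positive")
})

test_that("eyes-closed alpha power exceeds eyes-open on ear channels", {
  p <- makeSubjectProfile(7)
  prot <- protocolConfig(nTrials = 1L, trialDurationS = 5)
  ratios <- sapply(1:20, function(s) {
    closed <- synthesizeTrial(p, "breathe", prot, seed = 100 + s)
    open <- synthesizeTrial(p, "breathe_open", prot, seed = 200 + s)
    mean(vapply(earLabels(), function(ch)
      bandPower(closed, ch, 8, 12), numeric(1))) /
      mean(vapply(earLabels(), function(ch)
        bandPower(open, ch, 8, 12), numeric(1)))
  })
  expect_gt(mean(ratios), 1)
  expect_gt(min(ratios), 1)
})

test_that("the listen task carries a 40 Hz steady-state component", {
  p <- makeSubjectProfile(4)
  r <- synthesizeTrial(p, "listen", protocolConfig(), seed = 9)
  wins <- sliceWindows(r, 100L)
  sp <- rowMeans(vapply(wins, function(w) powerSpectrum(w[1, ], 200),
                        numeric(51)))
  f <- as.numeric(names(powerSpectrum(wins[[1]][1, ], 200)))
  p40 <- sp[f == 40]
  neigh <- sp[f >= 35 & f <= 45 & f != 40]
  expect_gt(p40, mean(neigh))
})

test_that("with EMG disabled nearly all non-DC power lies below 32 Hz", {
  p <- makeSubjectProfile(11)
  for (task in c("breathe", "song")) {
    r <- synthesizeTrial(p, task, protocolConfig(), seed = 31)
    for (ch in c(1L, 3L)) {
      sp <- powerSpectrum(r@data[ch, ], 200)
      f <- as.numeric(names(sp))
      expect_gt(sum(sp[f > 0 & f < 32]) / sum(sp[f > 0]), 0.95)
    }
  }
  ## enabling EMG moves power above 32 Hz
  emgCfg <- generatorConfig(emg = list(enabled = TRUE))
  pe <- makeSubjectProfile(11, emgCfg)
  re <- synthesizeTrial(pe, "breathe", protocolConfig(), seed = 31,
                        config = emgCfg)
  spe <- powerSpectrum(re@data[1, ], 200)
  f <- as.numeric(names(spe))
  expect_lt(sum(spe[f > 0 & f < 32]) / sum(spe[f > 0]), 0.95)
})

test_that("corpus synthesis follows the protocol arithmetic and is reproducible", {
  p <- lapply(1:2, function(i) makeSubjectProfile(i, subjectId = paste0("S", i)))
  prot <- protocolConfig(nTrials = 2L, trialDurationS = 1)
  c1 <- synthesizeCorpus(p, prot, seed = 3)
  expect_equal(length(c1), 2L * 9L * 2L)
  c2 <- synthesizeCorpus(p, prot, seed = 3)
  expect_identical(recordings(c1)[[5]]@data, recordings(c2)[[5]]@data)
  one <- synthesizeCorpus(p[1], protocolConfig(nTrials = 1L,
                                               trialDurationS = 1), seed = 3)
  expect_equal(length(one), 9L)
  ## trial indices 0..n-1 per (subject, task); 100 s per pair at defaults
  ti <- vapply(recordings(c1), trialIndex, integer(1))
  expect_setequal(unique(ti), 0:1)
  expect_error(synthesizeCorpus(list(p[[1]], p[[1]]), prot, seed = 1),
               "duplicate")
})

test_that("total data per (subject, task) is trials x duration seconds", {
  corpus <- smallCorpus()
  recs <- Filter(function(r) subjectId(r) == "P1" && taskName(r) == "song",
                 recordings(corpus))
  expect_equal(length(recs), smallProtocol()$nTrials)
  secs <- sum(vapply(recs, function(r) ncol(r@data) / samplingRate(r),
                     numeric(1)))
  expect_equal(secs, smallProtocol()$nTrials * smallProtocol()$trialDurationS)
})

test_that("a wider subject gain spread increases between-subject spectral divergence", {
  ## distance on log band powers of the mean trial spectrum (the fixed
  ## distance of choice: band powers scale directly with the gains)
  bandPow <- function(cfg, seed) {
    p <- makeSubjectProfile(seed, cfg)
    r <- synthesizeTrial(p, "breathe", protocolConfig(trialDurationS = 5),
                         seed = 50, config = cfg)
    wins <- sliceWindows(r, 100L)
    sp <- rowMeans(vapply(wins, function(w) powerSpectrum(w[1, ], 200),
                          numeric(51)))
    f <- as.numeric(names(powerSpectrum(wins[[1]][1, ], 200)))
    log(vapply(earauth:::eegBands(), function(b)
      sum(sp[f >= b[1] & f <= b[2]]), numeric(1)))
  }
  div <- vapply(c(0.3, 0.8, 1.6), function(spread) {
    cfg <- generatorConfig(gainSpreadLog = spread)
    bp <- lapply(1:4, function(s) bandPow(cfg, s))
    d <- 0
    for (i in 1:3) for (j in (i + 1):4)
      d <- d + sqrt(sum((bp[[i]] - bp[[j]])^2))
    d
  }, numeric(1))
  expect_true(all(diff(div) > 0))
})

test_that("imposter profiles copy secrets by knowledge level but never identity", {
  target <- makeSubjectProfile(1)
  full <- makeImposterProfile(target, knowledgeLevel = 1, seed = 99)
  expect_equal(full@taskSecrets, target@taskSecrets)
  expect_false(isTRUE(all.equal(full@fingerprintGains,
                                target@fingerprintGains)))
  none <- makeImposterProfile(target, knowledgeLevel = 0, seed = 99)
  own <- makeSubjectProfile(99, subjectId = none@subjectId)
  expect_equal(none@taskSecrets, own@taskSecrets)
  expect_false(isTRUE(all.equal(none@taskSecrets[["song"]]$freqs,
                                target@taskSecrets[["song"]]$freqs)))
  half <- makeImposterProfile(target, knowledgeLevel = 0.5, seed = 99)
  expect_equal(half@taskSecrets[["song"]]$amps,
               0.5 * own@taskSecrets[["song"]]$amps +
                 0.5 * target@taskSecrets[["song"]]$amps)
  expect_error(makeImposterProfile(target, knowledgeLevel = 1.2, seed = 1),
               "\\[0, 1\\]")
})
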