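test_that("event outcomes match the hand-counted example", {
  grid <- testWindows()$t
  mk <- function(id, detTimes) {
    data.frame(trial = id, t = grid,
               score = ifelse(grid %in% detTimes, 1, -1))
  }
  ## A detects only at -0.5 (intention); B only at -1.5 (rest);
  ## C never
  traces <- rbind(mk(1, -0.5), mk(2, -1.5), mk(3, numeric(0)))
  oc <- eventOutcomes(traces, threshold = 0)
  expect_equal(oc[c("TPE", "FPE", "TNE", "FNE")],
               list(TPE = 1, FPE = 1, TNE = 2, FNE = 2))
  expect_equal(oc$sensitivity, 1 / 3)
  expect_equal(oc$specificity, 2 / 3)

  ## detections everywhere / nowhere
  all3 <- rbind(mk(1, grid), mk(2, grid), mk(3, grid))
  ocAll <- eventOutcomes(all3, 0)
  expect_equal(c(ocAll$sensitivity, ocAll$specificity), c(1, 0))
  none <- rbind(mk(1, numeric(0)), mk(2, numeric(0)))
  ocNone <- eventOutcomes(none, 0)
  expect_equal(c(ocNone$sensitivity, ocNone$specificity), c(0, 1))

  ## the boundary window t = -1 belongs to the rest event
  bnd <- mk(1, -1)
  ocB <- eventOutcomes(bnd, 0)
  expect_equal(ocB$FPE, 1)
  expect_equal(ocB$TPE, 0)
})

test_that("event outcomes agree with a brute-force oracle on random traces", {
  for (seed in 1:20) {
    traces <- randomTraces(50, seed = seed)
    for (thr in quantile(traces$score, c(0.1, 0.5, 0.9))) {
      oc <- eventOutcomes(traces, thr)
      bf <- bruteEventOutcomes(traces, thr)
      expect_identical(oc[c("TPE", "FPE", "TNE", "FNE")], bf)
      ## event-count conservation
      expect_equal(oc$TPE + oc$FNE, 50)
      expect_equal(oc$FPE + oc$TNE, 50)
    }
  }
})

test_that("the event ROC is monotone with correct endpoints and AUC", {
  traces <- randomTraces(30, seed = 7)
  rc <- rocEvent(traces)
  expect_equal(rc$roc$sensitivity[1], 0)
  expect_equal(rc$roc$specificity[1], 1)
  n <- nrow(rc$roc)
  expect_equal(rc$roc$sensitivity[n], 1)
  expect_equal(rc$roc$specificity[n], 0)
  expect_true(all(diff(rc$roc$sensitivity) >= 0))
  expect_true(all(diff(rc$roc$specificity) <= 0))
  expect_gte(rc$auc, 0)
  expect_lte(rc$auc, 1)

  ## scores that perfectly separate intention from rest windows
  grid <- testWindows()$t
  sep <- do.call(rbind, lapply(1:10, function(k)
    data.frame(trial = k, t = grid, score = ifelse(grid > -1, 1, -1))))
  expect_equal(rocEvent(sep)$auc, 1)

  const <- data.frame(trial = rep(1:5, each = 17), t = rep(grid, 5),
                      score = 0)
  expect_warning(rcC <- rocEvent(const), "degenerate")
  expect_equal(rcC$auc, 0.5)
})

test_that("correct trials and anticipation follow their definitions", {
  grid <- testWindows()$t
  mk <- function(id, detTimes) data.frame(trial = id, t = grid,
    score = ifelse(grid %in% detTimes, 1, -1))
  ## clean rest, first intention detection at -0.375
  tr <- rbind(mk(1, c(-0.375, -0.125)), mk(2, c(-1.5, -0.25)),
              mk(3, numeric(0)))
  ct <- correctTrials(tr, 0)
  expect_equal(unname(ct$correct), c(TRUE, FALSE, FALSE))
  expect_equal(ct$anticipation, -0.375)
  expect_equal(ct$percentCorrect, 100 / 3)

  ctNone <- correctTrials(mk(1, numeric(0)), 0)
  expect_equal(ctNone$percentCorrect, 0)
  expect_length(ctNone$anticipation, 0)
})

test_that("decodeTrial scores all 17 windows and thresholds correctly", {
  ts <- fixture("small12")
  p <- 1056
  stats <- new("NormalizationStats", mean = rep(0, p), sd = rep(1, p),
               zeroVar = rep(FALSE, p))
  set.seed(20)
  beta <- rnorm(p)
  model <- new("SdaModel", beta = beta, intercept = 0, budget = p,
               gamma = 0, selected = which(beta != 0))
  osfE <- fitOSF(ts, "ERD")
  osfM <- fitOSF(ts, "MRCP")
  tr <- decodeTrial(model, ts, 1, osfE, osfM, stats, threshold = Inf)
  expect_equal(nrow(tr), 17)
  expect_false(any(tr$detected))
  tr2 <- decodeTrial(model, ts, 1, osfE, osfM, stats, threshold = -Inf)
  expect_true(all(tr2$detected))
  ## a monotone score trace crossing the threshold once detects a suffix
  mono <- data.frame(t = testWindows()$t,
                     score = seq(-1, 1, length.out = 17))
  det <- mono$t[mono$score >= 0.2]
  expect_identical(det, tail(mono$t, length(det)))
})

test_that("leave-one-out honors the fold contract deterministically", {
  ev <- suppressWarnings(looEvaluate(fixture("small12")))
  expect_equal(ev@nTrials, 12L)
  ## every trial scored exactly once on the full grid
  expect_equal(nrow(ev@traces), 12 * 17)
  expect_equal(as.vector(table(ev@traces$trial)), rep(17, 12))
  ## conservation at the working point
  oc <- ev@outcomes
  expect_equal(oc$TPE + oc$FNE, 12)
  expect_equal(oc$FPE + oc$TNE, 12)

  ## refitting a fold reproduces the identical model
  prep <- attr(ev, "prep")
  f <- prep$folds[[1]]
  m1 <- fitSda(f$Ztrain, f$ytrain, budget = prep$budget,
               gamma = prep$gamma)
  m2 <- fitSda(f$Ztrain, f$ytrain, budget = prep$budget,
               gamma = prep$gamma)
  expect_identical(m1@beta, m2@beta)
  ## the fold's model saw (N-1) * 6 training windows
  expect_equal(nrow(f$Ztrain), 11 * 6)
  expect_equal(nrow(f$Ztest), 17)
})

test_that("a fold is blind to its held-out trial (no leakage)", {
  ts <- fixture("small12")
  ts <- removeChannels(ts, c("FC3", "FC1"))
  prep1 <- movintent:::.looPrepare(ts)
  corrupted <- ts
  set.seed(30)
  corrupted@data[4, , ] <- matrix(rnorm(length(ts@data[4, , ]),
                                        sd = 50), dim(ts@data)[2])
  prep2 <- movintent:::.looPrepare(corrupted)
  expect_equal(prep1$folds[[4]]$Ztrain, prep2$folds[[4]]$Ztrain)
  expect_equal(prep1$folds[[4]]$osfErd@weights,
               prep2$folds[[4]]$osfErd@weights)
  expect_false(isTRUE(all.equal(prep1$folds[[4]]$Ztest,
                                prep2$folds[[4]]$Ztest)))
})

test_that("decoding null data is conservative, never above chance", {
  ## With no planted effects the fold-fitted optimal spatial filters
  ## still contrast the peri-onset window against rest on the training
  ## trials, and that window-position artifact anti-generalizes: the
  ## held-out intention windows look *more* rest-like, biasing the
  ## event AUC below the 8/17 combinatorial chance point rather than
  ## above it. The decoder must never report spurious intention.
  evN <- fixture("evalNull50")
  expect_lte(evN@auc, 0.6)
  tr <- evN@traces
  expect_lte(mean(tr$score[tr$t > -1]), mean(tr$score[tr$t <= -1]))
})

test_that("chance level warns on tiny permutation counts", {
  ev <- fixture("evalNull50")
  prep <- attr(ev, "prep")
  expect_warning(
    ch <- chanceLevel(NULL, nPermutations = 1, seed = 1, prep = prep),
    "unstable")
  expect_true(is.nan(ch$sd))
  expect_length(ch$percentCorrect, 1)
})
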