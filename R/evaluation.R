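## Event-based evaluation of the continuous decoder. Each trial
## contributes one rest event (the observable rest span, window right
## edges t in [-2, -1]) and one intention event (t in (-1, 0]). The
## window ending exactly at t = -1 lies wholly in the rest phase and is
## a rest exemplar in training, so it is assigned to the rest event.

#' Event-level confusion counts from detection traces
#'
#' Per trial: the rest event is a true negative (TNE) when no detection
#' falls at `t <= -1`, else a false positive (FPE); the intention event
#' is a true positive (TPE) when at least one detection falls in
#' `(-1, 0]`, else a false negative (FNE). `TPE + FNE` and `FPE + TNE`
#' both equal the number of trials.
#'
#' @param traces data.frame with columns `trial`, `t`, `score` (pooled
#'   per-window decoder scores on the test grid).
#' @param threshold detection threshold: a window is a detection when
#'   its score is >= threshold.
#' @return list with counts TPE, FPE, TNE, FNE and the event-based
#'   sensitivity `TPE/(TPE+FNE)` and specificity `TNE/(TNE+FPE)`.
#' @export
eventOutcomes <- function(traces, threshold) {
  stopifnot(nrow(traces) > 0)
  ids <- unique(traces$trial)
  det <- traces$score >= threshold
  restHit <- tapply(det & traces$t <= -1, traces$trial, any)
  intHit <- tapply(det & traces$t > -1 & traces$t <= 0, traces$trial, any)
  restHit <- restHit[as.character(ids)]
  intHit <- intHit[as.character(ids)]
  TPE <- sum(intHit); FNE <- sum(!intHit)
  FPE <- sum(restHit); TNE <- sum(!restHit)
  list(TPE = TPE, FPE = FPE, TNE = TNE, FNE = FNE,
       sensitivity = TPE / (TPE + FNE),
       specificity = TNE / (TNE + FPE))
}

#' Event-based ROC over a threshold sweep
#'
#' Sweeps the detection threshold over the pooled score range and
#' computes the event-based sensitivity and specificity at each value.
#' The area under the curve is computed by the trapezoid rule over
#' (1 - specificity, sensitivity); the working point is the threshold
#' minimizing |sensitivity - specificity|.
#'
#' @param traces pooled trace data.frame (`trial`, `t`, `score`).
#' @return list with `roc` (data.frame threshold/sensitivity/
#'   specificity), `auc`, and `workingPoint`. Constant scores give a
#'   degenerate ROC, flagged with a warning and AUC 0.5.
#' @export
rocEvent <- function(traces) {
  scores <- traces$score
  uq <- sort(unique(scores), decreasing = TRUE)
  degenerate <- length(uq) < 2
  thresholds <- c(Inf, uq)
  sens <- spec <- numeric(length(thresholds))
  for (i in seq_along(thresholds)) {
    oc <- eventOutcomes(traces, thresholds[i])
    sens[i] <- oc$sensitivity
    spec[i] <- oc$specificity
  }
  roc <- data.frame(threshold = thresholds, sensitivity = sens,
                    specificity = spec)
  fpr <- 1 - spec
  auc <- sum(diff(fpr) * (sens[-1] + sens[-length(sens)]) / 2)
  if (degenerate) {
    warning("constant scores: degenerate ROC, AUC set to 0.5")
    auc <- 0.5
  }
  wi <- which.min(abs(sens - spec))
  list(roc = roc, auc = auc,
       workingPoint = list(threshold = thresholds[wi],
                           sensitivity = sens[wi],
                           specificity = spec[wi]))
}

#' Correct trials and anticipation at a fixed threshold
#'
#' A trial is correct when its rest event is clean (no detection at
#' `t <= -1`) and an intention is detected in `(-1, 0]`. The
#' anticipation of a correct trial is the time of its first intention-
#' interval detection relative to onset, a value in (-1, 0].
#'
#' @param traces pooled trace data.frame.
#' @param threshold detection threshold (typically the working point).
#' @return list with `percentCorrect`, `anticipation` (s, one per
#'   correct trial) and `correct` (named logical per trial).
#' @export
correctTrials <- function(traces, threshold) {
  ids <- unique(traces$trial)
  correct <- logical(length(ids)); names(correct) <- as.character(ids)
  anticipation <- numeric(0)
  for (id in ids) {
    tr <- traces[traces$trial == id, ]
    det <- tr$t[tr$score >= threshold]
    restClean <- !any(det <= -1)
    intDet <- det[det > -1 & det <= 0]
    ok <- restClean && length(intDet) > 0
    correct[as.character(id)] <- ok
    if (ok) anticipation <- c(anticipation, min(intDet))
  }
  list(percentCorrect = 100 * mean(correct),
       anticipation = anticipation, correct = correct)
}

#' Remove channels from a TrialSet
#'
#' Drops channels entirely (data and labels), as done when electrodes
#' are excluded for artifacts; all channel-dependent feature counts
#' adapt downstream.
#'
#' @param trials A \linkS4class{TrialSet}.
#' @param labels channels to remove.
#' @return The reduced \linkS4class{TrialSet}.
#' @export
removeChannels <- function(trials, labels) {
  keep <- !trials@channelLabels %in% labels
  trials@data <- trials@data[, keep, , drop = FALSE]
  trials@channelLabels <- trials@channelLabels[keep]
  trials
}

## ---- internal LOO machinery -------------------------------------------

## Precompute everything label- and fold-independent, then per fold fit
## the two OSFs on the training trials only and assemble feature
## matrices. Real-channel features do not depend on the fold and are
## computed once; OSF-channel features are recomputed per fold because
## the filters are.
.looPrepare <- function(trials, erdCh = NULL, mrcpCh = NULL,
                        budget = NULL, gamma = 1e-2, bins = 7:30,
                        arOrder = 16, fsMrcp = 64, mrcpBand = c(0.1, 1),
                        erdBand = c(7, 30), verbose = FALSE) {
  stopifnot(is(trials, "TrialSet"))
  idx <- which(trials@kept)
  N <- length(idx)
  if (N < 10) stop("leave-one-out evaluation needs at least 10 kept trials")
  labels <- trials@channelLabels
  if (is.null(erdCh)) erdCh <- intersect(erdChannels(), labels)
  if (is.null(mrcpCh)) mrcpCh <- intersect(mrcpChannels(), labels)
  if (is.null(budget)) budget <- N - 2  # < N-1 training trials per fold
  fs <- trials@fs
  tAx <- trials@time
  grid <- testWindows()$t
  trainDef <- trainingWindows()
  trainIdx <- match(trainDef$t, grid)
  nW <- length(grid)
  selFs <- lapply(grid, function(t) which(tAx >= t - 1 & tAx < t))
  factor <- round(fs / fsMrcp)
  idx64 <- seq(1, length(tAx), by = factor)
  t64 <- tAx[idx64]
  sel64 <- lapply(grid, function(t) which(t64 >= t - 1 & t64 < t))

  nbrs <- montageNeighbors(labels)
  raw <- vector("list", N)
  erdReal <- array(0, c(N, nW, length(erdCh) * length(bins)))
  mrcpReal <- array(0, c(N, nW, length(mrcpCh) * length(sel64[[1]])))
  erdCov <- vector("list", N)
  mrcpCov <- vector("list", N)
  sSel <- tAx >= -1 & tAx < 1
  nSel <- tAx >= -3 & tAx < -1
  for (k in seq_len(N)) {
    m <- trials@data[idx[k], , ]
    rownames(m) <- labels
    raw[[k]] <- m
    lap <- .laplacianMatrix(m, nbrs)
    for (w in seq_len(nW)) {
      erdReal[k, w, ] <- unlist(lapply(erdCh, function(ch)
        arSpectrum(lap[ch, selFs[[w]]], fs, bins, arOrder)),
        use.names = FALSE)
    }
    mc <- carFilter(m)
    ds <- downsampleSignal(mc[match(mrcpCh, labels), , drop = FALSE],
                           fs, fsMrcp)
    f64 <- bandpassZP(ds$data, fsMrcp, mrcpBand, order = 2)
    for (w in seq_len(nW))
      mrcpReal[k, w, ] <- as.vector(t(f64[, sel64[[w]], drop = FALSE]))
    xe <- bandpassZP(m, fs, erdBand)
    erdCov[[k]] <- list(
      sig = tcrossprod(xe[, sSel]) / sum(sSel),
      noise = tcrossprod(xe[, nSel]) / sum(nSel))
    xm <- bandpassZP(m, fs, mrcpBand)
    mrcpCov[[k]] <- list(
      sig = tcrossprod(xm[, sSel]) / sum(sSel),
      noise = tcrossprod(xm[, nSel]) / sum(nSel))
    if (verbose && k %% 10 == 0)
      message("prepared trial ", k, "/", N)
  }

  erdInit <- if ("C3" %in% labels) "C3" else labels[1]
  mrcpInit <- if ("Cz" %in% labels) "Cz" else labels[1]
  folds <- vector("list", N)
  for (k in seq_len(N)) {
    tr <- setdiff(seq_len(N), k)
    probE <- list(sigCov = lapply(erdCov[tr], `[[`, "sig"),
                  noiseCov = lapply(erdCov[tr], `[[`, "noise"),
                  labels = labels, L = length(tr))
    probM <- list(sigCov = lapply(mrcpCov[tr], `[[`, "sig"),
                  noiseCov = lapply(mrcpCov[tr], `[[`, "noise"),
                  labels = labels, L = length(tr))
    osfE <- fitOSFProblem(probE, "ERD", erdInit)
    osfM <- fitOSFProblem(probM, "MRCP", mrcpInit)
    wE <- osfE@weights; wM <- osfM@weights

    osfErdFeat <- function(i, wsel) {
      v <- drop(wE %*% raw[[i]])
      t(vapply(wsel, function(w)
        unname(arSpectrum(v[selFs[[w]]], fs, bins, arOrder)),
        numeric(length(bins))))
    }
    osfMrcpFeat <- function(i, wsel) {
      v <- drop(wM %*% raw[[i]])
      dv <- downsampleSignal(v, fs, fsMrcp)
      fv <- bandpassZP(dv$data, fsMrcp, mrcpBand, order = 2)
      t(vapply(wsel, function(w) fv[sel64[[w]]],
               numeric(length(sel64[[1]]))))
    }

    nTrainW <- length(tr) * length(trainIdx)
    p <- dim(erdReal)[3] + length(bins) +
         dim(mrcpReal)[3] + length(sel64[[1]])
    Xtrain <- matrix(0, nTrainW, p)
    ytrain <- character(nTrainW)
    row <- 1
    for (i in tr) {
      eo <- osfErdFeat(i, trainIdx)
      mo <- osfMrcpFeat(i, trainIdx)
      for (j in seq_along(trainIdx)) {
        w <- trainIdx[j]
        Xtrain[row, ] <- c(erdReal[i, w, ], eo[j, ],
                           mrcpReal[i, w, ], mo[j, ])
        ytrain[row] <- trainDef$label[j]
        row <- row + 1
      }
    }
    eoT <- osfErdFeat(k, seq_len(nW))
    moT <- osfMrcpFeat(k, seq_len(nW))
    Xtest <- matrix(0, nW, p)
    for (w in seq_len(nW))
      Xtest[w, ] <- c(erdReal[k, w, ], eoT[w, ], mrcpReal[k, w, ], moT[w, ])

    stats <- fitNormalization(Xtrain)
    folds[[k]] <- list(Ztrain = applyNormalization(stats, Xtrain),
                       ytrain = ytrain,
                       Ztest = applyNormalization(stats, Xtest),
                       osfErd = osfE, osfMrcp = osfM, stats = stats)
    if (verbose) message("fold ", k, "/", N, " prepared")
  }
  list(folds = folds, N = N, grid = grid, budget = budget, gamma = gamma,
       erdCh = erdCh, mrcpCh = mrcpCh, bins = bins,
       nMrcpSamples = length(sel64[[1]]))
}

## Fit SDA per fold (optionally with shuffled training labels) and pool
## the held-out scores into one trace table.
.looDecode <- function(prep, shuffle = FALSE) {
  traces <- vector("list", prep$N)
  models <- vector("list", prep$N)
  for (k in seq_len(prep$N)) {
    f <- prep$folds[[k]]
    y <- f$ytrain
    if (shuffle) y <- sample(y)
    model <- fitSda(f$Ztrain, y, budget = prep$budget,
                    gamma = prep$gamma)
    models[[k]] <- model
    traces[[k]] <- data.frame(trial = k, t = prep$grid,
                              score = sdaScore(model, f$Ztest))
  }
  list(traces = do.call(rbind, traces), models = models)
}

.summarizeTraces <- function(traces, nTrials) {
  rc <- rocEvent(traces)
  ct <- correctTrials(traces, rc$workingPoint$threshold)
  oc <- eventOutcomes(traces, rc$workingPoint$threshold)
  new("IntentionEval", roc = rc$roc, auc = rc$auc,
      workingPoint = rc$workingPoint, outcomes = oc,
      percentCorrect = ct$percentCorrect,
      anticipation = ct$anticipation, traces = traces,
      nTrials = as.integer(nTrials))
}

#' Trial-based leave-one-out evaluation of the continuous decoder
#'
#' For each fold, the two SNR-optimal spatial filters, the feature
#' normalization and the sparse discriminant model are estimated on the
#' N-1 training trials only, and the held-out trial is scored on the 17
#' sliding test windows. All folds' scores are pooled into one
#' event-based ROC; the percentage of correct trials and the
#' anticipation are computed at the pooled equal-sensitivity-specificity
#' working point.
#'
#' @param trials A \linkS4class{TrialSet} with >= 10 kept trials.
#' @param dropChannels channels removed from the recording before any
#'   processing (default `c("FC3", "FC1")`, the canonical exclusion;
#'   spatial-filter length and feature counts adapt).
#' @param budget SDA feature budget; default `N - 2`, the largest value
#'   below the per-fold training-trial count.
#' @param gamma SDA ridge penalty.
#' @param verbose print fold progress.
#' @return An \linkS4class{IntentionEval}.
#' @export
looEvaluate <- function(trials, dropChannels = c("FC3", "FC1"),
                        budget = NULL, gamma = 1e-2, verbose = FALSE) {
  if (length(dropChannels))
    trials <- removeChannels(trials, dropChannels)
  prep <- .looPrepare(trials, budget = budget, gamma = gamma,
                      verbose = verbose)
  dec <- .looDecode(prep, shuffle = FALSE)
  out <- .summarizeTraces(dec$traces, prep$N)
  attr(out, "models") <- dec$models
  attr(out, "prep") <- prep
  out
}

#' Empirical chance level by label permutation
#'
#' Repeats the full leave-one-out decoding with the training-window
#' labels shuffled independently in every fold, and reports the mean and
#' standard deviation of the percentage of correct trials over
#' permutations — the empirical chance level of the correct-trial
#' metric. Spatial filters and normalization do not depend on labels and
#' are reused across permutations.
#'
#' @inheritParams looEvaluate
#' @param nPermutations number of label permutations (default 10).
#' @param seed RNG seed for the shuffles.
#' @param prep optionally, the `prep` attribute of a previous
#'   [looEvaluate()] run on the same trials, to skip recomputation.
#' @return list with `mean`, `sd` (NaN with a warning when
#'   `nPermutations` is 1), the per-permutation `percentCorrect`, and
#'   the per-permutation pooled event `auc` (which should hover around
#'   chance, i.e. 0.5).
#' @export
chanceLevel <- function(trials, nPermutations = 10, seed = NULL,
                        dropChannels = c("FC3", "FC1"), budget = NULL,
                        gamma = 1e-2, prep = NULL, verbose = FALSE) {
  if (nPermutations < 3)
    warning("fewer than 3 permutations: chance estimate is unstable")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(prep)) {
    if (length(dropChannels))
      trials <- removeChannels(trials, dropChannels)
    prep <- .looPrepare(trials, budget = budget, gamma = gamma,
                        verbose = verbose)
  }
  pc <- auc <- numeric(nPermutations)
  for (r in seq_len(nPermutations)) {
    dec <- .looDecode(prep, shuffle = TRUE)
    ev <- .summarizeTraces(dec$traces, prep$N)
    pc[r] <- ev@percentCorrect
    auc[r] <- ev@auc
    if (verbose) message("permutation ", r, ": ",
                         round(pc[r], 1), "% correct")
  }
  sdv <- if (nPermutations >= 2) stats::sd(pc) else NaN
  list(mean = mean(pc), sd = sdv, percentCorrect = pc, auc = auc)
}

#' Decode a single trial with a fitted model
#'
#' Extracts the combined feature vector at every test window of one
#' trial (using the supplied fold spatial filters and normalization),
#' scores it, and marks detections at the given threshold. This is the
#' stand-alone path; the cross-validation driver uses a cached
#' equivalent.
#'
#' @param model An \linkS4class{SdaModel}.
#' @param trials A \linkS4class{TrialSet}.
#' @param trial trial index.
#' @param osfErd,osfMrcp the fold's \linkS4class{SpatialFilter}s.
#' @param stats the fold's \linkS4class{NormalizationStats}.
#' @param threshold detection threshold (default 0).
#' @param erdCh,mrcpCh feature channel lists (defaults adapt to the
#'   montage).
#' @return data.frame with columns `t`, `score`, `detected`.
#' @export
decodeTrial <- function(model, trials, trial, osfErd, osfMrcp, stats,
                        threshold = 0, erdCh = NULL, mrcpCh = NULL) {
  if (is.null(erdCh))
    erdCh <- intersect(erdChannels(), trials@channelLabels)
  if (is.null(mrcpCh))
    mrcpCh <- intersect(mrcpChannels(), trials@channelLabels)
  grid <- testWindows()$t
  X <- t(vapply(grid, function(t)
    c(erdFeatures(trials, trial, t, channels = erdCh, osf = osfErd),
      mrcpFeatures(trials, trial, t, channels = mrcpCh, osf = osfMrcp)),
    numeric(length(model@beta))))
  Z <- applyNormalization(stats, X)
  sc <- sdaScore(model, Z)
  data.frame(t = grid, score = sc, detected = sc >= threshold)
}
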