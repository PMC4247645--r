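## Shared fixtures, built lazily and memoized for the whole test run so
## the expensive synthetic datasets are generated once.

.fx <- new.env(parent = emptyenv())

fixture <- function(name) {
  if (!is.null(.fx[[name]])) return(.fx[[name]])
  .fx[[name]] <- switch(name,
    ## reference study conditions, 50 trials (decoder-scale runs)
    strong50 = generateTrialSet(effectSpec(nTrials = 50, seed = 5)),
    ## large replicate for planted-parameter recovery
    strong200 = generateTrialSet(effectSpec(nTrials = 200, seed = 5)),
    ## no planted effects at all
    null50 = generateTrialSet(effectSpec(erdDepth = 0, mrcpPeak = 0,
                                         nTrials = 50, seed = 11)),
    null200 = generateTrialSet(effectSpec(erdDepth = 0, mrcpPeak = 0,
                                          nTrials = 200, seed = 11)),
    ## small set for driver-contract tests
    small12 = generateTrialSet(effectSpec(nTrials = 12, seed = 3)),
    ## full strong-effect leave-one-out evaluation
    evalStrong50 = looEvaluate(fixture("strong50")),
    evalNull50 = looEvaluate(fixture("null50")),
    ## label-shuffled reruns on the strong-effect folds (empirical
    ## chance of the correct-trial metric and of the event AUC)
    chance50 = suppressWarnings(
      chanceLevel(NULL, nPermutations = 5, seed = 101,
                  prep = attr(fixture("evalStrong50"), "prep"))),
    stop("unknown fixture: ", name))
  .fx[[name]]
}

## independent brute-force re-derivation of event outcomes from raw
## detection sets (oracle for eventOutcomes)
bruteEventOutcomes <- function(traces, threshold) {
  TPE <- FPE <- TNE <- FNE <- 0L
  for (id in unique(traces$trial)) {
    tr <- traces[traces$trial == id, ]
    det <- tr$t[tr$score >= threshold]
    if (any(det <= -1)) FPE <- FPE + 1L else TNE <- TNE + 1L
    if (any(det > -1 & det <= 0)) TPE <- TPE + 1L else FNE <- FNE + 1L
  }
  list(TPE = TPE, FPE = FPE, TNE = TNE, FNE = FNE)
}

## random pooled trace table on the standard test grid
randomTraces <- function(nTrials, seed = 1) {
  set.seed(seed)
  grid <- testWindows()$t
  do.call(rbind, lapply(seq_len(nTrials), function(k)
    data.frame(trial = k, t = grid, score = rnorm(length(grid)))))
}
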