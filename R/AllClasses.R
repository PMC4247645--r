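#' @import methods
NULL

#' Continuous multichannel EEG recording
#'
#' Container for a continuous EEG recording in microvolts, together with
#' auxiliary movement channels (kinematic/EMG) used for onset detection
#' and optional annotations.
#'
#' @slot data numeric matrix, channels x samples, microvolts.
#' @slot fs sampling frequency in Hz.
#' @slot channelLabels unique channel names (10/10 labels where possible).
#' @slot aux named list of auxiliary channels; each element is a list with
#'   fields `data` (numeric vector) and `fs` (its own sampling rate, Hz).
#' @slot annotations data.frame with columns `time` (s) and `label`.
#'
#' @export
setClass("EEGRecording",
  representation(
    data = "matrix",
    fs = "numeric",
    channelLabels = "character",
    aux = "list",
    annotations = "data.frame"
  ),
  prototype(
    fs = 512,
    aux = list(),
    annotations = data.frame(time = numeric(0), label = character(0))
  )
)

setValidity("EEGRecording", function(object) {
  msg <- character(0)
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (nrow(object@data) != length(object@channelLabels))
    msg <- c(msg, "channelLabels length must equal number of data rows")
  if (anyDuplicated(object@channelLabels))
    msg <- c(msg, sprintf("duplicate channel label: %s",
      paste(unique(object@channelLabels[duplicated(object@channelLabels)]),
            collapse = ", ")))
  for (nm in names(object@aux)) {
    a <- object@aux[[nm]]
    if (!is.list(a) || is.null(a$data) || is.null(a$fs))
      msg <- c(msg, sprintf("aux channel '%s' must carry data and fs", nm))
    else if (!is.numeric(a$fs) || a$fs <= 0)
      msg <- c(msg, sprintf("aux channel '%s' has invalid fs", nm))
  }
  if (length(msg)) msg else TRUE
})

#' Epoched trials on a fixed peri-movement time axis
#'
#' Trials epoched around detected movement onsets. Time is in seconds
#' relative to onset (t = 0); the default axis covers [-3, 3). Rejected
#' trials are masked via `kept`, never deleted, so the rejection audit
#' trail is preserved.
#'
#' @slot data numeric array, trials x channels x samples, microvolts.
#' @slot time numeric vector of sample times (s, relative to onset).
#' @slot fs sampling frequency, Hz.
#' @slot channelLabels channel names, one per array column.
#' @slot movement free-text movement label.
#' @slot kept logical mask of retained trials.
#' @slot rejectReasons character, one entry per trial ("" if kept).
#' @slot auxEpochs optional array (trials x samples) of an epoched
#'   auxiliary channel on the same axis, or a 0-length array.
#' @slot metadata free-form list (audit trail: artifact measures,
#'   dropped-onset log, generator parameters, ...).
#'
#' @export
setClass("TrialSet",
  representation(
    data = "array",
    time = "numeric",
    fs = "numeric",
    channelLabels = "character",
    movement = "character",
    kept = "logical",
    rejectReasons = "character",
    auxEpochs = "array",
    metadata = "list"
  ),
  prototype(movement = "unknown", auxEpochs = array(numeric(0), c(0, 0)),
            metadata = list())
)

setValidity("TrialSet", function(object) {
  msg <- character(0)
  d <- dim(object@data)
  if (length(d) != 3L)
    msg <- c(msg, "data must be a trials x channels x samples array")
  else {
    if (d[2] != length(object@channelLabels))
      msg <- c(msg, "channelLabels must match data dim 2")
    if (d[3] != length(object@time))
      msg <- c(msg, "time axis must match data dim 3")
    if (d[1] != length(object@kept))
      msg <- c(msg, "kept mask must have one entry per trial")
    if (d[1] != length(object@rejectReasons))
      msg <- c(msg, "rejectReasons must have one entry per trial")
  }
  if (length(object@time) > 1) {
    dt <- diff(object@time)
    if (any(abs(dt - 1 / object@fs) > 1e-9))
      msg <- c(msg, "time axis must be uniform at 1/fs")
  }
  if (length(msg)) msg else TRUE
})

#' Sum-zero spatial filter
#'
#' A per-channel weight vector with zero sum, targeting either the slow
#' movement-related potential (MRCP; SNR maximised) or the oscillatory
#' desynchronization (ERD; SNR minimised).
#'
#' @slot weights named numeric weights, one per channel, summing to zero.
#' @slot target `"ERD"` or `"MRCP"`.
#' @slot snrAchieved achieved mean SNR in dB.
#' @slot snrInit SNR of the initial (CAR-for-channel) filter, dB.
#' @slot converged logical; FALSE when the optimizer failed and the
#'   initial filter was returned.
#'
#' @export
setClass("SpatialFilter",
  representation(
    weights = "numeric",
    target = "character",
    snrAchieved = "numeric",
    snrInit = "numeric",
    converged = "logical"
  ),
  prototype(snrAchieved = NA_real_, snrInit = NA_real_, converged = TRUE)
)

setValidity("SpatialFilter", function(object) {
  msg <- character(0)
  if (!object@target %in% c("ERD", "MRCP"))
    msg <- c(msg, "target must be 'ERD' or 'MRCP'")
  if (is.null(names(object@weights)))
    msg <- c(msg, "weights must be named by channel")
  if (abs(sum(object@weights)) > 1e-8)
    msg <- c(msg, "weights must sum to zero (within 1e-8)")
  if (all(object@weights == 0))
    msg <- c(msg, "weights must not be all zero")
  if (length(msg)) msg else TRUE
})

#' Time-frequency map of relative power change
#'
#' Trial-averaged Morlet power expressed as percent change versus the
#' pre-movement baseline, optionally with a bootstrap significance mask.
#'
#' @slot values matrix, frequencies x times, percent change.
#' @slot freqs analysis frequencies, Hz.
#' @slot times time axis, s relative to onset.
#' @slot baseline baseline window (s pair) the change is referenced to.
#' @slot mask logical matrix (same shape) of significant cells, or a
#'   0 x 0 matrix when no bootstrap was run.
#' @slot channel source channel name (a montage label or "OSF").
#'
#' @export
setClass("TimeFreqMap",
  representation(
    values = "matrix",
    freqs = "numeric",
    times = "numeric",
    baseline = "numeric",
    mask = "matrix",
    channel = "character"
  ),
  prototype(baseline = c(-3, -1), mask = matrix(logical(0), 0, 0))
)

setValidity("TimeFreqMap", function(object) {
  msg <- character(0)
  if (nrow(object@values) != length(object@freqs))
    msg <- c(msg, "values rows must match freqs")
  if (ncol(object@values) != length(object@times))
    msg <- c(msg, "values cols must match times")
  if (length(object@mask) && !identical(dim(object@mask), dim(object@values)))
    msg <- c(msg, "mask shape must equal values shape")
  if (length(msg)) msg else TRUE
})

#' Trial-averaged movement-related cortical potential
#'
#' Slow (0.1-1 Hz) negative potential at 64 Hz around movement onset.
#'
#' @slot waveforms matrix, channels x samples, microvolts (or normalized).
#' @slot time time axis at 64 Hz, s relative to onset.
#' @slot channelLabels channel names (may include "OSF").
#' @slot peakAmplitude per-channel minimum in the peri-onset window.
#' @slot peakLatency per-channel latency of that minimum, s.
#' @slot normalized logical; TRUE after cross-movement normalization.
#'
#' @export
setClass("MrcpWaveform",
  representation(
    waveforms = "matrix",
    time = "numeric",
    channelLabels = "character",
    peakAmplitude = "numeric",
    peakLatency = "numeric",
    normalized = "logical"
  ),
  prototype(normalized = FALSE)
)

#' Per-feature normalization statistics
#'
#' Mean and standard deviation estimated on training windows only, applied
#' unchanged to test windows. Zero-variance features map to 0 and are
#' flagged.
#'
#' @slot mean per-feature training mean.
#' @slot sd per-feature training standard deviation.
#' @slot zeroVar logical flags for degenerate features.
#'
#' @export
setClass("NormalizationStats",
  representation(mean = "numeric", sd = "numeric", zeroVar = "logical")
)

#' Sparse discriminant model for rest vs intention
#'
#' Two-class sparse discriminant analysis: a single discriminant direction
#' with at most `budget` nonzero coefficients, fitted by sparse optimal
#' scoring (elastic-net regression of class scores). Higher scores mean
#' intention.
#'
#' @slot beta coefficient vector over the feature space.
#' @slot intercept scalar offset placing the decision threshold at 0.
#' @slot budget feature budget K (max nonzeros).
#' @slot gamma ridge penalty used in the elastic-net step.
#' @slot selected integer indices of nonzero coefficients.
#' @slot featureMap data.frame describing each feature (kind, channel,
#'   bin or sample), as produced by the feature extractor.
#' @slot normStats the \linkS4class{NormalizationStats} used at fit time.
#'
#' @export
setClass("SdaModel",
  representation(
    beta = "numeric",
    intercept = "numeric",
    budget = "numeric",
    gamma = "numeric",
    selected = "integer",
    featureMap = "data.frame",
    normStats = "ANY"
  ),
  prototype(featureMap = data.frame(), normStats = NULL)
)

setValidity("SdaModel", function(object) {
  msg <- character(0)
  if (sum(object@beta != 0) > object@budget)
    msg <- c(msg, "number of nonzero coefficients exceeds the budget")
  if (!identical(object@selected, which(object@beta != 0)))
    msg <- c(msg, "selected must index the nonzero coefficients")
  if (length(msg)) msg else TRUE
})

#' Event-based evaluation summary
#'
#' Pooled leave-one-out evaluation of the continuous decoder: event-based
#' ROC, AUC, the equal-sensitivity-specificity working point, percentage
#' of correct trials and their anticipation.
#'
#' @slot roc data.frame with columns threshold, sensitivity, specificity.
#' @slot auc area under the event-based ROC.
#' @slot workingPoint list(threshold, sensitivity, specificity).
#' @slot outcomes list with TPE, FPE, TNE, FNE at the working point.
#' @slot percentCorrect percentage of correct trials at the working point.
#' @slot anticipation anticipation times (s, in (-1, 0]) of correct trials.
#' @slot traces data.frame of pooled per-window scores (trial, t, score).
#' @slot nTrials number of evaluated trials.
#'
#' @export
setClass("IntentionEval",
  representation(
    roc = "data.frame",
    auc = "numeric",
    workingPoint = "list",
    outcomes = "list",
    percentCorrect = "numeric",
    anticipation = "numeric",
    traces = "data.frame",
    nTrials = "integer"
  )
)
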