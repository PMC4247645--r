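#' @rdname accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' @rdname accessors
#' @export
setGeneric("keptTrials", function(x) standardGeneric("keptTrials"))

#' @rdname accessors
#' @export
setGeneric("trialTime", function(x) standardGeneric("trialTime"))

#' @rdname accessors
#' @export
setGeneric("filterWeights", function(x) standardGeneric("filterWeights"))

#' Accessors for movintent containers
#'
#' Small accessor generics: `channelLabels` and `samplingRate` apply to
#' \linkS4class{EEGRecording} and \linkS4class{TrialSet}; `nTrials`,
#' `keptTrials` (indices of retained trials) and `trialTime` to
#' \linkS4class{TrialSet}; `filterWeights` to \linkS4class{SpatialFilter}.
#'
#' @param x object.
#' @name accessors
#' @rdname accessors
NULL

#' @rdname accessors
#' @export
setMethod("channelLabels", "EEGRecording", function(x) x@channelLabels)

#' @rdname accessors
#' @export
setMethod("channelLabels", "TrialSet", function(x) x@channelLabels)

#' @rdname accessors
#' @export
setMethod("samplingRate", "EEGRecording", function(x) x@fs)

#' @rdname accessors
#' @export
setMethod("samplingRate", "TrialSet", function(x) x@fs)

#' @rdname accessors
#' @export
setMethod("nTrials", "TrialSet", function(x) dim(x@data)[1])

#' @rdname accessors
#' @export
setMethod("keptTrials", "TrialSet", function(x) which(x@kept))

#' @rdname accessors
#' @export
setMethod("trialTime", "TrialSet", function(x) x@time)

#' @rdname accessors
#' @export
setMethod("filterWeights", "SpatialFilter", function(x) x@weights)

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: %d channels x %d samples @ %g Hz (%.1f s)\n",
    nrow(object@data), ncol(object@data), object@fs,
    ncol(object@data) / object@fs))
  if (length(object@aux))
    cat("  aux channels:", paste(names(object@aux), collapse = ", "), "\n")
  if (nrow(object@annotations))
    cat("  annotations:", nrow(object@annotations), "\n")
})

setMethod("show", "TrialSet", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "TrialSet '%s': %d trials (%d kept) x %d channels x %d samples @ %g Hz\n",
    object@movement, d[1], sum(object@kept), d[2], d[3], object@fs))
  cat(sprintf("  time axis [%g, %g] s relative to onset\n",
    min(object@time), max(object@time)))
})

setMethod("show", "SpatialFilter", function(object) {
  cat(sprintf("SpatialFilter (%s): %d channels, SNR %0.2f dB (init %0.2f)%s\n",
    object@target, length(object@weights), object@snrAchieved,
    object@snrInit, if (object@converged) "" else " [not converged]"))
})

setMethod("show", "TimeFreqMap", function(object) {
  cat(sprintf(
    "TimeFreqMap @%s: %d freqs [%g-%g Hz] x %d times [%g, %g] s%s\n",
    object@channel, length(object@freqs), min(object@freqs),
    max(object@freqs), length(object@times), min(object@times),
    max(object@times),
    if (length(object@mask)) " (with significance mask)" else ""))
})

setMethod("show", "SdaModel", function(object) {
  cat(sprintf(
    "SdaModel: %d/%d features selected (budget %d), ridge %g\n",
    length(object@selected), length(object@beta),
    as.integer(object@budget), object@gamma))
})

setMethod("show", "IntentionEval", function(object) {
  wp <- object@workingPoint
  cat(sprintf("IntentionEval over %d trials\n", object@nTrials))
  cat(sprintf("  event AUC: %.3f\n", object@auc))
  cat(sprintf("  working point: sens %.3f / spec %.3f (thr %.3g)\n",
    wp$sensitivity, wp$specificity, wp$threshold))
  cat(sprintf("  correct trials: %.1f%%; mean anticipation %.0f ms\n",
    object@percentCorrect,
    if (length(object@anticipation)) 1000 * mean(object@anticipation)
    else NA_real_))
})
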