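#' Detect movement onsets from auxiliary channels
#'
#' Onset detection from kinematic/EMG channels in three steps: each
#' channel is demeaned and rectified, channels are averaged, and onsets
#' are the upward crossings of `fraction` times the maximum of the
#' averaged signal. Crossings closer than `refractory` seconds are merged
#' (first kept); self-initiated trials are far apart, so the default 2 s
#' gap cannot merge true onsets.
#'
#' @param aux numeric vector or channels x samples matrix.
#' @param fs sampling rate of `aux`, Hz.
#' @param fraction threshold as a fraction of the maximum (default 0.05).
#' @param refractory merge gap, s.
#' @return Numeric vector of onset times, s (time of sample `i` is
#'   `(i-1)/fs`). Empty (with a warning) when the signal is identically
#'   zero.
#' @export
#' @examples
#' t <- seq(0, 10, by = 1/128)
#' bump <- exp(-(t - 5)^2 / (2 * 0.1^2))
#' detectOnsets(bump, fs = 128)
detectOnsets <- function(aux, fs, fraction = 0.05, refractory = 2) {
  stopifnot(fraction > 0, fraction < 1, fs > 0)
  if (!is.matrix(aux)) aux <- matrix(aux, nrow = 1)
  proc <- colMeans(abs(aux - rowMeans(aux)))
  m <- max(proc)
  if (m == 0) {
    warning("auxiliary signal is identically zero; no onsets")
    return(numeric(0))
  }
  thr <- fraction * m
  above <- proc >= thr
  cross <- which(above & !c(FALSE, above[-length(above)]))
  if (!length(cross)) return(numeric(0))
  keep <- cross[1]
  for (i in cross[-1])
    if ((i - keep[length(keep)]) / fs >= refractory) keep <- c(keep, i)
  (keep - 1) / fs
}

#' Epoch a recording around movement onsets
#'
#' Cuts one fixed-length epoch per onset on the time axis `window`
#' (half-open at the right edge) relative to each onset. Onsets without
#' full window support, or preceded by another onset within `minRest`
#' seconds (movements started before the required rest), are dropped with
#' a logged reason.
#'
#' @param recording An \linkS4class{EEGRecording}.
#' @param onsets onset times, s.
#' @param window epoch window, s pair (default `c(-3, 3)`).
#' @param movement movement label attached to the trials.
#' @param minRest required quiet time before each onset, s.
#' @param auxChannel name of an auxiliary channel to epoch alongside
#'   (must share the EEG sampling rate), or NULL.
#' @return A \linkS4class{TrialSet}; `metadata(x)$droppedOnsets` records
#'   dropped onsets and reasons.
#' @export
epochTrials <- function(recording, onsets, window = c(-3, 3),
                        movement = "unknown", minRest = 3,
                        auxChannel = "kinematic") {
  stopifnot(is(recording, "EEGRecording"), window[1] < window[2])
  fs <- recording@fs
  nSamp <- ncol(recording@data)
  winN <- round((window[2] - window[1]) * fs)
  time <- window[1] + (seq_len(winN) - 1) / fs

  aux <- NULL
  if (!is.null(auxChannel) && auxChannel %in% names(recording@aux)) {
    a <- recording@aux[[auxChannel]]
    if (isTRUE(all.equal(a$fs, fs))) aux <- a$data
  }

  keepOnsets <- list(); dropped <- list()
  ord <- order(onsets)
  onsets <- onsets[ord]
  for (i in seq_along(onsets)) {
    o <- onsets[i]
    i0 <- round((o + window[1]) * fs) + 1
    i1 <- i0 + winN - 1
    reason <- NULL
    if (i0 < 1) reason <- "insufficient pre-onset data"
    else if (i1 > nSamp) reason <- "insufficient post-onset data"
    else if (i > 1 && (o - onsets[i - 1]) < minRest)
      reason <- "insufficient pre-onset rest"
    if (is.null(reason)) keepOnsets[[length(keepOnsets) + 1]] <-
        list(onset = o, i0 = i0)
    else dropped[[length(dropped) + 1]] <- list(onset = o, reason = reason)
  }
  nTr <- length(keepOnsets)
  if (nTr == 0) stop("no onset has full epoch support")
  dat <- array(0, c(nTr, nrow(recording@data), winN))
  auxE <- if (!is.null(aux)) array(0, c(nTr, winN)) else
    array(numeric(0), c(0, 0))
  for (k in seq_len(nTr)) {
    idx <- keepOnsets[[k]]$i0 + seq_len(winN) - 1
    dat[k, , ] <- recording@data[, idx]
    if (!is.null(aux)) auxE[k, ] <- aux[idx]
  }
  new("TrialSet", data = dat, time = time, fs = fs,
    channelLabels = recording@channelLabels, movement = movement,
    kept = rep(TRUE, nTr), rejectReasons = rep("", nTr),
    auxEpochs = auxE,
    metadata = list(
      onsets = vapply(keepOnsets, `[[`, numeric(1), "onset"),
      droppedOnsets = dropped))
}

#' Z-score artifact rejection
#'
#' Per kept trial, six measures are computed: band power in delta
#' (1-4 Hz), theta (4-7 Hz), alpha (7-12 Hz) and beta (12-30 Hz), the
#' variance, and the maximum absolute amplitude. Each measure is computed
#' per channel then averaged over channels, giving one scalar per measure
#' per trial. A trial is rejected when any of its measures exceeds
#' `multiplier` times the mean of that measure across the trials
#' considered (single pass, no re-computation). Rejected trials are
#' masked, never deleted.
#'
#' @param trials A \linkS4class{TrialSet} with at least 3 kept trials.
#' @param multiplier rejection threshold multiplier (default 2.5).
#' @return The \linkS4class{TrialSet} with updated `kept` mask and
#'   reasons; the measure table is stored in `metadata$artifactMeasures`.
#' @export
rejectArtifacts <- function(trials, multiplier = 2.5) {
  stopifnot(is(trials, "TrialSet"))
  idx <- which(trials@kept)
  if (length(idx) < 3)
    stop("artifact rejection needs at least 3 kept trials")
  fs <- trials@fs
  bands <- list(delta = c(1, 4), theta = c(4, 7),
                alpha = c(7, 12), beta = c(12, 30))
  measures <- matrix(NA_real_, length(idx), 6,
    dimnames = list(NULL, c(names(bands), "variance", "maxAbs")))
  for (k in seq_along(idx)) {
    x <- trials@data[idx[k], , ]
    for (b in seq_along(bands))
      measures[k, b] <- mean(bandPower(x, fs, bands[[b]]))
    measures[k, "variance"] <- mean(apply(x, 1, stats::var))
    measures[k, "maxAbs"] <- mean(apply(abs(x), 1, max))
  }
  mu <- colMeans(measures)
  bad <- measures > multiplier * rep(mu, each = nrow(measures))
  out <- trials
  for (k in seq_along(idx)) {
    if (any(bad[k, ])) {
      out@kept[idx[k]] <- FALSE
      out@rejectReasons[idx[k]] <- paste0("artifact: ",
        paste(colnames(measures)[bad[k, ]], collapse = ","))
    }
  }
  out@metadata$artifactMeasures <-
    data.frame(trial = idx, measures, rejected = apply(bad, 1, any))
  out
}

#' Extract the kept trials of a TrialSet as a plain array
#'
#' @param trials A \linkS4class{TrialSet}.
#' @return Array kept-trials x channels x samples.
#' @export
keptData <- function(trials) {
  trials@data[trials@kept, , , drop = FALSE]
}
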