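## Quantification of the two pre-movement EEG correlates: event-related
## desynchronization (time-frequency % power change vs rest baseline) and
## the movement-related cortical potential (slow peri-onset negativity).

## single-channel epochs for a label or a supplied virtual channel
.channelEpochs <- function(trials, channel) {
  if (is.matrix(channel)) {
    stopifnot(ncol(channel) == length(trials@time))
    return(channel[trials@kept[seq_len(nrow(channel))], , drop = FALSE])
  }
  stopifnot(channel %in% trials@channelLabels)
  ci <- match(channel, trials@channelLabels)
  keptData(trials)[, ci, ]
}

## per-trial Morlet power on a block-averaged time grid:
## returns list(power = trials x freqs x times array, times)
.tfPower <- function(epochs, fs, time, freqs, cycles, timeDecim,
                     bandpass = c(1, 50)) {
  nTr <- nrow(epochs)
  nS <- ncol(epochs)
  nt <- floor(nS / timeDecim)
  blk <- rep(seq_len(nt), each = timeDecim)[seq_len(nS)]
  out <- array(0, c(nTr, length(freqs), nt))
  for (k in seq_len(nTr)) {
    x <- bandpassZP(epochs[k, ], fs, bandpass)
    p <- morletPower(x, fs, freqs, cycles)
    ## block-mean over time (power is positive; averaging is the
    ## anti-aliased way to decimate it)
    for (f in seq_along(freqs))
      out[k, f, ] <- tapply(p[f, seq_len(nt * timeDecim)],
                            blk[seq_len(nt * timeDecim)], mean)
  }
  times <- tapply(time[seq_len(nt * timeDecim)],
                  blk[seq_len(nt * timeDecim)], mean)
  list(power = out, times = as.numeric(times))
}

#' Time-frequency map of event-related (de)synchronization
#'
#' Morlet-wavelet power (7 cycles by default) of a single channel,
#' trial-averaged and expressed as percent change versus the trial-
#' averaged baseline power in `baseline` (classical ERD definition:
#' the reference is computed per frequency from the trial-averaged
#' power). Input trials should already be Laplacian-filtered for real
#' channels; pass a projected trials x samples matrix as `channel` for
#' an OSF virtual channel.
#'
#' @param trials A \linkS4class{TrialSet} (>= 5 kept trials).
#' @param channel montage label, or a trials x samples matrix of a
#'   virtual channel on the same time axis.
#' @param freqs analysis frequencies, Hz (default 1:50).
#' @param baseline reference window, s pair (default `c(-3, -1)`).
#' @param cycles Morlet width in cycles (default 7).
#' @param timeDecim block size (samples) for time-axis decimation of the
#'   power maps (default 16, i.e. 32 Hz map resolution at fs = 512).
#' @param bandpass broadband prefilter, Hz pair (default `c(1, 50)`).
#' @return A \linkS4class{TimeFreqMap}.
#' @export
erdMap <- function(trials, channel, freqs = 1:50, baseline = c(-3, -1),
                   cycles = 7, timeDecim = 16, bandpass = c(1, 50)) {
  if (sum(trials@kept) < 5)
    stop("erdMap needs at least 5 kept trials (unstable baseline)")
  epochs <- .channelEpochs(trials, channel)
  tf <- .tfPower(epochs, trials@fs, trials@time, freqs, cycles, timeDecim,
                 bandpass)
  P <- apply(tf$power, c(2, 3), mean)
  bSel <- tf$times >= baseline[1] & tf$times < baseline[2]
  ref <- rowMeans(P[, bSel, drop = FALSE])
  vals <- 100 * (P - ref) / ref
  new("TimeFreqMap", values = vals, freqs = freqs, times = tf$times,
      baseline = baseline,
      channel = if (is.matrix(channel)) "OSF" else channel)
}

#' Bootstrap significance mask for an ERD map
#'
#' Resamples trials with replacement `B` times, recomputes the percent-
#' change map for each resample (reference taken from the resampled
#' baseline), and flags a time-frequency cell as significant when the
#' percentile interval `(alpha/2, 1 - alpha/2)` of its percent change
#' excludes zero. Per-cell intervals, no multiple-comparison correction.
#'
#' @inheritParams erdMap
#' @param alpha significance level (default 0.05).
#' @param B number of bootstrap resamples (default 1000; < 100 warns).
#' @param seed optional RNG seed for the resampling.
#' @return The \linkS4class{TimeFreqMap} with its `mask` slot filled.
#' @export
bootstrapMask <- function(trials, channel, alpha = 0.05, B = 1000,
                          freqs = 1:50, baseline = c(-3, -1), cycles = 7,
                          timeDecim = 16, bandpass = c(1, 50),
                          seed = NULL) {
  if (sum(trials@kept) < 10)
    stop("bootstrapMask needs at least 10 kept trials")
  if (B < 100) warning("B < 100 bootstrap resamples is unreliable")
  if (!is.null(seed)) set.seed(seed)
  epochs <- .channelEpochs(trials, channel)
  tf <- .tfPower(epochs, trials@fs, trials@time, freqs, cycles, timeDecim,
                 bandpass)
  nTr <- dim(tf$power)[1]; nf <- length(freqs); nt <- length(tf$times)
  P <- matrix(tf$power, nTr, nf * nt)  # trials x cells, freq fastest
  W <- matrix(0, B, nTr)
  for (b in seq_len(B)) {
    cnt <- tabulate(sample.int(nTr, nTr, replace = TRUE), nTr)
    W[b, ] <- cnt / nTr
  }
  M <- array(W %*% P, c(B, nf, nt))
  bSel <- tf$times >= baseline[1] & tf$times < baseline[2]
  ref <- apply(M[, , bSel, drop = FALSE], c(1, 2), mean)  # B x nf
  pct <- array(0, c(B, nf, nt))
  for (tt in seq_len(nt)) pct[, , tt] <- 100 * (M[, , tt] - ref) / ref
  pctM <- matrix(pct, B, nf * nt)
  qs <- apply(pctM, 2, stats::quantile,
              probs = c(alpha / 2, 1 - alpha / 2), names = FALSE)
  mask <- matrix(qs[1, ] > 0 | qs[2, ] < 0, nf, nt)

  Pm <- apply(tf$power, c(2, 3), mean)
  refm <- rowMeans(Pm[, bSel, drop = FALSE])
  vals <- 100 * (Pm - refm) / refm
  new("TimeFreqMap", values = vals, freqs = freqs, times = tf$times,
      baseline = baseline, mask = mask,
      channel = if (is.matrix(channel)) "OSF" else channel)
}

#' Pre-movement ERD percentage
#'
#' Mean percent power change over the band's frequencies and the last
#' second before onset (times in `[-1, 0)`), the scalar summarized per
#' channel and movement in ERD tables.
#'
#' @param map A \linkS4class{TimeFreqMap}.
#' @param band `"alpha"` (7-12 Hz), `"beta"` (12-30 Hz) or an Hz pair.
#' @param window time window, s pair (default `c(-1, 0)`).
#' @return Percent change (negative = desynchronization).
#' @export
premovementERD <- function(map, band = "alpha", window = c(-1, 0)) {
  if (is.character(band))
    band <- switch(band, alpha = c(7, 12), beta = c(12, 30),
                   stop("unknown band: ", band))
  fSel <- map@freqs >= band[1] & map@freqs <= band[2]
  tSel <- map@times >= window[1] & map@times < window[2]
  if (!any(fSel)) stop("band outside the map's frequency range")
  if (!any(tSel)) stop("window outside the map's time range")
  mean(map@values[fSel, tSel])
}

#' Trial-averaged movement-related cortical potential
#'
#' CAR-filters the trials (unless `applyCar = FALSE`), subsamples each
#' channel to `fsTarget` (anti-aliased), bandpass-filters to
#' 0.1-1 Hz with a zero-phase 2nd-order Butterworth, and averages across
#' trials. The peak is the minimum in `peakWindow` around onset.
#'
#' @param trials A \linkS4class{TrialSet}.
#' @param channels labels to extract (default the 8 central MRCP
#'   channels present in the montage).
#' @param virtual optional trials x samples matrix of an OSF virtual
#'   channel to append (labelled "OSF").
#' @param fsTarget output rate, Hz (default 64).
#' @param band slow-potential band, Hz pair (default `c(0.1, 1)`).
#' @param peakWindow window for the negative peak, s pair.
#' @param applyCar apply common average referencing first (default TRUE).
#' @return A \linkS4class{MrcpWaveform}.
#' @export
mrcpWaveform <- function(trials, channels = NULL, virtual = NULL,
                         fsTarget = 64, band = c(0.1, 1),
                         peakWindow = c(-1, 1), applyCar = TRUE) {
  stopifnot(is(trials, "TrialSet"))
  if (is.null(channels))
    channels <- intersect(mrcpChannels(), trials@channelLabels)
  if (applyCar) trials <- carFilter(trials)
  dat <- keptData(trials)
  ci <- match(channels, trials@channelLabels)
  if (anyNA(ci)) stop("unknown channels: ",
                      paste(channels[is.na(ci)], collapse = ", "))
  nTr <- dim(dat)[1]
  labels <- channels
  sig <- lapply(seq_along(ci), function(j)
    matrix(dat[, ci[j], ], nrow = nTr))
  if (!is.null(virtual)) {
    sig <- c(sig, list(virtual[trials@kept[seq_len(nrow(virtual))], ,
                               drop = FALSE]))
    labels <- c(labels, "OSF")
  }
  ds1 <- downsampleSignal(sig[[1]], trials@fs, fsTarget)
  n64 <- ncol(ds1$data)
  time64 <- trials@time[seq(1, length(trials@time),
                            by = round(trials@fs / fsTarget))][seq_len(n64)]
  wf <- matrix(0, length(sig), n64)
  for (j in seq_along(sig)) {
    ds <- if (j == 1) ds1 else downsampleSignal(sig[[j]], trials@fs,
                                                fsTarget)
    filt <- bandpassZP(ds$data, fsTarget, band, order = 2)
    wf[j, ] <- colMeans(filt)
  }
  pSel <- time64 >= peakWindow[1] & time64 <= peakWindow[2]
  peak <- apply(wf[, pSel, drop = FALSE], 1, min)
  lat <- time64[pSel][apply(wf[, pSel, drop = FALSE], 1, which.min)]
  new("MrcpWaveform", waveforms = wf, time = time64,
      channelLabels = labels, peakAmplitude = peak, peakLatency = lat,
      normalized = FALSE)
}

#' Normalize MRCP waveforms across movements
#'
#' Per channel, scales every movement's waveform by the largest negative
#' peak magnitude across the movements, so the movement with the highest
#' amplitude has a normalized peak of exactly -1.0 at that channel.
#'
#' @param waveforms named list of \linkS4class{MrcpWaveform} objects
#'   (one per movement) sharing channel sets.
#' @return The list with waveforms and peaks normalized.
#' @export
normalizeMrcp <- function(waveforms) {
  stopifnot(length(waveforms) >= 1)
  labels <- waveforms[[1]]@channelLabels
  peaks <- vapply(waveforms, function(w) w@peakAmplitude,
                  numeric(length(labels)))
  if (is.null(dim(peaks))) peaks <- matrix(peaks, nrow = length(labels))
  scale <- apply(abs(peaks), 1, max)
  scale[scale == 0] <- 1
  lapply(waveforms, function(w) {
    w@waveforms <- w@waveforms / scale
    w@peakAmplitude <- w@peakAmplitude / scale
    w@normalized <- TRUE
    w
  })
}
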