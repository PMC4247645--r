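## Windowed feature extraction. Every feature vector describes one
## 1-second window [t-1, t) (half-open: the sample at exactly t is
## excluded, so a 64 Hz window holds exactly 64 samples and no sample at
## times >= t is ever used -- the causality that licenses "pre-movement"
## claims).

#' Burg autoregressive power spectrum at integer frequency bins
#'
#' Fits an AR model by Burg's method and evaluates its power spectral
#' density at the requested frequencies (1 Hz resolution when `freqs`
#' are consecutive integers). A zero-variance input returns a spectrum
#' of zeros rather than failing.
#'
#' @param x numeric vector (one window of one channel).
#' @param fs sampling rate, Hz.
#' @param freqs frequencies at which to evaluate the PSD, Hz.
#' @param order AR model order (default 16).
#' @return Named numeric vector of power values, one per frequency.
#' @export
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 1, length.out = 512))
#' sp <- arSpectrum(x, 512, 7:30)
#' names(which.max(sp))  # "10"
arSpectrum <- function(x, fs, freqs = 7:30, order = 16) {
  out <- stats::setNames(numeric(length(freqs)), freqs)
  if (stats::var(x) < .Machine$double.eps) return(out)
  fit <- stats::ar.burg(x, aic = FALSE, order.max = order,
                        demean = TRUE)
  a <- fit$ar
  ek <- exp(-2i * pi * outer(freqs, seq_len(order)) / fs)
  denom <- abs(1 - drop(ek %*% a))^2
  out[] <- fit$var.pred / denom
  out
}

#' ERD (spectral) features of one window
#'
#' Small-Laplacian-filters the trial, cuts the window `[t-1, t)`, and
#' computes per channel the AR(16) power spectrum at 1 Hz bins over
#' 7-30 Hz (24 bins covering the alpha and beta bands). With the
#' canonical 19-channel sensorimotor list this yields 456 features; an
#' optional ERD spatial filter contributes 24 more from its projected
#' virtual channel.
#'
#' @param trials A \linkS4class{TrialSet}.
#' @param trial trial index (default 1).
#' @param t window right edge, s (default 0).
#' @param channels ERD feature channels (default [erdChannels()]).
#' @param osf optional \linkS4class{SpatialFilter} (target "ERD").
#' @param bins spectral bins, Hz (default 7:30).
#' @param order AR order (default 16).
#' @return Named numeric feature vector.
#' @export
erdFeatures <- function(trials, trial = 1, t = 0,
                        channels = NULL, osf = NULL,
                        bins = 7:30, order = 16) {
  if (is.null(channels))
    channels <- intersect(erdChannels(), trials@channelLabels)
  sel <- trials@time >= (t - 1) & trials@time < t
  if (sum(sel) < 2 * order) stop("window truncated by trial edge")
  m <- trials@data[trial, , ]
  rownames(m) <- trials@channelLabels
  lap <- laplacianFilter(m)
  feats <- unlist(lapply(channels, function(ch) {
    sp <- arSpectrum(lap[ch, sel], trials@fs, bins, order)
    stats::setNames(sp, paste0("ERD.", ch, ".", bins, "Hz"))
  }))
  if (!is.null(osf)) {
    v <- applyFilter(m, osf)
    sp <- arSpectrum(v[sel], trials@fs, bins, order)
    feats <- c(feats, stats::setNames(sp, paste0("ERD.OSF.", bins, "Hz")))
  }
  feats
}

#' MRCP (temporal) features of one window
#'
#' CAR-filters the trial, subsamples it to 64 Hz (anti-aliased),
#' bandpass-filters to 0.1-1 Hz (zero-phase 2nd-order Butterworth), and
#' returns the 64 samples of the window `[t-1, t)` for each selected
#' channel (8 channels = 512 features); an optional MRCP spatial filter
#' contributes 64 more from its virtual channel.
#'
#' @inheritParams erdFeatures
#' @param channels MRCP feature channels (default [mrcpChannels()]).
#' @param osf optional \linkS4class{SpatialFilter} (target "MRCP").
#' @param fsTarget subsampling rate, Hz (default 64).
#' @param band slow-potential band, Hz pair (default `c(0.1, 1)`).
#' @return Named numeric feature vector.
#' @export
mrcpFeatures <- function(trials, trial = 1, t = 0, channels = NULL,
                         osf = NULL, fsTarget = 64, band = c(0.1, 1)) {
  if (is.null(channels))
    channels <- intersect(mrcpChannels(), trials@channelLabels)
  m <- trials@data[trial, , ]
  rownames(m) <- trials@channelLabels
  mc <- carFilter(m)
  factor <- round(trials@fs / fsTarget)
  idx64 <- seq(1, ncol(m), by = factor)
  time64 <- trials@time[idx64]
  sel <- time64 >= (t - 1) & time64 < t
  if (!any(sel)) stop("window truncated by trial edge")
  rows <- c(match(channels, rownames(m)))
  if (anyNA(rows)) stop("unknown MRCP channels")
  ds <- downsampleSignal(mc[rows, , drop = FALSE], trials@fs, fsTarget)
  filt <- bandpassZP(ds$data, fsTarget, band, order = 2)
  sampleIds <- seq_len(sum(sel))
  feats <- unlist(lapply(seq_along(channels), function(j) {
    stats::setNames(filt[j, sel],
                    paste0("MRCP.", channels[j], ".s", sampleIds))
  }))
  if (!is.null(osf)) {
    v <- applyFilter(m, osf)
    dv <- downsampleSignal(v, trials@fs, fsTarget)
    fv <- bandpassZP(dv$data, fsTarget, band, order = 2)
    feats <- c(feats,
               stats::setNames(fv[sel], paste0("MRCP.OSF.s", sampleIds)))
  }
  feats
}

#' Training window scheme
#'
#' Five rest windows with right edges at t = -2, -1.75, -1.5, -1.25, -1
#' (a 0.25 s sliding step through the rest interval) and one intention
#' window at t = 0 (the window `[-1, 0)` immediately preceding onset).
#'
#' @param restStep sliding step through rest, s (default 0.25).
#' @return data.frame with columns `t` and `label`.
#' @export
trainingWindows <- function(restStep = 0.25) {
  restT <- seq(-2, -1, by = restStep)
  data.frame(t = c(restT, 0),
             label = c(rep("rest", length(restT)), "intention"))
}

#' Test window scheme
#'
#' The sliding evaluation grid: unlabeled windows with right edges from
#' t = -2 to t = 0 in steps of 0.125 s (17 windows; windows with
#' t < -2 do not exist because a 1 s window needs data from -3 s).
#'
#' @param step sliding step, s (default 0.125).
#' @return data.frame with columns `t` and `label` ("unlabeled").
#' @export
testWindows <- function(step = 0.125) {
  tt <- seq(-2, 0, by = step)
  data.frame(t = tt, label = rep("unlabeled", length(tt)))
}

#' Fit feature normalization on training windows
#'
#' Per-feature mean and standard deviation from training windows only;
#' zero-variance features are flagged and later mapped to 0.
#'
#' @param X numeric matrix, windows x features.
#' @return A \linkS4class{NormalizationStats}.
#' @export
fitNormalization <- function(X) {
  stopifnot(is.matrix(X), nrow(X) >= 2)
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  zv <- sd < .Machine$double.eps
  sd[zv] <- 1
  new("NormalizationStats", mean = mu, sd = sd, zeroVar = zv)
}

#' Apply normalization statistics
#'
#' @param stats A \linkS4class{NormalizationStats} fitted on training
#'   windows.
#' @param X windows x features matrix (training or test).
#' @return Normalized matrix; zero-variance features are set to 0.
#' @export
applyNormalization <- function(stats, X) {
  Z <- sweep(sweep(X, 2, stats@mean), 2, stats@sd, "/")
  if (any(stats@zeroVar)) Z[, stats@zeroVar] <- 0
  Z
}

#' Feature index map
#'
#' Describes each position of the combined feature vector: kind (ERD /
#' MRCP, channel or OSF), channel, and spectral bin (Hz) or time sample
#' index. The closed-form length is
#' `length(bins) * (nErd + 1) + nMrcpSamples * (nMrcp + 1)` = 1056 with
#' the canonical 19 ERD and 8 MRCP channels.
#'
#' @param erdCh,mrcpCh channel lists.
#' @param bins ERD spectral bins (Hz).
#' @param nSamples MRCP samples per window (default 64).
#' @return data.frame with columns kind, channel, value (bin Hz or
#'   sample index).
#' @export
featureIndexMap <- function(erdCh = erdChannels(), mrcpCh = mrcpChannels(),
                            bins = 7:30, nSamples = 64) {
  rbind(
    data.frame(kind = "ERD",
               channel = rep(erdCh, each = length(bins)),
               value = rep(bins, length(erdCh))),
    data.frame(kind = "ERD", channel = "OSF", value = bins),
    data.frame(kind = "MRCP",
               channel = rep(mrcpCh, each = nSamples),
               value = rep(seq_len(nSamples), length(mrcpCh))),
    data.frame(kind = "MRCP", channel = "OSF", value = seq_len(nSamples))
  )
}
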