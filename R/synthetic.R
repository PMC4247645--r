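#' Specification of a synthetic EEG dataset with planted effects
#'
#' Defines the study conditions a synthetic recording emulates:
#' self-initiated trials separated by long rests, a contralateral
#' alpha/beta power decrease (ERD) beginning before movement onset, a slow
#' negative central potential (MRCP) peaking at onset, 1/f background
#' noise with 10/20 Hz rhythms, and a kinematic channel carrying one
#' movement burst per trial.
#'
#' @slot erdDepth fractional alpha/beta power change in (-1, 0]; -0.5
#'   plants a 50\% power decrease.
#' @slot erdChannel montage label where the ERD map peaks (e.g. "C3").
#' @slot erdLead seconds before onset at which the ERD begins.
#' @slot mrcpPeak negative MRCP peak amplitude in microvolts (<= 0).
#' @slot mrcpChannel montage label where the MRCP map peaks (e.g. "Cz").
#' @slot mrcpRamp MRCP rise time in seconds (fall is symmetric).
#' @slot bgExponent 1/f exponent of the background noise.
#' @slot noiseSd background noise standard deviation, microvolts.
#' @slot rhythmAmp named standard deviations (microvolts) of the
#'   narrowband `alpha` (7-12 Hz) and `beta` (15-25 Hz) rhythm processes
#'   at their source channel.
#' @slot nTrials number of trials.
#' @slot trialSpacing inter-onset spacing, s (>= 7 so every trial has a
#'   clean [-3, 3] epoch and >= 3 s rest).
#' @slot fs sampling frequency, Hz.
#' @slot seed RNG seed; identical specs generate identical recordings.
#' @slot artifactTrials trial indices receiving an injected amplitude
#'   artifact (for testing artifact rejection).
#'
#' @seealso [effectSpec()], [generateRecording()], [generateTrialSet()]
#' @export
setClass("EffectSpec",
  representation(
    erdDepth = "numeric", erdChannel = "character", erdLead = "numeric",
    mrcpPeak = "numeric", mrcpChannel = "character", mrcpRamp = "numeric",
    bgExponent = "numeric", noiseSd = "numeric", rhythmAmp = "numeric",
    nTrials = "numeric", trialSpacing = "numeric", fs = "numeric",
    seed = "numeric", artifactTrials = "numeric"
  )
)

setValidity("EffectSpec", function(object) {
  msg <- character(0)
  if (object@erdDepth <= -1 || object@erdDepth > 0)
    msg <- c(msg, "erdDepth must lie in (-1, 0]")
  if (object@mrcpPeak > 0)
    msg <- c(msg, "mrcpPeak must be <= 0 (a negativity)")
  if (object@trialSpacing < 7)
    msg <- c(msg, "trialSpacing must be >= 7 s for clean [-3,3] epochs")
  if (object@nTrials < 1) msg <- c(msg, "nTrials must be >= 1")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Create an EffectSpec
#'
#' Defaults are the package's reference study conditions: 50 self-initiated
#' trials 13 s apart at 512 Hz, ERD of -50\% at C3 starting 1 s before
#' onset, a -5 uV MRCP at Cz, 1/f background (sd 14 uV) and 10/20 Hz
#' rhythm processes of 40/16 uV at the sensorimotor sources.
#'
#' @param erdDepth,erdChannel,erdLead,mrcpPeak,mrcpChannel,mrcpRamp
#'   planted-effect parameters, see \linkS4class{EffectSpec}.
#' @param bgExponent,noiseSd,rhythmAmp background model parameters.
#' @param nTrials,trialSpacing,fs,seed,artifactTrials dataset structure.
#' @return An \linkS4class{EffectSpec}.
#' @export
#' @examples
#' spec <- effectSpec(nTrials = 5, seed = 1)
effectSpec <- function(erdDepth = -0.5, erdChannel = "C3", erdLead = 1,
                       mrcpPeak = -5, mrcpChannel = "Cz", mrcpRamp = 1.5,
                       bgExponent = 1, noiseSd = 14,
                       rhythmAmp = c(alpha = 40, beta = 16),
                       nTrials = 50, trialSpacing = 13, fs = 512,
                       seed = 1, artifactTrials = numeric(0)) {
  new("EffectSpec",
    erdDepth = erdDepth, erdChannel = erdChannel, erdLead = erdLead,
    mrcpPeak = mrcpPeak, mrcpChannel = mrcpChannel, mrcpRamp = mrcpRamp,
    bgExponent = bgExponent, noiseSd = noiseSd, rhythmAmp = rhythmAmp,
    nTrials = nTrials, trialSpacing = trialSpacing, fs = fs, seed = seed,
    artifactTrials = artifactTrials)
}

## 1/f^exponent Gaussian noise of length n, sd scaled to `sd`
.pinkNoise <- function(n, fs, exponent, sd) {
  nf <- stats::nextn(n, 2)
  freqs <- seq(0, fs / 2, length.out = nf / 2 + 1)
  shape <- c(0, 1 / pmax(freqs[-1], 0.1)^(exponent / 2))
  half <- complex(real = stats::rnorm(nf / 2 + 1),
                         imaginary = stats::rnorm(nf / 2 + 1)) * shape
  half[1] <- 0
  half[nf / 2 + 1] <- complex(real = Re(half[nf / 2 + 1]))
  spec <- c(half, Conj(rev(half[2:(nf / 2)])))
  x <- Re(stats::fft(spec, inverse = TRUE))[seq_len(n)]
  if (stats::sd(x) > 0) x <- x * sd / stats::sd(x)
  x
}

## Gaussian scalp map over 10/10 grid coordinates, peak 1 at `center`
.scalpMap <- function(labels, center, sigma = 0.8) {
  xy <- montageCoords(labels)
  c0 <- montageCoords(center)
  d2 <- (xy[, "x"] - c0[1, "x"])^2 + (xy[, "y"] - c0[1, "y"])^2
  g <- exp(-d2 / (2 * sigma^2))
  g[is.na(g)] <- 0
  g
}

## mirror a lateralized label across the midline (C3 -> C4); midline
## labels map to themselves
.mirrorLabel <- function(labels, center) {
  xy <- montageCoords(labels)
  c0 <- montageCoords(center)
  if (c0[1, "x"] == 0) return(center)
  d2 <- (xy[, "x"] + c0[1, "x"])^2 + (xy[, "y"] - c0[1, "y"])^2
  labels[which.min(d2)]
}

#' Generate a continuous synthetic EEG recording with known onsets
#'
#' Builds a 32-channel recording at `spec@fs` Hz containing 1/f background
#' noise, sensorimotor 10/20 Hz rhythms whose amplitude is attenuated by
#' `sqrt(1 + erdDepth)` from `onset - erdLead` to `onset + 1` (so band
#' power drops by `erdDepth`), a slow negativity ramping to `mrcpPeak` at
#' each onset, and a kinematic auxiliary channel with one rectified burst
#' per trial whose 5\%-of-maximum crossing falls at the true onset by
#' construction.
#'
#' @param spec An \linkS4class{EffectSpec}.
#' @return A list with elements `recording` (\linkS4class{EEGRecording})
#'   and `onsets` (numeric vector of true onset times, s).
#' @export
#' @examples
#' sim <- generateRecording(effectSpec(nTrials = 3, seed = 7))
#' sim$onsets
generateRecording <- function(spec) {
  validObject(spec)
  set.seed(spec@seed)
  fs <- spec@fs
  labels <- standardMontage()
  nCh <- length(labels)
  nTr <- as.integer(spec@nTrials)
  dur <- nTr * spec@trialSpacing + 4
  n <- round(dur * fs)
  tAx <- (seq_len(n) - 1) / fs

  ## self-initiated onsets: one per 13 s block, jittered
  onsets <- (seq_len(nTr) - 1) * spec@trialSpacing + 6 +
    stats::runif(nTr, -0.5, 0.5)

  data <- matrix(0, nCh, n)
  for (ch in seq_len(nCh))
    data[ch, ] <- .pinkNoise(n, fs, spec@bgExponent, spec@noiseSd)

  ## rhythm sources at the ERD channel and its mirrored counterpart;
  ## ERD (multiplicative envelope) applies at the lateralized source only
  erdEnv <- rep(1, n)
  att <- sqrt(1 + spec@erdDepth)
  ramp <- 0.25
  for (o in onsets) {
    i0 <- o - spec@erdLead; i1 <- o + 1
    seg <- tAx >= i0 - ramp & tAx <= i1 + ramp
    tt <- tAx[seg]
    e <- rep(att, length(tt))
    rIn <- tt < i0
    e[rIn] <- 1 + (att - 1) * 0.5 * (1 + cos(pi * (i0 - tt[rIn]) / ramp))
    rOut <- tt > i1
    e[rOut] <- 1 + (att - 1) * 0.5 * (1 + cos(pi * (tt[rOut] - i1) / ramp))
    erdEnv[seg] <- pmin(erdEnv[seg], e)
  }

  ## rhythm sources: narrowband Gaussian processes filling the alpha
  ## (6.5-13 Hz) and beta (14-26 Hz) bands, at the ERD channel and its
  ## mirrored counterpart; the ERD envelope multiplies the lateralized
  ## source only, so the planted band-power change is erdDepth exactly
  mirror <- .mirrorLabel(labels, spec@erdChannel)
  srcMain <- .scalpMap(labels, spec@erdChannel)
  srcMirr <- .scalpMap(labels, mirror)
  rhythmBands <- list(alpha = c(6.5, 13), beta = c(14, 26))
  for (bn in names(rhythmBands)) {
    amp <- spec@rhythmAmp[[bn]]
    if (amp == 0) next
    mk <- function() {
      r <- bandpassZP(stats::rnorm(n), fs, rhythmBands[[bn]])
      amp * r / stats::sd(r)
    }
    data <- data + (srcMain %o% (erdEnv * mk()))
    if (mirror != spec@erdChannel)
      data <- data + (srcMirr %o% mk())
  }

  ## MRCP: raised-cosine negativity peaking at each onset. The source is
  ## band-limited to the slow-potential band (0.1-1 Hz) and scaled so its
  ## filtered minimum equals mrcpPeak, and the scalp map is centered
  ## (CAR-invariant) with unit gain at the MRCP channel, so the standard
  ## CAR + 0.1-1 Hz measurement chain recovers the planted peak.
  if (spec@mrcpPeak < 0) {
    mrcpSrc <- rep(0, n)
    for (o in onsets) {
      seg <- abs(tAx - o) <= spec@mrcpRamp
      mrcpSrc[seg] <- mrcpSrc[seg] -
        0.5 * (1 + cos(pi * (tAx[seg] - o) / spec@mrcpRamp))
    }
    ## iterate the slow-potential bandpass to its fixed-point shape so
    ## one further pass (the measurement chain) leaves the peak intact
    for (i in 1:6) mrcpSrc <- bandpassZP(mrcpSrc, fs, c(0.1, 1), order = 2)
    ## scale by the typical per-onset minimum (repeated negativities sit
    ## on the highpass rebound of their predecessors, so the global
    ## minimum would overweight the first trial)
    localMin <- vapply(onsets, function(o)
      min(mrcpSrc[abs(tAx - o) <= 1]), 0)
    mrcpSrc <- mrcpSrc * abs(spec@mrcpPeak) /
      abs(stats::median(localMin))
    g <- .scalpMap(labels, spec@mrcpChannel)
    g <- g - mean(g)
    g <- g / g[match(spec@mrcpChannel, labels)]
    data <- data + (g %o% mrcpSrc)
  }

  ## amplitude artifact injection (optional, for rejection tests)
  for (k in spec@artifactTrials) {
    if (k < 1 || k > nTr) next
    seg <- tAx >= onsets[k] - 2 & tAx <= onsets[k] + 1
    data[, seg] <- data[, seg] + 8 * spec@noiseSd *
      sin(2 * pi * 2 * tAx[seg])
  }

  ## kinematic channel: rectified Gaussian burst of ~0.5 s per onset whose
  ## 5% crossing sits at the onset (crossing at 2.448 sd before center)
  sdK <- 0.102
  kin <- stats::rnorm(n, 0, 0.004)
  for (o in onsets) {
    seg <- abs(tAx - (o + 0.25)) <= 0.5
    kin[seg] <- kin[seg] + exp(-(tAx[seg] - (o + 0.25))^2 / (2 * sdK^2))
  }
  kin <- abs(kin)

  rec <- new("EEGRecording", data = data, fs = fs, channelLabels = labels,
    aux = list(kinematic = list(data = kin, fs = fs)),
    annotations = data.frame(time = onsets,
                             label = rep("true_onset", nTr)))
  list(recording = rec, onsets = onsets)
}

#' Generate a TrialSet aligned to the true onsets
#'
#' Convenience for unit-testing downstream stages: epochs the synthetic
#' recording on the exact planted onsets, bypassing kinematic onset
#' detection.
#'
#' @param spec An \linkS4class{EffectSpec}.
#' @param window epoch window in s relative to onset (default `c(-3, 3)`).
#' @return A \linkS4class{TrialSet} with one epoch per planted onset.
#' @export
#' @examples
#' ts <- generateTrialSet(effectSpec(nTrials = 4, seed = 2))
#' nTrials(ts)
generateTrialSet <- function(spec, window = c(-3, 3)) {
  sim <- generateRecording(spec)
  epochTrials(sim$recording, sim$onsets, window = window,
              movement = "synthetic")
}
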