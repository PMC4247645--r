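## Shared filtering primitives. All temporal filters in the pipeline are
## zero-phase Butterworth (forward-backward), matching the offline design;
## phase distortion would shift MRCP peaks and ERD onsets.

## zero-phase Butterworth bandpass applied along rows of a matrix
## (channels x samples) or to a vector
bandpassZP <- function(x, fs, band, order = 4) {
  lo <- band[1] / (fs / 2)
  hi <- band[2] / (fs / 2)
  if (hi >= 1) hi <- 0.999
  bf <- signal::butter(order, c(lo, hi), type = "pass")
  applyFiltfilt(x, bf)
}

lowpassZP <- function(x, fs, cutoff, order = 4) {
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  applyFiltfilt(x, bf)
}

applyFiltfilt <- function(x, bf) {
  if (is.matrix(x)) {
    t(apply(x, 1, function(r) signal::filtfilt(bf, r)))
  } else {
    signal::filtfilt(bf, x)
  }
}

## anti-aliased integer-factor downsampling; returns list(data, fs)
downsampleSignal <- function(x, fs, fsNew) {
  stopifnot(fsNew < fs)
  factor <- fs / fsNew
  if (abs(factor - round(factor)) > 1e-9)
    warning("fs not an integer multiple of target rate; using nearest grid")
  factor <- round(factor)
  y <- lowpassZP(x, fs, 0.4 * fsNew, order = 4)
  idx <- seq(1, if (is.matrix(x)) ncol(x) else length(x), by = factor)
  if (is.matrix(y)) list(data = y[, idx, drop = FALSE], fs = fsNew)
  else list(data = y[idx], fs = fsNew)
}

## mean squared amplitude in a frequency band (per row if matrix)
bandPower <- function(x, fs, band, order = 4) {
  y <- bandpassZP(x, fs, band, order = order)
  if (is.matrix(y)) rowMeans(y^2) else mean(y^2)
}

## Complex Morlet wavelet power via FFT convolution with reflection
## padding (trials are short relative to low-frequency wavelets).
## x: vector; returns power at each sample for each freq (freqs x samples).
morletPower <- function(x, fs, freqs, cycles = 7) {
  n <- length(x)
  pad <- n  # reflect a full trial on each side
  xp <- c(rev(x[seq_len(pad)]), x, rev(x[seq(n - pad + 1, n)]))
  np <- length(xp)
  nfft <- stats::nextn(np + ceiling(cycles * fs / min(freqs)), 2)
  X <- stats::fft(c(xp, rep(0, nfft - np)))
  out <- matrix(0, length(freqs), n)
  for (k in seq_along(freqs)) {
    f <- freqs[k]
    sdT <- cycles / (2 * pi * f)
    half <- ceiling(3.5 * sdT * fs)
    tt <- seq(-half, half) / fs
    w <- exp(2i * pi * f * tt) * exp(-tt^2 / (2 * sdT^2))
    w <- w / sqrt(sum(abs(w)^2))
    W <- stats::fft(c(w, rep(0, nfft - length(w))))
    conv <- stats::fft(X * W, inverse = TRUE) / nfft
    ## alignment: convolution center lag = half samples into the product
    sel <- pad + half + seq_len(n)
    out[k, ] <- abs(conv[sel])^2
  }
  out
}
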