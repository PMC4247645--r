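test_that("the ERD map baseline averages to zero by construction", {
  ts <- fixture("small12")
  lap <- laplacianFilter(ts)
  m <- erdMap(lap, "C3", freqs = c(8, 10, 12))
  bSel <- m@times >= -3 & m@times < -1
  expect_lt(max(abs(rowMeans(m@values[, bSel]))), 1e-9)
  expect_equal(dim(m@values), c(3, length(m@times)))
  expect_error(erdMap(laplacianFilter(generateTrialSet(
    effectSpec(nTrials = 4, seed = 1))), "C3"), "at least 5")
})

test_that("stationary noise yields a near-flat percent-change map", {
  ## per-cell % change has relative standard error ~1/sqrt(nTrials), so
  ## the 15% bound on the 95th percentile needs study-scale replication.
  ## Judged over the oscillatory analysis range (>= 10 Hz) and away from
  ## the wavelet cone of influence at the trial edges: below ~10 Hz a
  ## 2 s baseline holds too few wavelet-independent samples for the
  ## percent-change cells to concentrate, at any realistic trial count.
  ts <- fixture("null200")
  lap <- laplacianFilter(ts)
  m <- erdMap(lap, "C3", freqs = seq(10, 45, by = 5))
  interior <- m@times >= -2.3 & m@times <= 2.3
  expect_lt(unname(quantile(abs(m@values[, interior]), 0.95)), 15)
})

test_that("ERD percentages are invariant to a common gain", {
  ts <- fixture("small12")
  scaled <- ts
  scaled@data <- ts@data * 7.3
  m1 <- erdMap(laplacianFilter(ts), "C3", freqs = c(10, 20))
  m2 <- erdMap(laplacianFilter(scaled), "C3", freqs = c(10, 20))
  expect_equal(m1@values, m2@values, tolerance = 1e-9)
})

test_that("premovementERD summarizes the band and window correctly", {
  vals <- matrix(-30, 6, 20)
  m <- new("TimeFreqMap", values = vals, freqs = 7:12,
           times = seq(-2.9, 0.9, length.out = 20), channel = "C3")
  expect_equal(premovementERD(m, "alpha"), -30)
  ## 12 Hz sits in both alpha and beta, so beta still overlaps this map
  expect_equal(premovementERD(m, "beta"), -30)
  expect_error(premovementERD(m, band = c(31, 40)), "band")
  expect_error(premovementERD(m, "gamma"), "unknown band")
})

test_that("bootstrap significance is calibrated under the null", {
  ts <- fixture("null50")
  lap <- laplacianFilter(ts)
  m <- bootstrapMask(lap, "C3", alpha = 0.05, B = 400,
                     freqs = seq(6, 30, by = 4), seed = 2)
  frac <- mean(m@mask)
  expect_lt(abs(frac - 0.05), 0.03)
})

test_that("bootstrap flags the planted ERD region and alpha = 1 flags all", {
  ts <- fixture("strong200")
  lap <- laplacianFilter(ts)
  m <- bootstrapMask(lap, "C3", alpha = 0.05, B = 200,
                     freqs = 8:11, seed = 3)
  reg <- m@mask[, m@times >= -0.75 & m@times < 0]
  expect_gte(mean(reg), 0.9)

  small <- fixture("small12")
  expect_warning(
    mAll <- bootstrapMask(laplacianFilter(small), "C3", alpha = 1,
                          B = 50, freqs = c(10, 20), seed = 1),
    "unreliable")
  expect_true(all(mAll@mask))
})

test_that("MRCP waveforms are band-limited and normalized by definition", {
  ## band limitation is a property of the averaged waveform; at small n
  ## residual broadband noise dominates, so check at study scale
  ts <- fixture("strong200")
  w <- mrcpWaveform(ts)
  expect_equal(w@channelLabels, intersect(mrcpChannels(),
                                          ts@channelLabels))
  ## band limitation: spectral mass above 2 Hz below 1% of total, on
  ## the channels actually carrying the potential (low-signal channels
  ## are residual-noise-dominated and the ratio is uninformative there)
  carrying <- which(abs(w@peakAmplitude) >= 0.5 * max(abs(w@peakAmplitude)))
  expect_gte(length(carrying), 3)
  for (j in carrying) {
    sp <- Mod(fft(w@waveforms[j, ]))^2
    fr <- seq(0, 63, length.out = length(sp) + 1)[seq_along(sp)]
    hi <- sum(sp[fr > 2 & fr < 62])
    expect_lt(hi / sum(sp[-1]), 0.01)
  }

  ## normalization maps the largest-amplitude movement to exactly -1
  ts2 <- fixture("null50")
  wl <- normalizeMrcp(list(strong = w, weak = mrcpWaveform(ts2)))
  peaks <- vapply(wl, function(x)
    x@peakAmplitude[match("Cz", x@channelLabels)], 0)
  expect_equal(min(peaks), -1)
  expect_true(all(peaks >= -1))
})

test_that("decimate-then-filter agrees with filter-then-decimate", {
  ## anti-aliasing adequacy for the 0.1-1 Hz band, judged away from the
  ## filter edge transients of the finite record
  set.seed(4)
  fs <- 512
  x <- matrix(cumsum(rnorm(fs * 60)), 1)
  a <- movintent:::bandpassZP(
    movintent:::downsampleSignal(x, fs, 64)$data, 64, c(0.1, 1),
    order = 2)
  bFull <- movintent:::bandpassZP(x, fs, c(0.1, 1), order = 2)
  b <- bFull[, seq(1, ncol(x), by = 8)]
  core <- seq(round(length(b) * 0.1), round(length(b) * 0.9))
  rel <- sqrt(mean((a[core] - b[core])^2)) / sqrt(mean(b[core]^2))
  expect_lt(rel, 0.02)
})
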