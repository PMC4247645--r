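test_that("onset detection matches a brute-force threshold scan", {
  fs <- 128
  t <- seq(0, 20, by = 1 / fs)
  bump <- exp(-(t - 7.8)^2 / (2 * 0.1^2))
  det <- detectOnsets(bump, fs)
  ## oracle: direct scan of the demeaned, rectified signal
  proc <- abs(bump - mean(bump))
  first <- which(proc >= 0.05 * max(proc))[1]
  expect_length(det, 1)
  expect_equal(det, (first - 1) / fs)

  two <- bump + exp(-(t - 12.8)^2 / (2 * 0.1^2))
  det2 <- detectOnsets(two, fs)
  expect_length(det2, 2)
  expect_lt(abs(diff(det2) - 5), 2 / fs + 1e-9)
})

test_that("degenerate onset inputs are handled", {
  expect_warning(det <- detectOnsets(rep(0, 100), 128), "zero")
  expect_length(det, 0)
  expect_error(detectOnsets(rnorm(100), 128, fraction = 0))
  expect_error(detectOnsets(rnorm(100), 128, fraction = 1.5))
})

test_that("epoching cuts the documented sample windows and drops bad onsets", {
  fs <- 128
  rec <- new("EEGRecording",
    data = matrix(seq_len(2 * 20 * fs), nrow = 2, byrow = TRUE),
    fs = fs, channelLabels = c("C3", "C4"))
  ts <- epochTrials(rec, onsets = 10, auxChannel = NULL)
  ## epoch covers [7 s, 13 s): samples 897..1664 of the recording
  expect_equal(dim(ts@data)[3], 6 * fs)
  expect_equal(ts@data[1, 1, 1], rec@data[1, 7 * fs + 1])
  expect_equal(ts@data[1, 1, 6 * fs], rec@data[1, 13 * fs])

  ts2 <- epochTrials(rec, onsets = c(2, 10), auxChannel = NULL)
  expect_equal(nTrials(ts2), 1)
  dropped <- ts2@metadata$droppedOnsets
  expect_length(dropped, 1)
  expect_match(dropped[[1]]$reason, "pre-onset data")

  ## an onset 2 s after its predecessor violates the 3 s rest rule
  ts3 <- epochTrials(rec, onsets = c(8, 10), auxChannel = NULL)
  expect_equal(nTrials(ts3), 1)
  expect_match(ts3@metadata$droppedOnsets[[1]]$reason, "rest")
})

test_that("synthetic onsets epoch cleanly with the burst at t = 0", {
  sim <- generateRecording(effectSpec(nTrials = 10, seed = 6))
  det <- detectOnsets(matrix(sim$recording@aux$kinematic$data, 1), 512)
  ts <- epochTrials(sim$recording, det)
  expect_equal(nTrials(ts), 10)
  ## the epoched kinematic channel crosses 5% of its max near t = 0
  for (k in seq_len(10)) {
    kin <- ts@auxEpochs[k, ]
    on <- trialTime(ts)[which(kin >= 0.05 * max(kin))[1]]
    expect_lt(abs(on), 0.05)
  }
})

test_that("artifact rejection implements the multiplier-of-mean rule", {
  fs <- 128
  time <- -3 + (seq_len(6 * fs) - 1) / fs
  mk <- function(scales) {
    set.seed(42)
    base <- array(rnorm(2 * 6 * fs), c(1, 2, 6 * fs))
    dat <- array(0, c(length(scales), 2, 6 * fs))
    for (k in seq_along(scales)) dat[k, , ] <- base[1, , ] * scales[k]
    new("TrialSet", data = dat, time = time, fs = fs,
        channelLabels = c("C3", "C4"), kept = rep(TRUE, length(scales)),
        rejectReasons = rep("", length(scales)))
  }
  ## identical trials: every measure equals its mean, 1 < 2.5
  expect_equal(sum(!rejectArtifacts(mk(rep(1, 5)))@kept), 0)

  ## one trial scaled x10: its variance is ~100x the others, the mean is
  ## ~(4 + 100)/5 = 20.8, ratio ~4.8 > 2.5 -> exactly that trial goes
  out <- rejectArtifacts(mk(c(1, 1, 1, 1, 10)))
  expect_identical(which(!out@kept), 5L)
  expect_match(out@rejectReasons[5], "artifact")

  ## degenerate threshold rejects nothing
  expect_equal(sum(!rejectArtifacts(mk(c(1, 1, 1, 1, 10)),
                                    multiplier = Inf)@kept), 0)
  expect_error(rejectArtifacts(mk(c(1, 1))), "at least 3")
})

test_that("rejection is invariant to trial order and global rescaling", {
  ts <- fixture("small12")
  ref <- rejectArtifacts(ts)

  scaled <- ts
  scaled@data <- ts@data * 3.7
  expect_identical(rejectArtifacts(scaled)@kept, ref@kept)

  perm <- sample(nTrials(ts))
  shuffled <- ts
  shuffled@data <- ts@data[perm, , , drop = FALSE]
  shuffled@kept <- ts@kept[perm]
  shuffled@rejectReasons <- ts@rejectReasons[perm]
  expect_identical(rejectArtifacts(shuffled)@kept[order(perm)],
                   ref@kept)
})

test_that("the injected amplitude artifact is caught", {
  ts <- generateTrialSet(effectSpec(nTrials = 10, seed = 8,
                                    artifactTrials = 4))
  out <- rejectArtifacts(ts)
  expect_false(out@kept[4])
  expect_equal(sum(!out@kept), 1)
})
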