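mkTrials <- function(dat, fs = 128, labels = NULL) {
  d <- dim(dat)
  if (is.null(labels)) labels <- standardMontage()[seq_len(d[2])]
  new("TrialSet", data = dat, time = -3 + (seq_len(d[3]) - 1) / fs,
      fs = fs, channelLabels = labels, kept = rep(TRUE, d[1]),
      rejectReasons = rep("", d[1]))
}

test_that("common average referencing removes the channel mean exactly", {
  x <- matrix(rep(rnorm(100), 3), nrow = 3, byrow = TRUE)
  expect_equal(carFilter(x), x * 0)

  ab <- rbind(a = rnorm(50), b = rnorm(50))
  expect_equal(carFilter(ab)[1, ], (ab[1, ] - ab[2, ]) / 2)
  expect_equal(carFilter(ab)[2, ], (ab[2, ] - ab[1, ]) / 2)

  big <- matrix(rnorm(32 * 200), 32)
  expect_lt(max(abs(colSums(carFilter(big)))), 1e-9)
  expect_error(carFilter(matrix(1, 1, 10)), "2 channels")
})

test_that("small Laplacian equals brute-force neighbour-mean subtraction", {
  labels <- standardMontage()
  ## uniform field: zero at fully-neighboured channels
  u <- matrix(1, 32, 50, dimnames = list(labels, NULL))
  lap <- laplacianFilter(u)
  expect_equal(unname(lap["C3", ]), rep(0, 50))
  expect_equal(unname(lap["Cz", ]), rep(0, 50))

  ## C3 = s with silent neighbours passes through
  z <- matrix(0, 32, 50, dimnames = list(labels, NULL))
  s <- rnorm(50)
  z["C3", ] <- s
  expect_equal(unname(laplacianFilter(z)["C3", ]), s)

  ## random field vs table-lookup oracle
  r <- matrix(rnorm(32 * 64), 32, dimnames = list(labels, NULL))
  lapR <- laplacianFilter(r)
  nb <- montageNeighbors(labels)
  for (ch in c("C3", "AFz", "P2", "FC6")) {
    expected <- r[ch, ]
    if (length(nb[[ch]]))
      expected <- expected - colMeans(r[nb[[ch]], , drop = FALSE])
    expect_equal(unname(lapR[ch, ]), unname(expected))
  }
  expect_error(laplacianFilter(matrix(0, 2, 5,
    dimnames = list(c("C3", "XX9"), NULL))), "XX9")
})

test_that("snrDb implements the mean per-epoch log power ratio", {
  ## identical signal and noise epochs: 0 dB
  C <- crossprod(matrix(rnorm(16), 4))
  prob <- list(sigCov = list(C), noiseCov = list(C),
               labels = letters[1:4], L = 1)
  expect_equal(snrDb(rnorm(4), prob), 0)

  ## hand example: w = (1, -1), ch1 signal [2,2] / noise [1,1], ch2 zero
  prob2 <- list(sigCov = list(diag(c(4, 0))),
                noiseCov = list(diag(c(1, 0))),
                labels = c("a", "b"), L = 1)
  expect_equal(snrDb(c(1, -1), prob2), 10 * log10(4), tolerance = 1e-9)

  ## scale invariance of the power ratio
  w <- rnorm(4)
  prob3 <- list(sigCov = list(crossprod(matrix(rnorm(16), 4))),
                noiseCov = list(crossprod(matrix(rnorm(16), 4)) +
                                diag(4)),
                labels = letters[1:4], L = 1)
  expect_equal(snrDb(2 * w, prob3), snrDb(w, prob3))
  prob4 <- prob3
  prob4$noiseCov <- list(matrix(0, 4, 4))
  expect_error(snrDb(w, prob4), "degenerate")
})

test_that("the CAR-for-channel init vector sums to zero", {
  w <- carVector(standardMontage(), "Cz")
  expect_lt(abs(sum(w)), 1e-12)
  expect_equal(unname(w["Cz"]), 1 - 1 / 32)
  expect_equal(unname(w["C3"]), -1 / 32)
})

test_that("OSF optimization improves monotonically from the CAR start", {
  ts <- fixture("small12")
  fE <- fitOSF(ts, "ERD")
  expect_lte(fE@snrAchieved, fE@snrInit)
  expect_lt(abs(sum(filterWeights(fE))), 1e-8)
  fM <- fitOSF(ts, "MRCP")
  expect_gte(fM@snrAchieved, fM@snrInit)
  expect_lt(abs(sum(filterWeights(fM))), 1e-8)
})

test_that("OSF finds a channel-localized burst and matches a grid search", {
  ## 8-channel toy: a 15 Hz burst planted only in channel 3's signal
  ## window
  set.seed(10)
  fs <- 128
  nS <- 6 * fs
  time <- -3 + (seq_len(nS) - 1) / fs
  dat <- array(rnorm(8 * 8 * nS, sd = 1), c(8, 8, nS))
  burst <- 6 * sin(2 * pi * 15 * time) * (time >= -1 & time < 1)
  for (k in 1:8) dat[k, 3, ] <- dat[k, 3, ] + burst
  labels <- c("F3", "Fz", "F4", "C3", "Cz", "C4", "P3", "Pz")
  ts <- mkTrials(dat, fs, labels)
  f <- fitOSF(ts, "MRCP", band = c(10, 20), initChannel = "Fz")
  expect_equal(which.max(abs(filterWeights(f))), 3L,
               ignore_attr = TRUE)

  ## 3-channel reduction: achieved SNR within 0.5 dB of a coarse grid
  ## search over sum-zero weight vectors
  ts3 <- mkTrials(dat[, 1:3, , drop = FALSE], fs, labels[1:3])
  prob <- osfProblem(ts3, band = c(10, 20))
  f3 <- fitOSFProblem(prob, "MRCP", "Fz")
  grid <- seq(-1, 1, by = 0.05)
  best <- -Inf
  for (a in grid) for (b in grid) {
    w <- c(a, b, -a - b)
    if (sum(abs(w)) < 1e-6) next
    best <- max(best, snrDb(w, prob))
  }
  expect_lt(abs(f3@snrAchieved - best), 0.5)
})

test_that("filter application is an exact per-sample projection", {
  ts <- fixture("small12")
  labels <- ts@channelLabels
  oneHot <- rep(0, 32); names(oneHot) <- labels; oneHot["C3"] <- 1
  ## one-hot weights copy the channel (not sum-zero, so apply directly)
  v <- applyFilter(ts, oneHot)
  expect_equal(v[2, ], ts@data[2, match("C3", labels), ])

  ## CAR-for-Cz weights reproduce Cz after CAR
  vCz <- applyFilter(ts, carVector(labels, "Cz"))
  carTs <- carFilter(ts)
  expect_equal(vCz[1, ], carTs@data[1, match("Cz", labels), ],
               tolerance = 1e-9)

  ## random weights match the explicit dot product
  w <- rnorm(32); names(w) <- labels
  vr <- applyFilter(ts, w)
  expect_equal(vr[3, 100], sum(w * ts@data[3, , 100]))

  ## sum-zero filters ignore a common offset on every channel
  f <- fitOSF(ts, "MRCP")
  shifted <- ts
  shifted@data <- ts@data + 42
  expect_equal(applyFilter(shifted, f), applyFilter(ts, f),
               tolerance = 1e-6)
})
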