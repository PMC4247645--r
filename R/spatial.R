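#' Common average reference
#'
#' Subtracts the instantaneous mean over channels from every channel, so
#' the per-sample channel sum of the output is zero.
#'
#' @param x A \linkS4class{TrialSet} or a channels x samples matrix.
#' @return Object of the same kind, CAR-filtered.
#' @export
carFilter <- function(x) {
  if (is(x, "TrialSet")) {
    if (length(x@channelLabels) < 2) stop("CAR needs at least 2 channels")
    out <- x
    for (k in seq_len(dim(x@data)[1]))
      out@data[k, , ] <- carFilter(x@data[k, , ])
    return(out)
  }
  if (nrow(x) < 2) stop("CAR needs at least 2 channels")
  sweep(x, 2, colMeans(x))
}

#' Small Laplacian spatial filter
#'
#' Each channel minus the mean of its available nearest neighbours
#' (the orthogonally adjacent 10/10 electrodes); channels without any
#' neighbour in the montage are passed through unchanged and flagged.
#'
#' @param x A \linkS4class{TrialSet} or channels x samples matrix with
#'   rownames set to channel labels.
#' @param neighbors named list of neighbour sets, as produced by
#'   [montageNeighbors()]; defaults to the montage of `x`.
#' @return Same kind as `x`, Laplacian-filtered. For a TrialSet the
#'   pass-through channels are listed in `metadata$laplacianPassthrough`.
#' @export
laplacianFilter <- function(x, neighbors = NULL) {
  if (is(x, "TrialSet")) {
    if (is.null(neighbors)) neighbors <- montageNeighbors(x@channelLabels)
    out <- x
    for (k in seq_len(dim(x@data)[1])) {
      m <- x@data[k, , ]
      rownames(m) <- x@channelLabels
      out@data[k, , ] <- .laplacianMatrix(m, neighbors)
    }
    out@metadata$laplacianPassthrough <-
      x@channelLabels[!vapply(x@channelLabels, function(ch) {
        length(intersect(neighbors[[ch]], x@channelLabels)) > 0
      }, logical(1))]
    return(out)
  }
  if (is.null(neighbors)) neighbors <- montageNeighbors(rownames(x))
  .laplacianMatrix(x, neighbors)
}

.laplacianMatrix <- function(m, neighbors) {
  labels <- rownames(m)
  if (is.null(labels)) stop("matrix input needs channel rownames")
  unknown <- setdiff(labels, names(neighbors))
  ## labels that do not resolve to a 10/10 grid position are unknown to
  ## the montage, not merely isolated
  unknown <- union(unknown,
                   labels[is.na(montageCoords(labels)[, "x"])])
  if (length(unknown))
    stop("channels missing from montage: ", paste(unknown, collapse = ", "))
  out <- m
  for (ch in labels) {
    nb <- intersect(neighbors[[ch]], labels)
    if (length(nb))
      out[ch, ] <- m[ch, ] - colMeans(m[nb, , drop = FALSE])
  }
  out
}

#' Build an optimal-spatial-filter problem
#'
#' Band-filters each kept trial (zero-phase 4th-order Butterworth), cuts
#' the signal window (default [-1, 1] s, the peri-onset interval of
#' interest) and the noise window (default [-3, -1] s, rest), and stores
#' the per-epoch channel covariances from which projected powers are
#' evaluated.
#'
#' @param trials A \linkS4class{TrialSet}.
#' @param band frequency band, Hz pair (e.g. `c(0.1, 1)` for MRCP,
#'   `c(7, 30)` for ERD).
#' @param signalWindow,noiseWindow time windows, s pairs.
#' @return A list with per-epoch signal/noise covariance matrices
#'   (`sigCov`, `noiseCov`), `labels`, and `L` (number of epochs).
#' @export
osfProblem <- function(trials, band, signalWindow = c(-1, 1),
                       noiseWindow = c(-3, -1)) {
  stopifnot(is(trials, "TrialSet"))
  idx <- which(trials@kept)
  tAx <- trials@time
  sSel <- tAx >= signalWindow[1] & tAx < signalWindow[2]
  nSel <- tAx >= noiseWindow[1] & tAx < noiseWindow[2]
  if (!any(sSel) || !any(nSel)) stop("windows outside the trial axis")
  sigCov <- vector("list", length(idx))
  noiseCov <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    x <- bandpassZP(trials@data[idx[k], , ], trials@fs, band)
    s <- x[, sSel, drop = FALSE]
    q <- x[, nSel, drop = FALSE]
    sigCov[[k]] <- tcrossprod(s) / ncol(s)
    noiseCov[[k]] <- tcrossprod(q) / ncol(q)
  }
  list(sigCov = sigCov, noiseCov = noiseCov,
       labels = trials@channelLabels, L = length(idx))
}

#' Mean per-epoch SNR of a spatially filtered signal, in dB
#'
#' For weights `w`, the power of epoch i is the mean squared amplitude of
#' the projected signal, i.e. `w' C_i w` with `C_i` the epoch covariance;
#' the SNR is the mean over epochs of `10 log10(P_Si / P_Ni)`.
#'
#' @param w numeric weight vector (length = channel count).
#' @param problem as returned by [osfProblem()].
#' @return SNR in dB.
#' @export
snrDb <- function(w, problem) {
  stopifnot(length(w) == nrow(problem$sigCov[[1]]))
  tot <- 0
  for (i in seq_len(problem$L)) {
    ps <- drop(crossprod(w, problem$sigCov[[i]] %*% w))
    pn <- drop(crossprod(w, problem$noiseCov[[i]] %*% w))
    if (pn <= 0) stop("degenerate noise epoch (zero power)")
    tot <- tot + 10 * log10(ps / pn)
  }
  tot / problem$L
}

.snrGrad <- function(w, problem) {
  g <- numeric(length(w))
  for (i in seq_len(problem$L)) {
    aw <- problem$sigCov[[i]] %*% w
    bw <- problem$noiseCov[[i]] %*% w
    g <- g + drop(aw) / drop(crossprod(w, aw)) -
             drop(bw) / drop(crossprod(w, bw))
  }
  (20 / (problem$L * log(10))) * g
}

## orthonormal basis of the sum-zero subspace
.sumZeroBasis <- function(c) {
  qr.Q(qr(matrix(1, c, 1)), complete = TRUE)[, -1, drop = FALSE]
}

#' CAR-for-channel initialization vector
#'
#' The weight vector `1 - 1/c` at the anchor channel and `-1/c`
#' elsewhere: projecting with it reproduces the anchor channel after
#' common average referencing, and its weights sum to zero.
#'
#' @param labels channel labels.
#' @param channel anchor channel name.
#' @return Named numeric vector.
#' @export
carVector <- function(labels, channel) {
  stopifnot(channel %in% labels)
  c <- length(labels)
  w <- rep(-1 / c, c)
  names(w) <- labels
  w[channel] <- 1 - 1 / c
  w
}

#' Fit an SNR-optimal spatial filter
#'
#' Optimizes the mean per-epoch SNR (dB) of the projected signal under
#' the equality constraint that the weights sum to zero. For MRCP the
#' SNR is maximized (a large peri-onset slow potential against quiet
#' rest); for ERD it is minimized (oscillatory power decreases before
#' movement). The search starts from the CAR-for-channel vector (Cz for
#' MRCP, C3 for ERD by default) and the constraint is eliminated exactly
#' by optimizing in an orthonormal basis of the sum-zero subspace
#' (BFGS with analytic gradient). The returned weights are unit-norm
#' (the SNR is scale-invariant; normalization only stabilizes weight
#' maps for display).
#'
#' @param trials A \linkS4class{TrialSet} with at least 5 kept trials.
#' @param target `"ERD"` or `"MRCP"`.
#' @param band frequency band; defaults to `c(7, 30)` Hz for ERD and
#'   `c(0.1, 1)` Hz for MRCP.
#' @param initChannel anchor channel of the initial CAR filter; defaults
#'   to "C3" (ERD) or "Cz" (MRCP).
#' @param signalWindow,noiseWindow passed to [osfProblem()].
#' @param maxit,tol optimizer budget and relative objective tolerance.
#' @return A \linkS4class{SpatialFilter}. If the optimizer fails to
#'   improve on the start point the initial filter is returned with
#'   `converged = FALSE` and a warning.
#' @export
fitOSF <- function(trials, target = c("ERD", "MRCP"), band = NULL,
                   initChannel = NULL, signalWindow = c(-1, 1),
                   noiseWindow = c(-3, -1), maxit = 500, tol = 1e-6) {
  target <- match.arg(target)
  if (sum(trials@kept) < 5) stop("fitOSF needs at least 5 kept trials")
  if (is.null(band)) band <- if (target == "ERD") c(7, 30) else c(0.1, 1)
  if (is.null(initChannel))
    initChannel <- if (target == "ERD") "C3" else "Cz"
  problem <- osfProblem(trials, band, signalWindow, noiseWindow)
  fitOSFProblem(problem, target, initChannel, maxit = maxit, tol = tol)
}

#' @rdname fitOSF
#' @param problem a prebuilt [osfProblem()] (lower-level entry point used
#'   by the cross-validation driver to avoid refiltering).
#' @export
fitOSFProblem <- function(problem, target = c("ERD", "MRCP"),
                          initChannel, maxit = 500, tol = 1e-6) {
  target <- match.arg(target)
  labels <- problem$labels
  c <- length(labels)
  B <- .sumZeroBasis(c)
  w0 <- carVector(labels, initChannel)
  z0 <- drop(crossprod(B, w0))
  sgn <- if (target == "MRCP") -1 else 1  # optim minimizes
  fn <- function(z) sgn * snrDb(drop(B %*% z), problem)
  gr <- function(z) sgn * drop(crossprod(B, .snrGrad(drop(B %*% z),
                                                     problem)))
  initVal <- fn(z0)
  opt <- tryCatch(
    stats::optim(z0, fn, gr, method = "BFGS",
                 control = list(maxit = maxit, reltol = tol)),
    error = function(e) NULL)
  converged <- !is.null(opt) && is.finite(opt$value) &&
    opt$value <= initVal + 1e-12
  if (!converged) {
    warning("OSF optimization failed to improve; returning init filter")
    w <- w0; achieved <- sgn * initVal
  } else {
    w <- drop(B %*% opt$par)
    achieved <- sgn * opt$value
  }
  w <- w - mean(w)           # numerical cleanup of the constraint
  w <- w / sqrt(sum(w^2))
  names(w) <- labels
  new("SpatialFilter", weights = w, target = target,
      snrAchieved = achieved, snrInit = sgn * initVal,
      converged = converged)
}

#' Project trials through a spatial filter
#'
#' Computes the per-sample linear combination `w . x` of all channels,
#' yielding one virtual-channel time course per trial.
#'
#' @param trials A \linkS4class{TrialSet} or a channels x samples matrix
#'   (rownames = labels).
#' @param filter A \linkS4class{SpatialFilter} (or a named weight
#'   vector).
#' @return trials x samples matrix (or a vector for matrix input).
#' @export
applyFilter <- function(trials, filter) {
  w <- if (is(filter, "SpatialFilter")) filter@weights else filter
  if (is(trials, "TrialSet")) {
    if (!identical(names(w), trials@channelLabels))
      stop("filter channels do not match trial channels")
    d <- dim(trials@data)
    out <- matrix(0, d[1], d[3])
    for (k in seq_len(d[1])) out[k, ] <- drop(w %*% trials@data[k, , ])
    return(out)
  }
  if (!identical(names(w), rownames(trials)))
    stop("filter channels do not match matrix rownames")
  drop(w %*% trials)
}
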