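## 10/10 montage geometry used throughout the package.
##
## Channels live on a regular grid: rows are the sagittal lines
## (AF, F, FC, C, CP, P) and columns the lateral positions
## 5,3,1,z,2,4,6 mapped to integer offsets -3..3 (odd = left hemisphere).
## One grid step equals one electrode distance, which defines both the
## small-Laplacian neighbourhoods (the 4 orthogonally adjacent electrodes)
## and the Gaussian scalp maps of the synthetic generator.

.MONTAGE_ROWS <- c(AF = 3, F = 2, FC = 1, C = 0, CP = -1, P = -2)

#' Standard 32-channel 10/10 montage
#'
#' The montage used for acquisition in this pipeline: 32 active electrodes
#' over prefrontal to parietal rows of the international 10/10 system.
#'
#' @return Character vector of 32 channel labels.
#' @export
#' @examples
#' standardMontage()
standardMontage <- function() {
  c("AFz", "F3", "F1", "Fz", "F2", "F4",
    "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6",
    "C5", "C3", "C1", "Cz", "C2", "C4", "C6",
    "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6",
    "P3", "P1", "Pz", "P2", "P4")
}

#' Default ERD feature channels
#'
#' The fronto-central (FCx), central (Cx) and centro-parietal (CPx)
#' channels over sensorimotor cortex used for spectral (ERD) features.
#' With `drop = c("FC3", "FC1")` (channels removed for artifacts in the
#' reference acquisition) this yields the canonical 19-channel list.
#'
#' @param drop Channels to exclude (default `c("FC3", "FC1")`).
#' @return Character vector of channel labels.
#' @export
erdChannels <- function(drop = c("FC3", "FC1")) {
  ch <- standardMontage()
  out <- ch[grepl("^FC", ch) | grepl("^CP", ch) | grepl("^C[0-9z]$", ch)]
  setdiff(out, drop)
}

#' Default MRCP feature channels
#'
#' The 8 central-midline channels whose slow-potential time courses are
#' used as MRCP features.
#'
#' @return Character vector of 8 channel labels.
#' @export
mrcpChannels <- function() {
  c("FCz", "FC2", "C1", "Cz", "C2", "CP1", "CPz", "CP2")
}

## label -> (x, y) grid coordinates; unknown labels give NA rows
montageCoords <- function(labels) {
  m <- regmatches(labels, regexec("^([A-Za-z]+?)([0-9]+|z)$", labels))
  xy <- t(vapply(seq_along(labels), function(i) {
    p <- m[[i]]
    if (length(p) != 3L) return(c(NA_real_, NA_real_))
    row <- p[2]; col <- p[3]
    if (!row %in% names(.MONTAGE_ROWS)) return(c(NA_real_, NA_real_))
    x <- if (col == "z") 0 else {
      k <- as.integer(col)
      if (k %% 2L == 1L) -(k + 1L) / 2 else k / 2
    }
    c(x, .MONTAGE_ROWS[[row]])
  }, numeric(2)))
  rownames(xy) <- labels
  colnames(xy) <- c("x", "y")
  xy
}

#' Small-Laplacian neighbour sets
#'
#' For each channel, the orthogonally adjacent 10/10 electrodes at
#' one grid step (up to 4); edge channels keep whatever subset exists
#' in `labels`.
#'
#' @param labels Channel labels present in the recording.
#' @return Named list mapping each label to a character vector of
#'   neighbours (possibly empty).
#' @export
montageNeighbors <- function(labels = standardMontage()) {
  xy <- montageCoords(labels)
  out <- vector("list", length(labels))
  names(out) <- labels
  for (i in seq_along(labels)) {
    if (anyNA(xy[i, ])) { out[[i]] <- character(0); next }
    d <- sweep(xy, 2, xy[i, ])
    adj <- which((abs(d[, "x"]) == 1 & d[, "y"] == 0) |
                 (d[, "x"] == 0 & abs(d[, "y"]) == 1))
    out[[i]] <- labels[setdiff(adj, i)]
  }
  out
}
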