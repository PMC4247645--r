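## Readers and writers. EDF is import/export for interchange with
## acquisition software; the internal single-file store (RDS of the S4
## containers) holds epoch-aligned arrays, which EDF cannot represent.

.edfPad <- function(x, n) {
  x <- substr(as.character(x), 1, n)
  formatC(x, width = n, flag = "-")
}

#' Write an EEGRecording to EDF
#'
#' Minimal continuous EDF export: 16-bit samples, 1 s data records,
#' per-signal physical scaling from the data range. Auxiliary channels
#' are stored as additional signals (their own sampling rate must give
#' an integer number of samples per record). The recording is truncated
#' to a whole number of records.
#'
#' @param recording An \linkS4class{EEGRecording}.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeEDF <- function(recording, path) {
  stopifnot(is(recording, "EEGRecording"))
  fs <- recording@fs
  sigs <- lapply(seq_along(recording@channelLabels), function(i)
    list(label = recording@channelLabels[i],
         data = recording@data[i, ], fs = fs))
  for (nm in names(recording@aux)) {
    a <- recording@aux[[nm]]
    sigs <- c(sigs, list(list(label = nm, data = a$data, fs = a$fs)))
  }
  ns <- length(sigs)
  nRec <- floor(min(vapply(sigs, function(s) length(s$data) / s$fs,
                           0)))
  if (nRec < 1) stop("recording shorter than one data record")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edfPad("0", 8), .edfPad("X X X X", 80), .edfPad("synthetic", 80),
    .edfPad("01.01.00", 8), .edfPad("00.00.00", 8),
    .edfPad(256 * (ns + 1), 8), .edfPad("", 44),
    .edfPad(nRec, 8), .edfPad(1, 8), .edfPad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  pmin_ <- vapply(sigs, function(s) min(s$data, -1e-6), 0)
  pmax_ <- vapply(sigs, function(s) max(s$data, 1e-6), 0)
  fld <- function(vals, n) paste0(vapply(vals, .edfPad, "", n = n),
                                  collapse = "")
  writeChar(paste0(
    fld(vapply(sigs, `[[`, "", "label"), 16),
    fld(rep("", ns), 80), fld(rep("uV", ns), 8),
    fld(sprintf("%.5g", pmin_), 8), fld(sprintf("%.5g", pmax_), 8),
    fld(rep("-32768", ns), 8), fld(rep("32767", ns), 8),
    fld(rep("", ns), 80),
    fld(vapply(sigs, function(s) as.character(round(s$fs)), ""), 8),
    fld(rep("", ns), 32)), con, eos = NULL)
  pmin2 <- as.numeric(sprintf("%.5g", pmin_))
  pmax2 <- as.numeric(sprintf("%.5g", pmax_))
  for (r in seq_len(nRec)) {
    for (i in seq_len(ns)) {
      spr <- round(sigs[[i]]$fs)
      seg <- sigs[[i]]$data[(r - 1) * spr + seq_len(spr)]
      dig <- round((seg - pmin2[i]) / (pmax2[i] - pmin2[i]) * 65535 -
                     32768)
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read a continuous EDF file
#'
#' Parses a standard (continuous, 16-bit) EDF file. Signals whose labels
#' belong to the 10/10 montage become EEG channels; other signals are
#' preserved as auxiliary channels and reported with a message, so
#' nothing is silently dropped.
#'
#' @param path EDF file.
#' @return An \linkS4class{EEGRecording}.
#' @export
readEDF <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  ver <- rd(8)
  if (!identical(ver, "0")) stop("not an EDF file (bad version field)")
  rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  nRec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("corrupt EDF signal count")
  rdN <- function(n) vapply(seq_len(ns), function(i) rd(n), "")
  labels <- rdN(16)
  rdN(80); rdN(8)
  physMin <- as.numeric(rdN(8)); physMax <- as.numeric(rdN(8))
  digMin <- as.numeric(rdN(8)); digMax <- as.numeric(rdN(8))
  rdN(80)
  spr <- as.integer(rdN(8))
  rdN(32)
  if (anyNA(c(physMin, physMax, digMin, digMax, spr)))
    stop("corrupt EDF signal headers")
  if (anyDuplicated(labels))
    stop("duplicate channel label in EDF: ",
         labels[duplicated(labels)][1])
  dat <- lapply(seq_len(ns), function(i) numeric(nRec * spr[i]))
  for (r in seq_len(nRec)) {
    for (i in seq_len(ns)) {
      raw <- readBin(con, "integer", n = spr[i], size = 2,
                     signed = TRUE, endian = "little")
      phys <- physMin[i] + (raw - digMin[i]) *
        (physMax[i] - physMin[i]) / (digMax[i] - digMin[i])
      dat[[i]][(r - 1) * spr[i] + seq_len(spr[i])] <- phys
    }
  }
  fsAll <- spr / recDur
  known <- labels %in% standardMontage()
  if (!any(known)) stop("no montage channel found in EDF")
  eegIdx <- which(known)
  fs <- fsAll[eegIdx[1]]
  if (length(unique(fsAll[eegIdx])) > 1)
    stop("EEG channels have inconsistent sampling rates")
  data <- do.call(rbind, dat[eegIdx])
  aux <- list()
  if (any(!known)) {
    message("non-montage signals kept as auxiliary channels: ",
            paste(labels[!known], collapse = ", "))
    for (i in which(!known))
      aux[[labels[i]]] <- list(data = dat[[i]], fs = fsAll[i])
  }
  new("EEGRecording", data = data, fs = fs,
      channelLabels = labels[eegIdx], aux = aux)
}

#' Load a recording from EDF or the internal store
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"edf"`, `"internal"` (RDS of
#'   an \linkS4class{EEGRecording}) or `"gdf"` (not supported: convert
#'   to EDF).
#' @return An \linkS4class{EEGRecording}.
#' @export
loadRecording <- function(path, format = c("auto", "edf", "internal",
                                           "gdf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)),
                     edf = "edf", gdf = "gdf", "internal")
  if (format == "gdf")
    stop("GDF import is not supported; convert the file to EDF")
  if (format == "edf") return(readEDF(path))
  x <- readRDS(path)
  if (!is(x, "EEGRecording"))
    stop("internal file does not contain an EEGRecording")
  validObject(x)
  x
}

#' Save a recording to the internal store
#'
#' Single-file store with embedded metadata (sampling rate, labels,
#' auxiliary channels); `loadRecording(saveRecording(x, p))`
#' round-trips bit-identically.
#'
#' @param recording An \linkS4class{EEGRecording}.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
saveRecording <- function(recording, path) {
  stopifnot(is(recording, "EEGRecording"))
  saveRDS(recording, path)
  invisible(path)
}

#' Save / load TrialSets and other pipeline objects
#'
#' @param x a \linkS4class{TrialSet}, \linkS4class{SdaModel},
#'   \linkS4class{IntentionEval} or \linkS4class{SpatialFilter}.
#' @param path file path.
#' @return `saveTrialStore`: `path` invisibly; `loadTrialStore`: the
#'   object.
#' @export
saveTrialStore <- function(x, path) {
  ok <- c("TrialSet", "SdaModel", "IntentionEval", "SpatialFilter",
          "EEGRecording")
  if (!any(vapply(ok, function(cl) is(x, cl), logical(1))))
    stop("unsupported object class: ", class(x)[1])
  saveRDS(x, path)
  invisible(path)
}

#' @rdname saveTrialStore
#' @export
loadTrialStore <- function(path) {
  x <- readRDS(path)
  validObject(x)
  x
}

#' Serialize a spatial filter to JSON
#'
#' @param filter A \linkS4class{SpatialFilter}.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
writeFilterJSON <- function(filter, path) {
  jsonlite::write_json(list(
    target = filter@target,
    labels = names(filter@weights),
    weights = unname(filter@weights),
    snr_achieved_db = filter@snrAchieved,
    snr_init_db = filter@snrInit,
    converged = filter@converged), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeFilterJSON
#' @export
readFilterJSON <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- stats::setNames(j$weights, j$labels)
  new("SpatialFilter", weights = w, target = j$target,
      snrAchieved = j$snr_achieved_db, snrInit = j$snr_init_db,
      converged = j$converged)
}
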