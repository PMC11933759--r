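#' @include simulate-cohort.R
NULL

## EDF (European Data Format) minimal reader/writer: 256-byte fixed header,
## 256 bytes per signal header, little-endian 16-bit samples in 1-second
## data records. Only what the two-channel recordings need.

edfField <- function(x, width) {
  s <- formatC(as.character(x), width = width, flag = "-")
  stopIf(nchar(s) > width, "EDF header field too long: '%s'", x)
  s
}

#' Write a recording as EDF
#'
#' Samples are quantised to 16-bit integers over a symmetric physical range
#' in microvolts. A value outside the range is an error, never silent
#' saturation, because clipping corrupts spectra. The record duration is
#' 1 s; a trailing fraction of a second is dropped with a warning.
#'
#' @param rec an [EEGRecording-class].
#' @param path output file.
#' @param physicalRange symmetric range limit in uV; default is the data
#'   maximum rounded up to the next integer.
#' @return `path`, invisibly.
#' @export
writeEDF <- function(rec, path, physicalRange = NULL) {
  stopifnot(is(rec, "EEGRecording"))
  x <- rec@samples
  if (is.null(physicalRange))
    physicalRange <- max(ceiling(max(abs(x))), 1)
  stopIf(any(abs(x) > physicalRange),
         "samples exceed the physical range +/-%g uV; writing would clip",
         physicalRange)
  nPerRec <- as.integer(rec@fs)
  stopIf(nPerRec != rec@fs, "EDF writer requires an integer sampling rate")
  nRec <- nrow(x) %/% nPerRec
  stopIf(nRec < 1, "recording shorter than one 1-second data record")
  if (nRec * nPerRec < nrow(x))
    warning(sprintf("dropping %d trailing samples (not a whole second)",
                    nrow(x) - nRec * nPerRec))
  ns <- ncol(x)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edfField("0", 8),
    edfField("X X X X", 80),
    edfField(sprintf("id=%s month=%d condition=%s", rec@participantId,
                     rec@month, rec@condition), 80),
    edfField("01.01.26", 8), edfField("00.00.00", 8),
    edfField(256 * (ns + 1), 8),
    edfField("", 44),
    edfField(nRec, 8), edfField("1", 8), edfField(ns, 4))
  sig <- function(vals, width)
    paste(vapply(vals, edfField, character(1), width = width), collapse = "")
  hdr <- paste0(hdr,
    sig(rec@channels, 16),
    sig(rep("", ns), 80),
    sig(rep("uV", ns), 8),
    sig(rep(-physicalRange, ns), 8),
    sig(rep(physicalRange, ns), 8),
    sig(rep(-32767L, ns), 8),
    sig(rep(32767L, ns), 8),
    sig(rep("BP 0.5-30 Hz", ns), 80),
    sig(rep(nPerRec, ns), 8),
    sig(rep("", ns), 32))
  writeChar(hdr, con, eos = NULL)
  scale <- 32767 / physicalRange
  for (r in seq_len(nRec)) {
    idx <- ((r - 1) * nPerRec + 1):(r * nPerRec)
    for (s in seq_len(ns))
      writeBin(as.integer(round(x[idx, s] * scale)), con, size = 2,
               endian = "little")
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' @param path EDF file written by [writeEDF()] or any single-rate EDF
#'   with microvolt channels.
#' @return an [EEGRecording-class].
#' @export
readEDF <- function(path) {
  stopIf(!file.exists(path), "file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rd(8); rd(80)
  recInfo <- rd(80); rd(8); rd(8)
  hdrBytes <- as.integer(rd(8)); rd(44)
  nRec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  stopIf(is.na(ns) || ns < 1, "%s: unparseable EDF header (signal count)",
         path)
  rdN <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- rdN(16); rdN(80)
  dims <- rdN(8)
  physMin <- as.numeric(rdN(8)); physMax <- as.numeric(rdN(8))
  digMin <- as.numeric(rdN(8)); digMax <- as.numeric(rdN(8))
  rdN(80)
  nPerRec <- as.integer(rdN(8)); rdN(32)
  stopIf(any(is.na(c(physMin, physMax, digMin, digMax, nPerRec, nRec))),
         "%s: unparseable EDF header (signal fields)", path)
  stopIf(length(unique(nPerRec)) != 1,
         "%s: channels with differing sampling rates are not supported", path)
  stopIf(!all(grepl("uV", dims)),
         "%s: physical dimension must be uV (got: %s)", path,
         paste(dims, collapse = ", "))
  n <- nPerRec[1]
  out <- matrix(0, nRec * n, ns)
  for (r in seq_len(nRec)) for (s in seq_len(ns)) {
    d <- readBin(con, "integer", n = n, size = 2, endian = "little",
                 signed = TRUE)
    stopIf(length(d) < n, "%s: truncated data record %d", path, r)
    out[((r - 1) * n + 1):(r * n), s] <-
      physMin[s] + (d - digMin[s]) * (physMax[s] - physMin[s]) /
        (digMax[s] - digMin[s])
  }
  meta <- edfRecInfo(recInfo)
  new("EEGRecording", participantId = meta$id, month = meta$month,
      condition = meta$condition, channels = labels, samples = out,
      fs = n / recDur)
}

edfRecInfo <- function(info) {
  pick <- function(key, default) {
    m <- regmatches(info, regexec(paste0(key, "=([^ ]+)"), info))[[1]]
    if (length(m) == 2) m[2] else default
  }
  list(id = pick("id", "unknown"),
       month = as.integer(pick("month", "1")),
       condition = pick("condition", "open"))
}
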