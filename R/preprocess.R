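#' @include io-results.R
NULL

#' Zero-phase bandpass filter
#'
#' 4th-order Butterworth bandpass applied forward and backward
#' (`signal::filtfilt`), so the passband is ripple-free and no group delay
#' distorts band powers. Each channel is filtered independently.
#'
#' @param rec an [EEGRecording-class].
#' @param fLo,fHi cutoff frequencies in Hz (defaults 0.5 and 30, the
#'   device band).
#' @param order Butterworth order per section (default 4).
#' @return the filtered [EEGRecording-class].
#' @export
bandpassFilter <- function(rec, fLo = 0.5, fHi = 30, order = 4) {
  stopifnot(is(rec, "EEGRecording"))
  stopIf(!(fLo < fHi), "fLo must be below fHi")
  stopIf(fHi >= rec@fs / 2, "fHi must be below the Nyquist frequency %g",
         rec@fs / 2)
  bf <- signal::butter(order, c(fLo, fHi) / (rec@fs / 2), type = "pass")
  rec@samples <- apply(rec@samples, 2, function(x)
    signal::filtfilt(bf, x))
  rec
}

#' Cut a recording into non-overlapping epochs
#'
#' @param rec an [EEGRecording-class].
#' @param lengthS epoch length in seconds (default 4, giving a 0.25 Hz
#'   spectral grid at 512 Hz).
#' @param overlap fraction of overlap; only 0 is supported.
#' @return an [EpochSet-class] with `floor(duration / lengthS)` epochs;
#'   the remainder is discarded.
#' @export
epochRecording <- function(rec, lengthS = 4, overlap = 0) {
  stopifnot(is(rec, "EEGRecording"))
  stopIf(overlap != 0, "overlapping epochs are not supported")
  nPer <- round(lengthS * rec@fs)
  nEp <- nrow(rec@samples) %/% nPer
  stopIf(nEp < 1, "recording (%g s) shorter than one epoch (%g s)",
         nrow(rec@samples) / rec@fs, lengthS)
  dat <- array(rec@samples[seq_len(nEp * nPer), , drop = FALSE],
               dim = c(nPer, nEp, ncol(rec@samples)))
  dat <- aperm(dat, c(1, 3, 2))  # samples x channels x epochs
  new("EpochSet",
      recordingId = recId(rec@participantId, rec@month, rec@condition),
      fs = rec@fs, epochLength = lengthS, data = dat,
      keptMask = rep(TRUE, nEp), rejectionStats = list())
}

#' Reject artifact epochs
#'
#' Stands in for ocular-artifact removal, which is not feasible with two
#' channels: an epoch is rejected when any sample exceeds `ampThresholdUv`
#' (absolute, uV) or when its peak-to-peak amplitude is an outlier across
#' epochs (z-score above `zThreshold`; z-scores are computed over all
#' epochs of the set, so the operation is idempotent and
#' permutation-equivariant). Epochs are masked, never dropped.
#'
#' @param epochs an [EpochSet-class].
#' @param ampThresholdUv absolute amplitude threshold, uV (default 150).
#' @param zThreshold peak-to-peak z-score threshold (default 5).
#' @return the [EpochSet-class] with an updated mask and rejection stats.
#'   All epochs rejected is an error instructing threshold review.
#' @export
rejectArtifacts <- function(epochs, ampThresholdUv = 150, zThreshold = 5) {
  stopifnot(is(epochs, "EpochSet"))
  nEp <- dim(epochs@data)[3]
  stopIf(nEp < 1, "no epochs to screen")
  ampBad <- apply(epochs@data, 3, function(e) any(abs(e) > ampThresholdUv))
  p2p <- apply(epochs@data, 3, function(e)
    max(apply(e, 2, function(ch) diff(range(ch)))))
  z <- if (stats::sd(p2p) > 0) (p2p - mean(p2p)) / stats::sd(p2p) else
    rep(0, nEp)
  zBad <- z > zThreshold
  kept <- !(ampBad | zBad)
  stopIf(!any(kept),
         paste("all %d epochs rejected; review ampThresholdUv=%g /",
               "zThreshold=%g against the data"), nEp, ampThresholdUv,
         zThreshold)
  epochs@keptMask <- kept
  epochs@rejectionStats <- list(
    nEpochs = nEp, nKept = sum(kept), nAmplitude = sum(ampBad),
    nPeakToPeak = sum(zBad & !ampBad))
  epochs
}

#' @describeIn nEpochs total number of epochs.
#' @export
setMethod("nEpochs", "EpochSet", function(object) dim(object@data)[3])

#' @describeIn nEpochs logical mask of kept epochs.
#' @export
setMethod("keptMask", "EpochSet", function(object) object@keptMask)

setMethod("show", "EpochSet", function(object) {
  cat(sprintf("EpochSet '%s': %d x %g s epochs (%d kept), %d channel(s), %g Hz\n",
              object@recordingId, nEpochs(object), object@epochLength,
              sum(object@keptMask), dim(object@data)[2], object@fs))
})
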