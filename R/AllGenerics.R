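#' @include AllClasses.R
NULL

#' Multitaper power spectral density
#'
#' Estimate one-sided PSDs by averaging DPSS eigenspectra over tapers and
#' kept epochs. See [multitaperPSD,EpochSet-method].
#'
#' @param x an [EpochSet-class] or a numeric epochs matrix.
#' @param ... further arguments passed to methods.
#' @export
setGeneric("multitaperPSD", function(x, ...) standardGeneric("multitaperPSD"))

#' Number of epochs / kept epochs
#' @param object an [EpochSet-class].
#' @export
setGeneric("nEpochs", function(object) standardGeneric("nEpochs"))

#' @rdname nEpochs
#' @export
setGeneric("keptMask", function(object) standardGeneric("keptMask"))

#' Frequency grid accessor
#' @param object a [PowerSpectrum-class] or [SpectralDecomposition-class].
#' @export
setGeneric("freqs", function(object) standardGeneric("freqs"))

#' PSD values accessor
#' @param object a [PowerSpectrum-class].
#' @export
setGeneric("psd", function(object) standardGeneric("psd"))

#' Aperiodic model parameters accessor
#' @param object an [AperiodicFit-class].
#' @export
setGeneric("aperiodicParams", function(object)
  standardGeneric("aperiodicParams"))
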