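#' @import methods
NULL

#' Cohort participation design
#'
#' Describes which of the three study months each participant attended.
#' Validity enforces the inclusion-exclusion identity: the union of the
#' per-month membership sets must equal the number of participants.
#'
#' @slot monthsPresent named list; one integer vector of months (subset of
#'   1:3) per participant, names are participant ids.
#' @slot nParticipants integer, number of unique participants.
#'
#' @seealso [defaultCohortDesign()]
#' @export
setClass("CohortDesign",
  representation(monthsPresent = "list", nParticipants = "integer"))

setValidity("CohortDesign", function(object) {
  mp <- object@monthsPresent
  if (length(mp) != object@nParticipants)
    return("nParticipants must equal length(monthsPresent)")
  if (is.null(names(mp)) || anyDuplicated(names(mp)))
    return("monthsPresent must have unique participant names")
  for (m in mp) {
    if (length(m) < 1L || !all(m %in% 1:3) || anyDuplicated(m))
      return("each participant's months must be a non-empty subset of 1:3")
  }
  TRUE
})

#' Latent sleep-quality trait
#'
#' Standardised poor-sleep propensity of one participant plus per-month
#' deviations around it. These latent values drive both the synthetic PSQI
#' scores and the low-alpha oscillation amplitude, so their shared variance
#' is the generator's ground-truth coupling.
#'
#' @slot participantId character scalar.
#' @slot trait numeric z-score (unitless), finite.
#' @slot monthlyJitter named numeric, one standardised deviation per month.
#' @export
setClass("LatentTrait",
  representation(participantId = "character", trait = "numeric",
                 monthlyJitter = "numeric"))

setValidity("LatentTrait", function(object) {
  if (!is.finite(object@trait)) return("trait must be finite")
  if (!all(is.finite(object@monthlyJitter)))
    return("monthlyJitter must be finite")
  TRUE
})

#' Synthetic EEG signal specification
#'
#' Target one-sided power spectral density of a synthetic recording: an
#' aperiodic 1/f-like background \eqn{a + b/(c + f^d)} plus Gaussian
#' oscillatory bumps, under one eye condition.
#'
#' @slot fs sampling rate in Hz.
#' @slot duration recording length in seconds.
#' @slot aperiodic named numeric with elements `a`, `b`, `c`, `d`.
#' @slot oscillations data.frame with columns `center` (Hz), `amplitude`
#'   (uV^2/Hz at the peak), `bandwidth` (Gaussian sigma, Hz).
#' @slot condition `"open"` or `"closed"`.
#' @export
setClass("SignalSpec",
  representation(fs = "numeric", duration = "numeric", aperiodic = "numeric",
                 oscillations = "data.frame", condition = "character"))

setValidity("SignalSpec", function(object) {
  if (object@fs <= 0) return("fs must be positive")
  if (object@duration <= 0) return("duration must be positive")
  ap <- object@aperiodic
  if (!all(c("a", "b", "c", "d") %in% names(ap)))
    return("aperiodic must contain a, b, c, d")
  if (any(ap[c("b", "c", "d")] < 0)) return("b, c, d must be non-negative")
  osc <- object@oscillations
  if (nrow(osc)) {
    if (!all(c("center", "amplitude", "bandwidth") %in% names(osc)))
      return("oscillations needs columns center, amplitude, bandwidth")
    if (any(osc$amplitude < 0)) return("bump amplitudes must be >= 0")
    if (any(osc$center <= 0.5 | osc$center >= 30))
      return("bump centers must lie within (0.5, 30) Hz")
    if (any(osc$bandwidth <= 0)) return("bump bandwidths must be positive")
  }
  if (!object@condition %in% c("open", "closed"))
    return("condition must be 'open' or 'closed'")
  TRUE
})

#' Two-channel EEG recording
#'
#' One participant-month-condition segment of prefrontal EEG in microvolts.
#'
#' @slot participantId character scalar.
#' @slot month integer in 1:3.
#' @slot condition `"open"` or `"closed"`.
#' @slot channels character vector of channel labels (default FP1, FP2).
#' @slot samples numeric matrix, samples x channels, microvolts.
#' @slot fs sampling rate in Hz.
#' @export
setClass("EEGRecording",
  representation(participantId = "character", month = "integer",
                 condition = "character", channels = "character",
                 samples = "matrix", fs = "numeric"))

setValidity("EEGRecording", function(object) {
  if (ncol(object@samples) != length(object@channels))
    return("samples must have one column per channel")
  if (anyNA(object@samples)) return("samples must not contain NA")
  if (object@fs <= 60) return("fs must exceed 60 Hz (2 x 30 Hz analysis band)")
  if (!object@condition %in% c("open", "closed"))
    return("condition must be 'open' or 'closed'")
  if (!object@month %in% 1:3) return("month must be in 1:3")
  TRUE
})

#' Epoched recording
#'
#' Non-overlapping fixed-length epochs of a recording together with the
#' artifact-rejection mask. Epochs are never physically dropped; downstream
#' estimation honours `keptMask`.
#'
#' @slot recordingId character label of the source recording.
#' @slot fs sampling rate in Hz.
#' @slot epochLength epoch length in seconds.
#' @slot data numeric array, samples x channels x epochs, microvolts.
#' @slot keptMask logical per epoch.
#' @slot rejectionStats list of counters filled by [rejectArtifacts()].
#' @export
setClass("EpochSet",
  representation(recordingId = "character", fs = "numeric",
                 epochLength = "numeric", data = "array",
                 keptMask = "logical", rejectionStats = "list"))

setValidity("EpochSet", function(object) {
  d <- dim(object@data)
  if (length(d) != 3) return("data must be samples x channels x epochs")
  if (length(object@keptMask) != d[3])
    return("keptMask length must equal epoch count")
  if (d[1] != round(object@epochLength * object@fs))
    return("epoch sample count inconsistent with epochLength * fs")
  TRUE
})

#' Power spectrum
#'
#' One-sided power spectral density on a uniform ascending frequency grid,
#' in uV^2/Hz, with provenance metadata.
#'
#' @slot freqs frequency grid in Hz.
#' @slot psd density values, same length as `freqs`.
#' @slot df grid spacing in Hz.
#' @slot meta list (recording id, condition, month, channel, epochs, tapers).
#' @export
setClass("PowerSpectrum",
  representation(freqs = "numeric", psd = "numeric", df = "numeric",
                 meta = "list"))

setValidity("PowerSpectrum", function(object) {
  if (length(object@freqs) != length(object@psd))
    return("freqs and psd must have equal length")
  if (object@df <= 0) return("df must be positive")
  if (is.unsorted(object@freqs, strictly = TRUE))
    return("freqs must be strictly ascending")
  if (any(object@psd < 0)) return("psd must be non-negative")
  TRUE
})

#' Aperiodic (1/f-like) fit
#'
#' Parameters of the aperiodic model \eqn{a + b/(c + f^d)} fitted to
#' log10 power, with fit diagnostics.
#'
#' @slot params named numeric `a`, `b`, `c`, `d`.
#' @slot fitRange numeric length 2, Hz.
#' @slot rmseLog root-mean-square residual in log10 power over the final
#'   (peak-masked) fit support.
#' @slot converged logical.
#' @export
setClass("AperiodicFit",
  representation(params = "numeric", fitRange = "numeric",
                 rmseLog = "numeric", converged = "logical"))

setValidity("AperiodicFit", function(object) {
  p <- object@params
  if (!all(c("a", "b", "c", "d") %in% names(p)))
    return("params must contain a, b, c, d")
  if (any(p[c("b", "c", "d")] < -1e-12))
    return("b, c, d must be non-negative")
  if (object@converged && !is.finite(object@rmseLog))
    return("rmseLog must be finite for a converged fit")
  TRUE
})

#' Aperiodic/periodic spectral decomposition
#'
#' Raw spectrum, evaluated aperiodic curve, and the signed periodic
#' residual on a shared grid. The additive identity
#' `raw == aperiodic + periodic` holds exactly by construction.
#'
#' @slot freqs frequency grid, Hz.
#' @slot raw raw psd, uV^2/Hz.
#' @slot aperiodic evaluated fit, uV^2/Hz, strictly positive.
#' @slot periodic signed residual, uV^2/Hz.
#' @slot fit the [AperiodicFit-class] used.
#' @export
setClass("SpectralDecomposition",
  representation(freqs = "numeric", raw = "numeric", aperiodic = "numeric",
                 periodic = "numeric", fit = "AperiodicFit"))

setValidity("SpectralDecomposition", function(object) {
  n <- length(object@freqs)
  if (length(object@raw) != n || length(object@aperiodic) != n ||
      length(object@periodic) != n)
    return("freqs, raw, aperiodic, periodic must share one grid")
  if (any(object@aperiodic <= 0)) return("aperiodic curve must be positive")
  err <- max(abs(object@raw - object@aperiodic - object@periodic)) /
    max(object@raw, 1e-300)
  if (err > 1e-9) return("raw must equal aperiodic + periodic")
  TRUE
})

#' Synthetic cohort
#'
#' Output of [generateCohort()]: one PSQI record per participant-month and
#' two recordings (eyes open / eyes closed) per participant-month, either
#' as time series ([EEGRecording-class]) or directly as spectra
#' ([PowerSpectrum-class]) in the fast spectrum-level mode.
#'
#' @slot design the [CohortDesign-class] realised.
#' @slot psqi data.frame: participant, month, psqi_c1..psqi_c7, psqi_total.
#' @slot recordings named list of recordings or spectra.
#' @slot mode `"time"` or `"spectrum"`.
#' @slot truth data.frame of latent ground truth per recording.
#' @slot seed integer master seed.
#' @export
setClass("SleepCohort",
  representation(design = "CohortDesign", psqi = "data.frame",
                 recordings = "list", mode = "character",
                 truth = "data.frame", seed = "integer"))

#' Result bundle of a pipeline run
#'
#' All canonical tables produced by [runPipeline()].
#'
#' @slot bandPower per-recording relative band powers (raw and, when the
#'   decomposition stage is on, aperiodic/periodic components).
#' @slot corrBands band-level Pearson correlations against PSQI across all
#'   groupings.
#' @slot corrSpectrum frequency-resolved (0.5 Hz bin) correlations.
#' @slot bergerTests paired eyes-closed vs eyes-open tests per month.
#' @slot monthTests cross-month comparisons with Bonferroni adjustment.
#' @slot meta run metadata: config hash, seed, package version, counters.
#' @export
setClass("ResultBundle",
  representation(bandPower = "data.frame", corrBands = "data.frame",
                 corrSpectrum = "data.frame", bergerTests = "data.frame",
                 monthTests = "data.frame", meta = "list"))

setValidity("ResultBundle", function(object) {
  for (nm in c("corrBands", "corrSpectrum")) {
    tab <- slot(object, nm)
    if (nrow(tab)) {
      if (any(tab$p < 0 | tab$p > 1, na.rm = TRUE))
        return(sprintf("%s: p-values must lie in [0,1]", nm))
      if (any(abs(tab$r) > 1 + 1e-12, na.rm = TRUE))
        return(sprintf("%s: r must lie in [-1,1]", nm))
    }
  }
  TRUE
})
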