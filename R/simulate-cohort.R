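#' @include simulate-eeg.R
NULL

#' Default generator parameters
#'
#' The synthetic-cohort generator's fixed study conditions: device grid
#' (512 Hz, 180 s per recording), the aperiodic background and its
#' between-participant and within-participant (test-retest) variability,
#' and the oscillatory bumps. Amplitudes are uV^2/Hz at the bump peak.
#'
#' The low-alpha (LA) bump at 7.75 Hz carries the sleep-quality coupling:
#' its log-amplitude is a linear map of a latent variable correlated with
#' the PSQI trait (see [defaultCoupling()]). The 10 Hz bump carries the
#' eyes-closed alpha enhancement; aperiodic parameters are drawn with the
#' same distribution in both eye conditions so the open/closed difference
#' is carried entirely by the periodic component in expectation.
#'
#' @return nested list of parameters.
#' @export
defaultGeneratorParams <- function() {
  list(
    fs = 512, duration = 180,
    aperiodic = c(a = 0.08, b = 30, c = 1, d = 2),
    participantMonthSd = c(bLog = 0.4, d = 0.15),
    recordingSd = c(aLog = 0.2, bLog = 0.25, d = 0.09),
    la = list(center = 7.75, bandwidth = 0.5, amplitude = 0.40, scale = 0.65),
    ma = list(center = 10, bandwidth = 0.7, sdLog = 0.30),
    beta = list(center = 18, bandwidth = 2, amplitude = 0.06),
    jitterSd = 0.3,
    grid = seq(0.5, 30, by = 0.25),
    nAveraged = 225)
}

#' Default latent coupling
#'
#' Latent correlations between the low-alpha bump amplitude and the PSQI
#' trait, one per eye condition, together with the 10 Hz bump amplitudes
#' that set the eyes-closed alpha enhancement. The correlations were
#' calibrated with [calibrateCoupling()] so that the full pipeline recovers
#' the study's pooled Pearson correlations (0.45 eyes closed, 0.26 eyes
#' open) after attenuation by PSQI discretisation and spectral-estimation
#' noise.
#'
#' @return list with `rhoClosed`, `rhoOpen`, `maClosed`, `maOpen`.
#' @export
defaultCoupling <- function() {
  list(rhoClosed = 0.66, rhoOpen = 0.40, maClosed = 0.85, maOpen = 0.30)
}

## SignalSpec plus latent truth for one recording
recordingSpec <- function(id, month, condition, zpm, coupling, params, seed) {
  rho <- if (condition == "closed") coupling$rhoClosed else coupling$rhoOpen
  stopIf(abs(rho) > 1, "latent correlation rho must lie in [-1, 1]")
  pmDraw <- withSeed(deriveSeed(seed, id, "ap", month),
                     stats::rnorm(2))
  bPm <- params$aperiodic["b"] * exp(params$participantMonthSd["bLog"] *
                                       pmDraw[1])
  dPm <- params$aperiodic["d"] + params$participantMonthSd["d"] * pmDraw[2]
  draw <- withSeed(deriveSeed(seed, id, "rec", month, condition),
                   stats::rnorm(5))
  aR <- params$aperiodic["a"] * exp(params$recordingSd["aLog"] * draw[1])
  bR <- bPm * exp(params$recordingSd["bLog"] * draw[2])
  dR <- max(dPm + params$recordingSd["d"] * draw[3], 0.5)
  zla <- rho * zpm + sqrt(1 - rho^2) * draw[4]
  laAmp <- params$la$amplitude * exp(params$la$scale * zla)
  maMean <- if (condition == "closed") coupling$maClosed else coupling$maOpen
  maAmp <- maMean * exp(params$ma$sdLog * draw[5])
  osc <- data.frame(
    center = c(params$la$center, params$ma$center, params$beta$center),
    amplitude = c(laAmp, maAmp, params$beta$amplitude),
    bandwidth = c(params$la$bandwidth, params$ma$bandwidth,
                  params$beta$bandwidth))
  ap <- c(a = unname(aR), b = unname(bR), c = unname(params$aperiodic["c"]),
          d = unname(dR))
  list(spec = signalSpec(ap, osc, condition = condition, fs = params$fs,
                         duration = params$duration),
       truth = data.frame(participant = id, month = month,
                          condition = condition, zpm = zpm, zla = zla,
                          laAmp = laAmp, maAmp = maAmp, a = ap["a"],
                          b = ap["b"], c = ap["c"], d = ap["d"],
                          row.names = NULL))
}

#' Generate a synthetic longitudinal cohort
#'
#' For every participant-month of the design: one PSQI record and two
#' recordings (eyes open and eyes closed). In `"time"` mode each recording
#' is a two-channel [EEGRecording-class] synthesised by
#' [synthesizeEEG()]; in `"spectrum"` mode the multitaper estimate is
#' emulated directly by [samplePowerSpectrum()], which is orders of
#' magnitude faster and statistically equivalent for band-power analyses.
#'
#' A single master seed spawns one substream per participant, month,
#' condition, and purpose (trait, PSQI, aperiodic state, channel noise),
#' so the cohort is bit-identical for a given seed regardless of
#' evaluation order.
#'
#' @param design a [CohortDesign-class]; default [defaultCohortDesign()].
#' @param coupling list as [defaultCoupling()].
#' @param params list as [defaultGeneratorParams()].
#' @param seed integer master seed.
#' @param mode `"time"` or `"spectrum"`.
#' @return a [SleepCohort-class].
#' @examples
#' coh <- generateCohort(seed = 1, mode = "spectrum")
#' coh
#' @export
generateCohort <- function(design = defaultCohortDesign(),
                           coupling = defaultCoupling(),
                           params = defaultGeneratorParams(),
                           seed = 1, mode = c("time", "spectrum")) {
  mode <- match.arg(mode)
  for (rho in c(coupling$rhoClosed, coupling$rhoOpen))
    stopIf(abs(rho) > 1, "latent correlation rho must lie in [-1, 1]")
  traits <- simulateTraits(design, seed, jitterSd = params$jitterSd)
  psqi <- list(); recs <- list(); truth <- list()
  for (id in names(design@monthsPresent)) {
    for (m in design@monthsPresent[[id]]) {
      zpm <- latentState(traits[[id]], m, jitterSd = params$jitterSd)
      psqi[[length(psqi) + 1L]] <-
        generatePsqi(traits[[id]], m, deriveSeed(seed, id, "psqi", m))
      for (cond in c("open", "closed")) {
        rs <- recordingSpec(id, m, cond, zpm, coupling, params, seed)
        truth[[length(truth) + 1L]] <- rs$truth
        rid <- recId(id, m, cond)
        recs[[rid]] <- if (mode == "time") {
          ch <- vapply(c("FP1", "FP2"), function(lab)
            synthesizeEEG(rs$spec, deriveSeed(seed, id, "sig", m, cond, lab)),
            numeric(round(params$fs * params$duration)))
          new("EEGRecording", participantId = id, month = as.integer(m),
              condition = cond, channels = c("FP1", "FP2"),
              samples = ch, fs = params$fs)
        } else {
          samplePowerSpectrum(rs$spec, freqs = params$grid,
                              seed = deriveSeed(seed, id, "psd", m, cond),
                              nAveraged = params$nAveraged,
                              meta = list(recordingId = rid, participant = id,
                                          month = as.integer(m),
                                          condition = cond,
                                          channel = "FP-mean"))
        }
      }
    }
  }
  new("SleepCohort", design = design,
      psqi = validatePsqiTable(do.call(rbind, psqi)),
      recordings = recs, mode = mode, truth = do.call(rbind, truth),
      seed = as.integer(seed))
}

setMethod("show", "SleepCohort", function(object) {
  cat(sprintf("SleepCohort: %d recordings (%s mode), %d PSQI records, seed %d\n",
              length(object@recordings), object@mode, nrow(object@psqi),
              object@seed))
})

## pooled Pearson r between low-alpha relative power and PSQI total for one
## condition of a spectrum-mode cohort (used by the calibration loop)
pooledLaCorrelation <- function(cohort, condition, band = c(7, 8.5),
                                totalBand = c(0.5, 30)) {
  sel <- cohort@psqi
  rp <- vapply(seq_len(nrow(sel)), function(i) {
    ps <- cohort@recordings[[recId(sel$participant[i], sel$month[i],
                                   condition)]]
    relativePower(ps, band, totalBand)
  }, numeric(1))
  stats::cor(rp, sel$psqi_total)
}

#' Calibrate the latent coupling to a target recovered correlation
#'
#' The correlation the pipeline recovers between low-alpha relative power
#' and PSQI is attenuated relative to the latent coupling `rho` (ordinal
#' PSQI discretisation, spectral-estimation noise, aperiodic variability).
#' This performs a stochastic bisection on `rho`, evaluating the realised
#' pooled correlation by Monte-Carlo over spectrum-mode cohorts, until the
#' mean realised r is within `tol` of `target`.
#'
#' @param target target pooled Pearson r, |target| < 1.
#' @param condition `"closed"` or `"open"`: which condition's coupling to
#'   calibrate (the other keeps its default).
#' @param tol tolerance on the realised correlation (default 0.03).
#' @param seed integer seed for the evaluation cohorts.
#' @param nRep cohorts per Monte-Carlo evaluation (default 30).
#' @param design,coupling,params cohort settings, as [generateCohort()].
#' @param maxIter bisection iterations (default 12).
#' @return list: `rho` (calibrated value), `realized` (its Monte-Carlo
#'   mean r), `evaluations` (data.frame of the bisection path).
#' @export
calibrateCoupling <- function(target, condition = c("closed", "open"),
                              tol = 0.03, seed = 1, nRep = 30,
                              design = defaultCohortDesign(),
                              coupling = defaultCoupling(),
                              params = defaultGeneratorParams(),
                              maxIter = 12) {
  condition <- match.arg(condition)
  stopIf(abs(target) >= 1, "|target| must be < 1")
  evalRho <- function(rho) {
    cp <- coupling
    cp[[if (condition == "closed") "rhoClosed" else "rhoOpen"]] <- rho
    mean(vapply(seq_len(nRep), function(i) {
      coh <- generateCohort(design, cp, params,
                            seed = deriveSeed(seed, "cal", condition, i),
                            mode = "spectrum")
      pooledLaCorrelation(coh, condition)
    }, numeric(1)))
  }
  path <- data.frame(rho = numeric(), realized = numeric())
  note <- function(rho, r) path[nrow(path) + 1L, ] <<- c(rho, r)
  if (abs(target) < tol / 2) {
    r0 <- evalRho(0); note(0, r0)
    return(list(rho = 0, realized = r0, evaluations = path))
  }
  sgn <- sign(target)
  hi <- sgn * 0.99; lo <- 0
  rHi <- evalRho(hi); note(hi, rHi)
  stopIf(sgn * rHi < sgn * target - tol,
         "target r=%.3f unattainable: at rho=%.2f the realised r is %.3f",
         target, hi, rHi)
  rLo <- evalRho(lo); note(lo, rLo)
  for (i in seq_len(maxIter)) {
    mid <- (lo + hi) / 2
    rMid <- evalRho(mid); note(mid, rMid)
    if (abs(rMid - target) <= tol)
      return(list(rho = mid, realized = rMid, evaluations = path))
    if (sgn * rMid < sgn * target) lo <- mid else hi <- mid
  }
  list(rho = (lo + hi) / 2, realized = evalRho((lo + hi) / 2),
       evaluations = path)
}
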