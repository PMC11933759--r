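#' @include spectral.R
NULL

#' Fit the aperiodic 1/f-like background
#'
#' Nonlinear least squares of `log10(a + b/(c + f^d))` against the log10
#' spectrum over `fitRange`, with all parameters bounded non-negative and
#' the exponent capped at 6 and the knee at 1000 (physiological exponents
#' stay well below 4, and knee frequencies within the analysis band keep
#' `c` far below the cap; the bounds exclude a degenerate "cliff" basin
#' and a weakly identified large-knee ridge on which `b`, `c`, `d` drift
#' jointly without changing the curve). The fit is staged for robustness: a knee-free
#' model `a + b f^-d` is fitted first from three deterministic starts
#' (exponents 1, 2, 3, scale matched to the low end) to localise
#' oscillatory peaks, then the full knee model is fitted with the peaks
#' excluded. Peak exclusion is the robust iteration: frequencies whose
#' positive residual exceeds 2.5 times the MAD of the residuals are
#' masked -- together with a +/-0.75 Hz neighbourhood, because peak tails
#' adjoin the detected cores and otherwise bias the background upward --
#' and the fit is repeated.
#'
#' @param ps a [PowerSpectrum-class]; the density must be strictly
#'   positive over `fitRange`.
#' @param fitRange fitting range in Hz; starts at 3 Hz by default to avoid
#'   filter roll-off at the low edge.
#' @param robustIters number of mask-and-refit iterations (default 2).
#' @return an [AperiodicFit-class]. Non-convergence is returned as a
#'   flagged (`converged = FALSE`) fit, not an error, so cohort runs can
#'   skip the recording with a warning.
#' @examples
#' f <- seq(0.5, 30, 0.25)
#' ps <- new("PowerSpectrum", freqs = f,
#'           psd = aperiodicCurve(f, c(a = .1, b = 50, c = 10, d = 2)),
#'           df = 0.25, meta = list())
#' aperiodicParams(fitAperiodic(ps))
#' @export
fitAperiodic <- function(ps, fitRange = c(3, 30), robustIters = 2) {
  sel <- ps@freqs >= fitRange[1] & ps@freqs <= fitRange[2]
  f <- ps@freqs[sel]
  p <- ps@psd[sel]
  stopIf(any(p <= 0), "psd must be strictly positive over the fit range")
  y <- log10(p)
  dMax <- 6
  cMax <- 1e3
  resFull <- function(par, fv, yv)
    log10(pmax(par[1] + par[2] / (par[3] + fv^par[4]), 1e-300)) - yv
  resNoKnee <- function(par, fv, yv)
    log10(pmax(par[1] + par[2] * fv^(-par[3]), 1e-300)) - yv
  lmFit <- function(resFun, start, lower, upper, fv, yv) {
    ft <- try(minpack.lm::nls.lm(
      start, lower = lower, upper = upper, fn = resFun, fv = fv, yv = yv,
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(ft, "try-error")) return(NULL)
    list(par = ft$par, ok = all(is.finite(ft$par)),
         score = stats::mad(resFun(ft$par, f, y)))
  }
  bestOf <- function(fits) {
    fits <- Filter(Negate(is.null), fits)
    if (length(fits) == 0) return(NULL)
    fits[[which.min(vapply(fits, `[[`, numeric(1), "score"))]]
  }
  failed <- function() new(
    "AperiodicFit", params = c(a = NA_real_, b = NA_real_, c = NA_real_,
                               d = NA_real_),
    fitRange = fitRange, rmseLog = NA_real_, converged = FALSE)
  ## stage 1: knee-free fit localises the peaks without the degenerate
  ## knee basin; deterministic starts at exponents 1-3
  a0 <- max(min(p) * 0.5, 1e-6)
  s1 <- bestOf(lapply(c(1, 2, 3), function(d0)
    lmFit(resNoKnee, c(a0, max((p[1] - a0) * f[1]^d0, 1e-6), d0),
          lower = rep(0, 3), upper = c(Inf, Inf, dMax), fv = f, yv = y)))
  if (is.null(s1)) return(failed())
  dil <- round(0.75 / ps@df)
  maskFrom <- function(resid, prev) {
    bad <- resid > 2.5 * stats::mad(resid[prev])
    for (s in seq(-dil, dil)) {
      sh <- which(bad) + s
      bad[sh[sh >= 1 & sh <= length(bad)]] <- TRUE
    }
    !bad
  }
  mask <- maskFrom(-resNoKnee(s1$par, f, y), rep(TRUE, length(f)))
  if (sum(mask) < 8) mask <- rep(TRUE, length(f))
  ## stage 2: full knee model on the peak-masked support, knee started at
  ## three magnitudes
  startFull <- function(c0) {
    pr <- s1$par
    c(pr[1], pr[2], c0, pr[3])
  }
  best <- bestOf(lapply(c(0.1, 1, 10), function(c0)
    lmFit(resFull, startFull(c0), lower = rep(0, 4),
          upper = c(Inf, Inf, cMax, dMax), fv = f[mask], yv = y[mask])))
  if (is.null(best)) return(failed())
  ## robust iterations: re-derive the mask from the full model and refit
  for (it in seq_len(robustIters)) {
    mask <- maskFrom(-resFull(best$par, f, y), mask)
    if (sum(mask) < 8) break
    nxt <- lmFit(resFull, best$par, lower = rep(0, 4),
                 upper = c(Inf, Inf, cMax, dMax), fv = f[mask], yv = y[mask])
    if (!is.null(nxt)) best <- nxt
  }
  pars <- stats::setNames(best$par, c("a", "b", "c", "d"))
  new("AperiodicFit", params = pars, fitRange = fitRange,
      rmseLog = sqrt(mean(resFull(best$par, f[mask], y[mask])^2)),
      converged = isTRUE(best$ok) &&
        is.finite(sqrt(mean(resFull(best$par, f[mask], y[mask])^2))))
}

#' @describeIn aperiodicParams named parameter vector of a fit.
#' @export
setMethod("aperiodicParams", "AperiodicFit", function(object) object@params)

setMethod("show", "AperiodicFit", function(object) {
  p <- object@params
  cat(sprintf(
    "AperiodicFit: a=%.4g b=%.4g c=%.4g d=%.3f (%g-%g Hz, rmse=%.2e, %s)\n",
    p["a"], p["b"], p["c"], p["d"], object@fitRange[1], object@fitRange[2],
    object@rmseLog, if (object@converged) "converged" else "NOT converged"))
})

#' Decompose a spectrum into aperiodic and periodic components
#'
#' Evaluates the fitted background on the spectrum's grid and takes the
#' signed residual (in linear power, not log) as the periodic component,
#' so `raw = aperiodic + periodic` holds exactly on every grid point.
#' The residual is deliberately not floored at zero: flooring would bias
#' band powers.
#'
#' @param ps a [PowerSpectrum-class].
#' @param fit a converged [AperiodicFit-class] (default: fit `ps` with
#'   [fitAperiodic()]).
#' @param range grid range (Hz) of the decomposition, default the 0.5-30 Hz
#'   analysis band; keeps the evaluated model away from f = 0, where a
#'   kneeless fit diverges.
#' @return a [SpectralDecomposition-class].
#' @export
decomposeSpectrum <- function(ps, fit = fitAperiodic(ps),
                              range = c(0.5, 30)) {
  stopIf(!fit@converged, "aperiodic fit did not converge")
  sel <- ps@freqs >= range[1] - 1e-9 & ps@freqs <= range[2] + 1e-9
  fg <- ps@freqs[sel]
  ap <- aperiodicCurve(fg, fit@params)
  new("SpectralDecomposition", freqs = fg, raw = ps@psd[sel],
      aperiodic = ap, periodic = ps@psd[sel] - ap, fit = fit)
}

#' @describeIn freqs frequency grid of a decomposition.
#' @export
setMethod("freqs", "SpectralDecomposition", function(object) object@freqs)

setMethod("show", "SpectralDecomposition", function(object) {
  cat(sprintf("SpectralDecomposition: %d bins, %g-%g Hz\n",
              length(object@freqs), object@freqs[1],
              object@freqs[length(object@freqs)]))
  show(object@fit)
})

#' Component-wise relative band powers
#'
#' Integrates each component (raw, aperiodic, periodic) over `band` and
#' normalises all three by the raw total power over `totalBand`. The
#' shared raw denominator preserves additivity: the raw relative power is
#' exactly the sum of the aperiodic and periodic relative powers.
#'
#' @param dec a [SpectralDecomposition-class].
#' @param band numeric length 2, Hz.
#' @param totalBand normalisation range, Hz (default 0.5-30).
#' @return named numeric: `raw`, `aperiodic`, `periodic`.
#' @export
componentBandPower <- function(dec, band, totalBand = c(0.5, 30)) {
  iTot <- snapIdx(dec@freqs, totalBand[1]):snapIdx(dec@freqs, totalBand[2])
  tot <- trapz(dec@freqs[iTot], dec@raw[iTot])
  stopIf(tot <= 0, "raw total power is zero")
  i <- snapIdx(dec@freqs, band[1]):snapIdx(dec@freqs, band[2])
  fg <- dec@freqs[i]
  c(raw = trapz(fg, dec@raw[i]) / tot,
    aperiodic = trapz(fg, dec@aperiodic[i]) / tot,
    periodic = trapz(fg, dec@periodic[i]) / tot)
}
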