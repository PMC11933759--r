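#' @include simulate-psqi.R
NULL

#' Aperiodic model curve
#'
#' The 1/f-like background \eqn{a + b/(c + f^d)}: `a` is a constant offset
#' (uV^2/Hz), `b` a scale, `c` a knee parameter (the curve flattens for
#' \eqn{f^d \ll c}), and `d` the decay exponent.
#'
#' @param f frequencies in Hz.
#' @param params named numeric with `a`, `b`, `c`, `d`.
#' @return density values, uV^2/Hz.
#' @export
aperiodicCurve <- function(f, params) {
  unname(params["a"] + params["b"] / (params["c"] + f^params["d"]))
}

#' Construct a signal specification
#'
#' @param aperiodic named numeric `a`, `b`, `c`, `d` of the background curve.
#' @param oscillations data.frame with columns `center`, `amplitude`,
#'   `bandwidth`: Gaussian spectral bumps added to the background.
#' @param condition `"open"` or `"closed"`.
#' @param fs sampling rate, Hz (default 512).
#' @param duration recording length, seconds (default 180).
#' @return a validated [SignalSpec-class].
#' @export
signalSpec <- function(aperiodic, oscillations = data.frame(),
                       condition = "closed", fs = 512, duration = 180) {
  if (nrow(oscillations) == 0)
    oscillations <- data.frame(center = numeric(), amplitude = numeric(),
                               bandwidth = numeric())
  new("SignalSpec", fs = fs, duration = duration,
      aperiodic = aperiodic[c("a", "b", "c", "d")],
      oscillations = oscillations, condition = condition)
}

#' Target power spectral density of a specification
#'
#' Background curve plus the Gaussian bumps, evaluated on `f`.
#'
#' @param spec a [SignalSpec-class].
#' @param f frequencies in Hz.
#' @return density values, uV^2/Hz.
#' @export
targetPSD <- function(spec, f) {
  y <- aperiodicCurve(f, spec@aperiodic)
  osc <- spec@oscillations
  for (i in seq_len(nrow(osc)))
    y <- y + osc$amplitude[i] *
      exp(-(f - osc$center[i])^2 / (2 * osc$bandwidth[i]^2))
  y
}

## squared magnitude response of the emulated 4th-order device bandpass
## (0.5-30 Hz), applied to the synthesis target so that synthetic raw
## recordings look like the device's already-filtered output
deviceResponse <- function(f, fLo = 0.5, fHi = 30, order = 4) {
  lp <- 1 / (1 + (f / fHi)^(2 * order))
  hp <- ifelse(f <= 0, 0, 1 / (1 + (fLo / pmax(f, 1e-12))^(2 * order)))
  lp * hp
}

#' Synthesize one EEG channel
#'
#' Frequency-domain amplitude shaping of seeded Gaussian noise: complex
#' Fourier coefficients are drawn with variance proportional to the target
#' one-sided PSD (background + bumps, shaped by the emulated device
#' bandpass) and randomised phases, then inverse-transformed. The expected
#' multitaper PSD of the output equals the target curve over the passband.
#'
#' @param spec a [SignalSpec-class].
#' @param seed integer seed.
#' @param deviceFilter shape the target by the emulated 0.5-30 Hz device
#'   bandpass (default TRUE); set FALSE for idealised band-unlimited
#'   output, e.g. when validating spectral estimators against the bare
#'   model curve.
#' @return numeric vector of `fs * duration` samples, microvolts.
#' @examples
#' sp <- signalSpec(c(a = 0.08, b = 30, c = 1, d = 2),
#'                  data.frame(center = 10, amplitude = 0.8, bandwidth = 0.7))
#' x <- synthesizeEEG(sp, seed = 1)
#' @export
synthesizeEEG <- function(spec, seed, deviceFilter = TRUE) {
  validObject(spec)
  n <- round(spec@fs * spec@duration)
  f <- seq(0, spec@fs / 2, length.out = n %/% 2 + 1)
  inBand <- f >= 0.5 & f <= 30
  tgt <- targetPSD(spec, f)
  stopIf(any(tgt[inBand] <= 0),
         "target PSD must be positive over the 0.5-30 Hz analysis band")
  if (deviceFilter) tgt <- tgt * deviceResponse(f)
  tgt[1] <- 0                      # no DC
  withSeed(seed, {
    nf <- length(f)
    amp <- sqrt(tgt * spec@fs * n / 4)
    re <- stats::rnorm(nf) * amp
    im <- stats::rnorm(nf) * amp
    im[1] <- 0
    if (n %% 2 == 0) {             # real Nyquist bin
      im[nf] <- 0
      re[nf] <- re[nf] * sqrt(2)
    }
    spec_full <- complex(real = re, imaginary = im)
    full <- c(spec_full, Conj(rev(spec_full[2:(nf - (n %% 2 == 0))])))
    Re(stats::fft(full, inverse = TRUE)) / n
  })
}

#' Draw a spectrum-level PSD observation
#'
#' Fast mode for calibration loops and replicate studies: instead of
#' synthesising 180 s of samples and running the estimation chain, the
#' multitaper estimate is emulated directly as the target PSD times
#' independent Gamma(m, m) multipliers per frequency bin, where
#' `m = tapers * epochs` is the number of averaged eigenspectra (each
#' approximately a scaled chi-squared with 2 degrees of freedom).
#'
#' @param spec a [SignalSpec-class].
#' @param freqs frequency grid, Hz.
#' @param seed integer seed.
#' @param nAveraged number of averaged eigenspectra (default 225 = 5 tapers
#'   x 45 four-second epochs of a 180 s recording).
#' @param meta list of provenance metadata.
#' @return a [PowerSpectrum-class].
#' @export
samplePowerSpectrum <- function(spec, freqs = seq(0.5, 30, by = 0.25), seed,
                                nAveraged = 225, meta = list()) {
  tgt <- targetPSD(spec, freqs)
  stopIf(any(tgt <= 0), "target PSD must be positive on the grid")
  obs <- withSeed(seed,
    tgt * stats::rgamma(length(freqs), shape = nAveraged, rate = nAveraged))
  new("PowerSpectrum", freqs = freqs, psd = obs,
      df = freqs[2] - freqs[1],
      meta = c(meta, list(nAveraged = nAveraged, mode = "spectrum")))
}
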