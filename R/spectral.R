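#' @include preprocess.R
NULL

.dpssCache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` with time-bandwidth
#' product `nw` as eigenvectors of the standard symmetric tridiagonal
#' matrix, together with their spectral concentration in the band
#' `|f| <= nw/n` (evaluated by FFT quadrature). Tapers are unit-norm,
#' mutually orthogonal, and sign-fixed (non-negative mean for symmetric
#' orders, positive initial slope otherwise). Results are cached per
#' `(n, nw, k)`.
#'
#' @param n taper length in samples.
#' @param nw time-bandwidth product (default 3).
#' @param k number of tapers (default 5); must satisfy `k <= 2 * nw - 1`.
#' @return list with `tapers` (n x k matrix) and `concentrations`
#'   (length-k eigenvalue vector, all close to 1 for `k <= 2 nw - 1`).
#' @export
dpssTapers <- function(n, nw = 3, k = 5) {
  stopIf(k > 2 * nw - 1, "k=%d exceeds 2*nw-1=%g usable tapers", k,
         2 * nw - 1)
  stopIf(n <= k, "need n > k samples")
  key <- sprintf("%d_%g_%d", n, nw, k)
  if (!is.null(.dpssCache[[key]])) return(.dpssCache[[key]])
  w <- nw / n
  tt <- 0:(n - 1)
  A <- matrix(0, n, n)
  diag(A) <- ((n - 1 - 2 * tt) / 2)^2 * cos(2 * pi * w)
  off <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  A[cbind(1:(n - 1), 2:n)] <- off
  A[cbind(2:n, 1:(n - 1))] <- off
  ev <- eigen(A, symmetric = TRUE)
  h <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {           # deterministic polarity
    s <- sum(h[, j])
    if (abs(s) > 1e-8) {
      if (s < 0) h[, j] <- -h[, j]
    } else if (h[2, j] - h[1, j] < 0) h[, j] <- -h[, j]
  }
  nfft <- 2^ceiling(log2(8 * n))
  conc <- vapply(seq_len(k), function(j) {
    u <- abs(stats::fft(c(h[, j], rep(0, nfft - n))))^2
    fgrid <- (0:(nfft - 1)) / nfft
    inBand <- pmin(fgrid, 1 - fgrid) <= w
    sum(u[inBand]) / sum(u)
  }, numeric(1))
  out <- list(tapers = h, concentrations = conc)
  .dpssCache[[key]] <- out
  out
}

## average eigenspectra of a samples x epochs matrix over tapers and
## epochs; one mvfft call per taper keeps this vectorised
mtEigenspectra <- function(xm, tapers, fs) {
  n <- nrow(xm)
  nf <- n %/% 2 + 1
  acc <- numeric(nf)
  for (j in seq_len(ncol(tapers))) {
    X <- stats::mvfft(xm * tapers[, j])[seq_len(nf), , drop = FALSE]
    acc <- acc + rowSums(Mod(X)^2) / fs
  }
  p <- acc / (ncol(tapers) * ncol(xm))
  scale <- rep(2, nf)               # one-sided
  scale[1] <- 1
  if (n %% 2 == 0) scale[nf] <- 1
  p * scale
}

#' @describeIn multitaperPSD average over tapers and kept epochs of an
#'   [EpochSet-class]; returns a named list with one
#'   [PowerSpectrum-class] per channel. The one-sided density integrates
#'   to the (filtered) signal variance.
#' @param fs sampling rate in Hz (taken from the object for epoch sets).
#' @param nw time-bandwidth product (default 3).
#' @param k number of tapers (default 5).
#' @export
setMethod("multitaperPSD", "EpochSet", function(x, nw = 3, k = 5, ...) {
  kept <- which(x@keptMask)
  stopIf(length(kept) == 0, "no kept epochs")
  n <- dim(x@data)[1]
  tp <- dpssTapers(n, nw, k)$tapers
  fgrid <- seq(0, x@fs / 2, length.out = n %/% 2 + 1)
  chans <- seq_len(dim(x@data)[2])
  labs <- if (dim(x@data)[2] == 2) c("FP1", "FP2") else
    paste0("ch", chans)
  out <- lapply(chans, function(ch) {
    new("PowerSpectrum", freqs = fgrid,
        psd = mtEigenspectra(matrix(x@data[, ch, kept], nrow = n),
                             tp, x@fs),
        df = fgrid[2] - fgrid[1],
        meta = list(recordingId = x@recordingId, channel = labs[ch],
                    nEpochs = length(kept), nw = nw, k = k))
  })
  stats::setNames(out, labs)
})

#' @describeIn multitaperPSD single-channel matrix of epochs
#'   (samples x epochs); returns one [PowerSpectrum-class].
#' @export
setMethod("multitaperPSD", "matrix", function(x, fs, nw = 3, k = 5, ...) {
  n <- nrow(x)
  tp <- dpssTapers(n, nw, k)$tapers
  fgrid <- seq(0, fs / 2, length.out = n %/% 2 + 1)
  new("PowerSpectrum", freqs = fgrid, psd = mtEigenspectra(x, tp, fs),
      df = fgrid[2] - fgrid[1],
      meta = list(nEpochs = ncol(x), nw = nw, k = k))
})

#' Average two spectra across channels
#'
#' Pointwise arithmetic mean of the two prefrontal channels; grids must be
#' identical. Metadata channel becomes `"FP-mean"`.
#'
#' @param ps1,ps2 [PowerSpectrum-class] objects on identical grids.
#' @return a [PowerSpectrum-class].
#' @export
averageChannels <- function(ps1, ps2) {
  stopIf(length(ps1@freqs) != length(ps2@freqs) ||
           any(ps1@freqs != ps2@freqs),
         "frequency grids differ; spectra cannot be averaged")
  meta <- ps1@meta
  meta$channel <- "FP-mean"
  new("PowerSpectrum", freqs = ps1@freqs, psd = (ps1@psd + ps2@psd) / 2,
      df = ps1@df, meta = meta)
}

## snap a frequency to the nearest grid point
snapIdx <- function(freqs, f) which.min(abs(freqs - f))

#' Band power by trapezoidal integration
#'
#' Integrates the density between the band edges snapped to the nearest
#' grid frequencies (closed interval).
#'
#' @param ps a [PowerSpectrum-class].
#' @param band numeric length 2, Hz.
#' @return power in uV^2.
#' @export
bandPower <- function(ps, band) {
  i <- snapIdx(ps@freqs, band[1]):snapIdx(ps@freqs, band[2])
  trapz(ps@freqs[i], ps@psd[i])
}

#' Relative band power
#'
#' Band power divided by the total power over `totalBand` (default the
#' 0.5-30 Hz filtered range), both by trapezoidal integration on the
#' spectrum's grid. For a non-negative density the result lies in [0, 1].
#'
#' @param ps a [PowerSpectrum-class].
#' @param band numeric length 2, Hz; must lie within `totalBand`.
#' @param totalBand numeric length 2, Hz.
#' @return unitless fraction.
#' @examples
#' ps <- new("PowerSpectrum", freqs = seq(0.5, 30, 0.25),
#'           psd = rep(1, 119), df = 0.25, meta = list())
#' relativePower(ps, c(7, 8.5))   # 1.5 / 29.5
#' @export
relativePower <- function(ps, band, totalBand = c(0.5, 30)) {
  stopIf(band[1] < totalBand[1] - 1e-9 || band[2] > totalBand[2] + 1e-9,
         "band must lie within totalBand")
  stopIf(totalBand[1] < ps@freqs[1] - 1e-9 ||
           totalBand[2] > ps@freqs[length(ps@freqs)] + 1e-9,
         "totalBand outside the spectrum's grid")
  tot <- bandPower(ps, totalBand)
  stopIf(tot <= 0, "total power over (%g, %g) Hz is zero", totalBand[1],
         totalBand[2])
  bandPower(ps, band) / tot
}

#' Frequency-resolved relative power
#'
#' Relative power in contiguous fixed-width bins tiling `range`,
#' normalised by the total power over `totalBand`. With the default
#' settings the bins tile 5-30 Hz in 0.5 Hz steps.
#'
#' @param ps a [PowerSpectrum-class].
#' @param totalBand normalisation range, Hz.
#' @param binWidth bin width, Hz (default 0.5).
#' @param range tiled range, Hz (default `c(5, 30)`).
#' @return data.frame with `f_lo`, `f_hi`, `f_mid`, `relPower`.
#' @export
relativePowerSpectrum <- function(ps, totalBand = c(0.5, 30),
                                  binWidth = 0.5, range = c(5, 30)) {
  stopIf(ps@freqs[1] > range[1] || ps@freqs[length(ps@freqs)] < range[2],
         "grid does not cover the %g-%g Hz range", range[1], range[2])
  tot <- bandPower(ps, totalBand)
  stopIf(tot <= 0, "total power is zero")
  lo <- seq(range[1], range[2] - binWidth, by = binWidth)
  hi <- lo + binWidth
  rp <- vapply(seq_along(lo), function(i) {
    idx <- snapIdx(ps@freqs, lo[i]):snapIdx(ps@freqs, hi[i])
    trapz(ps@freqs[idx], ps@psd[idx]) / tot
  }, numeric(1))
  data.frame(f_lo = lo, f_hi = hi, f_mid = (lo + hi) / 2, relPower = rp)
}

#' Standard analysis bands
#'
#' The alpha band (8-13 Hz) and its three sub-bands: low alpha
#' (LA, 7-8.5 Hz), medium alpha (MA, 9-10.5 Hz), high alpha
#' (HA, 11-13 Hz).
#'
#' @return named list of length-2 numeric vectors (Hz).
#' @export
analysisBands <- function() {
  list(LA = c(7, 8.5), MA = c(9, 10.5), HA = c(11, 13), alpha = c(8, 13))
}

#' @describeIn freqs frequency grid of a spectrum.
#' @export
setMethod("freqs", "PowerSpectrum", function(object) object@freqs)

#' @describeIn psd density values of a spectrum.
#' @export
setMethod("psd", "PowerSpectrum", function(object) object@psd)

setMethod("show", "PowerSpectrum", function(object) {
  cat(sprintf("PowerSpectrum: %d bins, %g-%g Hz (df=%g)",
              length(object@freqs), object@freqs[1],
              object@freqs[length(object@freqs)], object@df))
  if (!is.null(object@meta$channel))
    cat(", channel", object@meta$channel)
  cat("\n")
})
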