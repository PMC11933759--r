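---
title: "Methods: prefrontal low-alpha EEG and sleep quality"
author: "sleepalpha"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prefrontal low-alpha EEG and sleep quality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepalpha)
```

## The question the pipeline answers

Subjective sleep quality, measured by the Pittsburgh Sleep Quality Index
(PSQI: seven component scores of 0-3, total 0-21, higher = worse sleep), is
tested for association with resting-state EEG recorded from two prefrontal
electrodes (FP1, FP2) by a portable device (512 Hz, 0.5-30 Hz bandpass,
about 3 minutes per eye condition). The cohort is longitudinal: three
monthly sessions with overlapping participation (27/25/40 participants per
month, 22 present in all three, 42 unique). The biomarker of interest is
the *relative power* of the low-alpha band (LA, 7-8.5 Hz), with medium
alpha (MA, 9-10.5 Hz) and high alpha (HA, 11-13 Hz) as specificity
controls, and the question of whether the association is carried by the
oscillatory (periodic) or broadband (aperiodic) part of the spectrum.

Because the underlying recordings are not publicly distributable, the
package pairs the analysis with a synthetic-cohort generator that encodes
the intended statistical structure as ground truth. Every claim the
analysis makes on real data corresponds to a recoverable parameter of the
generator, which is what the test suite exercises.

## Spectral estimation

Recordings are bandpass filtered (4th-order Butterworth, 0.5-30 Hz,
applied forward-backward so the filter is zero-phase), cut into
non-overlapping 4 s epochs, and screened for artifacts. Four-second epochs
give a 0.25 Hz spectral grid, which represents the half-integer band edges
(8.5, 10.5 Hz) exactly. The power spectral density of each epoch is
estimated with the multitaper method (time-bandwidth product `nw = 3`,
`k = 5` DPSS tapers, plain average over tapers); eigenspectra are averaged
over tapers and kept epochs, and the two channels are averaged pointwise
into an "FP-mean" spectrum. The one-sided density is scaled so that its
integral equals the variance of the filtered signal (checked to 5% in the
tests). DPSS tapers are computed from the standard tridiagonal
eigenproblem and cached per length; their orthonormality (to 1e-8) and
in-band concentration (> 0.9 for all five tapers) are asserted in the
property suite.

Artifact screening stands in for ocular-artifact removal, which is not
identifiable with two channels: an epoch is dropped if any sample exceeds
150 uV or if its peak-to-peak amplitude is a > 5 SD outlier across epochs.
On clean synthetic recordings the default thresholds reject essentially
nothing, and an injected 500 uV transient removes exactly its own epoch.

## Relative power

Relative power of a band is its integrated density divided by the total
integrated density over the analysis range, by trapezoidal integration
between band edges snapped to the spectral grid. The normalisation range
is a configuration parameter; the default is the device band 0.5-30 Hz,
which is the only choice that keeps the statistic interpretable as "share
of recorded power" and bounded in [0, 1]. The frequency-resolved analysis
uses contiguous 0.5 Hz bins tiling 5-30 Hz with the same denominator.

## Aperiodic/periodic decomposition

The spectrum is modelled as the sum of an aperiodic 1/f-like background

$$P_{ap}(f) = a + \frac{b}{c + f^{d}}$$

(`a` constant offset in uV^2/Hz, `b` scale, `c` knee, `d` exponent) and a
*periodic* component defined as the signed residual of the raw spectrum
after subtracting the fitted background. The residual is kept in linear
power and is not floored at zero, so the additive identity
`raw = aperiodic + periodic` holds exactly on the grid, and component band
powers — all normalised by the same raw total power — add up exactly.

The background is fitted by nonlinear least squares on log10 power over
3-30 Hz (starting at 3 Hz to stay clear of the high-pass edge), with all
parameters bounded non-negative. Two numerical safeguards proved
necessary and are deliberate design choices:

* **Staged fitting with bounded parameters.** The knee model has a
  degenerate basin in which `b`, `c` and `d` grow without bound while the
  curve approaches a plateau-plus-cliff that mimics the alpha bump, and a
  weakly identified large-knee ridge along which the parameters drift
  jointly. The fit therefore starts from a knee-free model
  `a + b f^{-d}` (three deterministic starts at exponents 1, 2, 3),
  uses its residuals to locate oscillatory peaks, then fits the full
  model with `d <= 6` and `c <= 1000`. Candidates are compared by the
  MAD of their residuals over the whole range, so a candidate cannot win
  by over-masking.
* **Peak masking with dilation.** Frequencies whose positive residual
  exceeds 2.5 x MAD are masked as oscillatory and the fit repeated
  (two robust iterations by default). The mask is dilated by +/-0.75 Hz
  because peak *tails* adjoin the detected cores; without dilation the
  sub-threshold tails of the 10 Hz bump leak into the background fit and
  manufacture a spurious eyes-open/closed difference in aperiodic band
  power (the paired effect size was about 0.15 without dilation and is
  statistically null with it).

On noise-free model spectra the fit recovers the generating curve to
machine precision; under realistic estimation noise the median exponent
error over `d` in [1, 3] is below 0.1 (asserted in the property suite).

## Statistics

Pearson correlations (two-sided t test, Fisher-z 95% CI) relate relative
band power to PSQI totals per month, pooled over months (each
participant-month recording is one observation, as in the scatter
construction the design follows; the repeated-measures dependence this
ignores is a documented simplification), per eye condition, for all
participants and for the 22-participant complete subgroup.
Frequency-resolved correlations are flagged at uncorrected p < .05; the
Bonferroni correction is reserved for the three cross-month comparisons,
which are paired tests on the participants shared by each month pair.
The eyes-closed alpha enhancement is tested within month by paired t
tests on raw, aperiodic, and periodic alpha relative power.

The sample-size operation searches the smallest `n` whose matched-pairs t
test reaches the target power, using the noncentral-t distribution with
noncentrality `dz * sqrt(n)`. With `dz = 0.65`, alpha = .05 and power
= .95 the one-tailed search returns exactly 28; the implementation takes
the number of tails as an explicit argument because the printed "beta of
0.05 with n = 28" is only consistent with the one-tailed convention.

## The synthetic cohort generator

The generator is first-class, tested code. It reproduces:

* the participation pattern above, via the unique membership partition
  implied by the printed counts (22 in all three months, 2 in months 1+2
  only, 3 in 1+3 only, 1 in 2+3 only, 14 in month 3 only);
* a latent standardised poor-sleep trait per participant with monthly
  jitter (sd 0.3), driving both PSQI scores and low-alpha power;
* PSQI scores from a graded-response model: each component's latent value
  loads 0.8 on the participant-month trait and is cut at thresholds
  (-0.2, 0.9, 1.8), giving a community-like marginal (total mean ~5.7,
  sd ~3.3 — the source study prints no PSQI distribution, so this is a
  free choice made once);
* EEG spectra as an aperiodic background `a + b/(c + f^d)` (defaults
  a = 0.08 uV^2/Hz, b = 30, c = 1, d = 2) plus Gaussian bumps: a
  low-alpha bump at 7.75 Hz (sigma 0.5 Hz) whose log-amplitude follows a
  latent variable correlated with the trait, a 10 Hz bump (sigma 0.7 Hz)
  carrying the eyes-closed enhancement (peak amplitude 0.85 closed vs
  0.30 open, lognormal sd 0.30), and a small 18 Hz beta bump;
* realistic variability: between-participant aperiodic scale/exponent
  spread (lognormal sd 0.4 on `b`, sd 0.15 on `d`) and within-subject
  recording-to-recording fluctuations (lognormal sd 0.25 on `b`, sd 0.09
  on `d`, lognormal 0.2 on `a`). The within-subject term matters: the two
  eye conditions are separate recordings minutes apart, and without
  test-retest-scale aperiodic fluctuation the paired aperiodic comparison
  becomes a near-noiseless test in which even a fraction-of-a-percent
  denominator shift is significant — contradicting the stable-background
  structure the generator is meant to encode. Aperiodic parameters are
  drawn from the same distribution in both conditions, so the open/closed
  difference is carried entirely by the periodic component in
  expectation.

Two output modes share identical generative parameters. *Time mode*
synthesises 180 s two-channel recordings by frequency-domain amplitude
shaping of seeded Gaussian noise (randomised phases), shaped by an
emulated device bandpass, and is the default for end-to-end tests.
*Spectrum mode* emulates the multitaper estimate directly as the target
density times independent Gamma(m, m) bin multipliers with
m = tapers x epochs = 225 averaged eigenspectra; it is orders of
magnitude faster and statistically equivalent for band-power analyses, so
calibration loops and the 50-replicate studies use it. Time mode differs
from spectrum mode in one known respect: the offline re-filtering rolls
off the top of the fit range, which biases the absolute aperiodic
exponent and adds a small negative bias to the paired aperiodic
comparison; both conditions share the filter, and the replicate-level
claims are made in spectrum mode.

The latent couplings between low-alpha amplitude and the trait are
`rhoClosed = 0.66` and `rhoOpen = 0.40`. These were calibrated once with
`calibrateCoupling()` (stochastic bisection with Monte-Carlo evaluation)
so that the *recovered* pooled correlations — after attenuation by PSQI
discretisation, amplitude-to-relative-power nonlinearity, and
spectral-estimation noise — land at the study-level values of 0.45
(eyes closed) and 0.26 (eyes open), and then frozen as package defaults.

Seeding is explicit everywhere: a master seed spawns one substream per
participant, month, condition and purpose through a stable string hash,
so cohorts are bit-identical per seed and independent of evaluation
order.

## Problem sizes and reproducibility

The replicate studies summarised by `replicateSummary()` use the full
default design (92 participant-month pairs, 184 recordings) over 50
seeded replicates in spectrum mode; the package's own acceptance checks
use those sizes. End-to-end time-mode checks use the full design once and
reduced designs (3-4 participants, 8-60 s recordings) for I/O and
preprocessing properties. Property tests use fixed seeds; stochastic
assertions are stated with margins consistent with their Monte-Carlo
error (for example, a true-null p > .05 rate has expectation 0.95, and
the suite requires >= 0.8 over 150 month-tests).

## What the synthetic cohort does and does not establish

Passing tests show that the pipeline recovers, with correct calibration,
the statistical structure the generator encodes: band-specific latent
correlations, an eyes-closed enhancement confined to the periodic
component, a stationary background across months. Real prefrontal EEG
additionally contains non-stationary oscillatory bursts, ocular and
muscle artifacts with structured spectra, device-specific noise floors,
and possibly month-level physiological drift — none of which the
generator emulates (oscillations are injected as stationary spectral
bumps because the analysis only consumes time-averaged spectra; artifact
injection is limited to optional large transients for testing the
rejection stage). Results on synthetic data therefore validate the
*computation*, not the empirical claim.

## Known limitations

* The algebraic form of the aperiodic model and its fitting domain are a
  documented choice (the standard offset-plus-knee parameterisation in
  linear power, fitted in log10 power); the model function sits behind a
  single interface and can be swapped.
* Pooled correlations ignore repeated-measures dependence, as in the
  design being replicated.
* The decomposition defines "periodic" purely as a residual; it does not
  model individual peaks, so periodic band power includes residual
  misfit of the background.
* With two frontal channels, true ocular artifact removal is not
  possible; the amplitude/peak-to-peak screen only removes gross
  transients.
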