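#' @include specfit.R
NULL

#' Pearson correlation with test and confidence interval
#'
#' Product-moment correlation with the two-sided t-test
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} and a 95\% Fisher-z confidence
#' interval.
#'
#' @param x,y numeric vectors of equal length, n >= 3, non-zero variance.
#' @return data.frame row: `r`, `p`, `n`, `ciLo`, `ciHi`.
#' @examples
#' pearsonCorr(1:10, (1:10) * 2 + rnorm(10))
#' @export
pearsonCorr <- function(x, y) {
  stopIf(length(x) != length(y), "x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  stopIf(n < 3, "need at least 3 complete pairs")
  stopIf(stats::sd(x) == 0 || stats::sd(y) == 0,
         "correlation undefined: zero variance")
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), n - 2)
  }
  ci <- if (abs(r) >= 1) c(r, r) else {
    z <- atanh(r)
    se <- 1 / sqrt(n - 3)
    tanh(z + c(-1, 1) * stats::qnorm(0.975) * se)
  }
  data.frame(r = r, p = p, n = n, ciLo = ci[1], ciHi = ci[2])
}

#' Paired t test
#'
#' \eqn{t = \bar d / (s_d / \sqrt n)} on the differences `a - b`, with
#' `df = n - 1` and a two-sided p-value.
#'
#' @param a,b numeric vectors of equal length, n >= 2.
#' @return data.frame row: `t`, `df`, `p`, `meanDiff`, `n`.
#' @export
pairedT <- function(a, b) {
  stopIf(length(a) != length(b), "a and b must have equal length")
  d <- a - b
  n <- length(d)
  stopIf(n < 2, "need at least 2 pairs")
  sdd <- stats::sd(d)
  stopIf(sdd == 0 && mean(d) != 0, "zero difference variance")
  t <- if (sdd == 0) 0 else mean(d) / (sdd / sqrt(n))
  data.frame(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1),
             meanDiff = mean(d), n = n)
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)` for a family of `m` comparisons; `m` may exceed
#' the number of p-values supplied.
#'
#' @param p numeric p-values.
#' @param m family size; default `length(p)`.
#' @return adjusted p-values.
#' @export
bonferroni <- function(p, m = length(p)) {
  stopIf(m < length(p), "m must be at least the number of tests")
  pmin(1, m * p)
}

#' Matched-pairs sample size by noncentral-t power search
#'
#' Smallest `n >= 2` whose matched-pairs t test reaches the target power
#' at standardised effect `dz`: the power at `n` is
#' \eqn{P(T' > t_{crit})} with `T'` noncentral t, `df = n - 1`,
#' noncentrality \eqn{dz \sqrt n}; two-tailed tests accumulate both
#' rejection regions.
#'
#' @param dz standardised mean difference (Cohen's dz), > 0.
#' @param alpha significance level (default 0.05).
#' @param power target power (default 0.95).
#' @param tails 1 or 2 (default 1).
#' @return integer sample size.
#' @examples
#' sampleSizeMatchedPairs(0.65, 0.05, 0.95, tails = 1)  # 28
#' @export
sampleSizeMatchedPairs <- function(dz, alpha = 0.05, power = 0.95,
                                   tails = 1) {
  stopIf(dz <= 0, "dz must be positive")
  stopIf(alpha <= 0 || alpha >= 1, "alpha must be in (0, 1)")
  stopIf(power <= 0 || power >= 1, "power must be in (0, 1)")
  stopIf(!tails %in% c(1, 2), "tails must be 1 or 2")
  powerAt <- function(n) {
    ncp <- dz * sqrt(n)
    if (tails == 1) {
      stats::pt(stats::qt(1 - alpha, n - 1), n - 1, ncp = ncp,
                lower.tail = FALSE)
    } else {
      tc <- stats::qt(1 - alpha / 2, n - 1)
      stats::pt(tc, n - 1, ncp = ncp, lower.tail = FALSE) +
        stats::pt(-tc, n - 1, ncp = ncp)
    }
  }
  n <- 2L
  while (powerAt(n) < power) n <- n + 1L
  n
}

#' Frequency-resolved correlation against PSQI
#'
#' One Pearson correlation per 0.5 Hz bin per month and condition
#' (significance flagged at uncorrected p < .05, as in frequency-dot
#' displays), plus the across-month mean-r spectrum per condition.
#'
#' @param binPowers data.frame with columns `participant`, `month`,
#'   `condition`, `f_lo`, `f_hi`, `f_mid`, `relPower` (one row per
#'   recording and bin, e.g. from [runPipeline()]'s internals).
#' @param psqi PSQI table with `participant`, `month`, `psqi_total`.
#' @return data.frame: `grouping` (`"month1"`.. or `"mean"`), `condition`,
#'   `f_mid`, `r`, `p`, `n`, `sig`.
#' @export
correlationSpectrum <- function(binPowers, psqi) {
  dat <- merge(binPowers, psqi[c("participant", "month", "psqi_total")],
               by = c("participant", "month"))
  out <- list()
  for (cond in sort(unique(dat$condition))) {
    sub <- dat[dat$condition == cond, ]
    perMonth <- list()
    for (m in sort(unique(sub$month))) {
      ms <- sub[sub$month == m, ]
      for (fm in sort(unique(ms$f_mid))) {
        cell <- ms[ms$f_mid == fm, ]
        ct <- pearsonCorr(cell$relPower, cell$psqi_total)
        row <- data.frame(grouping = paste0("month", m), condition = cond,
                          f_mid = fm, r = ct$r, p = ct$p, n = ct$n,
                          sig = ct$p < 0.05)
        out[[length(out) + 1L]] <- row
        perMonth[[length(perMonth) + 1L]] <- row
      }
    }
    pm <- do.call(rbind, perMonth)
    for (fm in sort(unique(pm$f_mid))) {
      rs <- pm$r[pm$f_mid == fm]
      pooled <- sub[sub$f_mid == fm, ]
      ct <- pearsonCorr(pooled$relPower, pooled$psqi_total)
      out[[length(out) + 1L]] <- data.frame(
        grouping = "mean", condition = cond, f_mid = fm, r = mean(rs),
        p = ct$p, n = ct$n, sig = ct$p < 0.05)
    }
  }
  do.call(rbind, out)
}

#' Band-level correlations against PSQI
#'
#' Pearson correlation between relative band power and PSQI total for
#' every combination of grouping (each month and pooled across months),
#' condition, subgroup (all participants, or only those present in all
#' three months), band, and spectral component. Pooled correlations treat
#' each participant-month recording as one observation.
#'
#' @param bandPowers data.frame with columns `participant`, `month`,
#'   `condition`, `band`, `component`, `relPower`.
#' @param psqi PSQI table with `participant`, `month`, `psqi_total`.
#' @param completeIds character ids of the complete-subgroup participants.
#' @return data.frame with one [pearsonCorr()] row per cell.
#' @export
bandCorrelations <- function(bandPowers, psqi, completeIds = character()) {
  dat <- merge(bandPowers, psqi[c("participant", "month", "psqi_total")],
               by = c("participant", "month"))
  out <- list()
  subgroups <- list(all = unique(dat$participant))
  if (length(completeIds)) subgroups$complete <- completeIds
  for (sg in names(subgroups)) {
    sdat <- dat[dat$participant %in% subgroups[[sg]], ]
    groupings <- c(paste0("month", sort(unique(sdat$month))), "pooled")
    for (g in groupings) for (cond in sort(unique(sdat$condition)))
      for (b in sort(unique(sdat$band)))
        for (cmp in sort(unique(sdat$component))) {
          cell <- sdat[sdat$condition == cond & sdat$band == b &
                         sdat$component == cmp, ]
          if (g != "pooled")
            cell <- cell[paste0("month", cell$month) == g, ]
          if (nrow(cell) < 3) next
          ct <- pearsonCorr(cell$relPower, cell$psqi_total)
          out[[length(out) + 1L]] <- cbind(
            data.frame(grouping = g, condition = cond, subgroup = sg,
                       band = b, component = cmp), ct)
        }
  }
  do.call(rbind, out)
}
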