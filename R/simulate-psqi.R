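#' @include cohort-design.R
NULL

## graded-response parameters for the synthetic PSQI: each of the 7
## components loads on the standardised participant-month trait and is cut
## at fixed thresholds into ordinal scores 0-3. Thresholds give a
## community-like marginal (total mean ~5.7, sd ~3.3).
psqiModel <- function() {
  list(loading = 0.8, thresholds = c(-0.2, 0.9, 1.8), nComponents = 7L)
}

#' Simulate latent traits for a design
#'
#' Draws one standardised poor-sleep propensity per participant and one
#' monthly deviation per attended month, each from its own seed substream
#' so results are independent of iteration order.
#'
#' @param design a [CohortDesign-class].
#' @param seed integer master seed.
#' @param jitterSd standard deviation of the monthly deviation (trait is
#'   standard normal); default 0.3.
#' @return named list of [LatentTrait-class] objects.
#' @export
simulateTraits <- function(design, seed, jitterSd = 0.3) {
  lapply(stats::setNames(nm = names(design@monthsPresent)), function(id) {
    months <- design@monthsPresent[[id]]
    tr <- withSeed(deriveSeed(seed, id, "trait"), stats::rnorm(1))
    jit <- vapply(months, function(m)
      withSeed(deriveSeed(seed, id, "jitter", m), stats::rnorm(1, 0, jitterSd)),
      numeric(1))
    new("LatentTrait", participantId = id, trait = tr,
        monthlyJitter = stats::setNames(jit, as.character(months)))
  })
}

## standardised participant-month latent state
latentState <- function(trait, month, jitterSd = 0.3) {
  j <- trait@monthlyJitter[as.character(month)]
  stopIf(is.na(j), "participant %s has no month %s", trait@participantId,
         month)
  unname((trait@trait + j) / sqrt(1 + jitterSd^2))
}

#' Generate one synthetic PSQI record
#'
#' Each of the 7 component scores is drawn from an ordinal graded-response
#' model that is monotone in the participant-month latent state
#' (trait + monthly jitter): the component latent is
#' `loading * z + sqrt(1 - loading^2) * noise`, cut at fixed thresholds
#' into 0-3. The total is the sum of components, so it lies in [0, 21] and
#' its expectation increases strictly with the trait.
#'
#' @param trait a [LatentTrait-class].
#' @param month month to score (must be attended).
#' @param seed integer seed for the record's substream.
#' @return one-row data.frame: `participant`, `month`, `psqi_c1` ..
#'   `psqi_c7`, `psqi_total`.
#' @examples
#' tr <- simulateTraits(defaultCohortDesign(), seed = 1)[["P01"]]
#' generatePsqi(tr, month = 1, seed = 7)
#' @export
generatePsqi <- function(trait, month, seed) {
  mod <- psqiModel()
  z <- latentState(trait, month)
  comp <- withSeed(seed, {
    u <- mod$loading * z +
      sqrt(1 - mod$loading^2) * stats::rnorm(mod$nComponents)
    findInterval(u, mod$thresholds)
  })
  rec <- data.frame(participant = trait@participantId,
                    month = as.integer(month))
  rec[paste0("psqi_c", seq_len(mod$nComponents))] <- as.list(as.integer(comp))
  rec$psqi_total <- as.integer(sum(comp))
  rec
}

#' Validate a PSQI table
#'
#' Checks component ranges (0-3 each), total range (0-21), and that each
#' total equals the sum of its components; violations name the offending
#' row.
#'
#' @param tab data.frame with columns `participant`, `month`,
#'   `psqi_c1`..`psqi_c7`, `psqi_total`.
#' @return the table, invisibly, if valid.
#' @export
validatePsqiTable <- function(tab) {
  need <- c("participant", "month", paste0("psqi_c", 1:7), "psqi_total")
  miss <- setdiff(need, names(tab))
  stopIf(length(miss) > 0, "PSQI table missing columns: %s",
         paste(miss, collapse = ", "))
  comp <- as.matrix(tab[paste0("psqi_c", 1:7)])
  bad <- which(apply(comp, 1, function(x) any(x < 0 | x > 3)))
  stopIf(length(bad) > 0,
         "PSQI component outside 0-3 in row(s): %s",
         paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(tab$psqi_total < 0 | tab$psqi_total > 21)
  stopIf(length(bad) > 0, "PSQI total outside 0-21 in row(s): %s",
         paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(rowSums(comp) != tab$psqi_total)
  stopIf(length(bad) > 0,
         "PSQI total does not equal component sum in row(s): %s",
         paste(utils::head(bad, 5), collapse = ", "))
  invisible(tab)
}
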