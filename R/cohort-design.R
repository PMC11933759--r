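#' @include utils.R
NULL

#' Construct a cohort participation design
#'
#' @param monthsPresent named list of integer month vectors (subsets of 1:3),
#'   one element per participant.
#' @return a validated [CohortDesign-class].
#' @examples
#' d <- cohortDesign(list(p1 = c(1, 2, 3), p2 = 3L))
#' designCounts(d)
#' @export
cohortDesign <- function(monthsPresent) {
  monthsPresent <- lapply(monthsPresent, function(m) sort(as.integer(m)))
  new("CohortDesign", monthsPresent = monthsPresent,
      nParticipants = length(monthsPresent))
}

#' Default three-month participation design
#'
#' The unique membership partition implied by the study's participation
#' counts: per-month 27/25/40, pairwise overlaps 24 (months 1 and 2),
#' 25 (1 and 3), 23 (2 and 3), 22 in all three months, and 42 unique
#' participants. By inclusion-exclusion this forces 22 participants in all
#' three months, 2 in months 1+2 only, 3 in months 1+3 only, 1 in months
#' 2+3 only, 14 in month 3 only, and none in month 1 or month 2 only.
#'
#' @return a [CohortDesign-class] with 42 participants.
#' @examples
#' designCounts(defaultCohortDesign())
#' @export
defaultCohortDesign <- function() {
  cells <- list(
    list(n = 22L, months = c(1L, 2L, 3L)),
    list(n = 2L,  months = c(1L, 2L)),
    list(n = 3L,  months = c(1L, 3L)),
    list(n = 1L,  months = c(2L, 3L)),
    list(n = 14L, months = 3L))
  mp <- list()
  i <- 0L
  for (cell in cells) for (k in seq_len(cell$n)) {
    i <- i + 1L
    mp[[sprintf("P%02d", i)]] <- cell$months
  }
  cohortDesign(mp)
}

#' Participation counts of a design
#'
#' Per-month counts, pairwise overlaps, triple overlap, and the union; the
#' inclusion-exclusion identity
#' \eqn{|U| = \sum n_i - \sum n_{ij} + n_{123}} holds for any valid design
#' because the counts are computed from one membership partition.
#'
#' @param design a [CohortDesign-class].
#' @return named integer vector: `m1`, `m2`, `m3`, `m12`, `m13`, `m23`,
#'   `m123`, `union`.
#' @export
designCounts <- function(design) {
  stopifnot(is(design, "CohortDesign"))
  has <- function(m) vapply(design@monthsPresent, function(x) all(m %in% x),
                            logical(1))
  c(m1 = sum(has(1L)), m2 = sum(has(2L)), m3 = sum(has(3L)),
    m12 = sum(has(c(1L, 2L))), m13 = sum(has(c(1L, 3L))),
    m23 = sum(has(c(2L, 3L))), m123 = sum(has(1:3)),
    union = design@nParticipants)
}

#' Participants present in every month
#' @param design a [CohortDesign-class].
#' @return character vector of participant ids.
#' @export
completeSubgroup <- function(design) {
  names(design@monthsPresent)[vapply(design@monthsPresent,
                                     function(x) all(1:3 %in% x), logical(1))]
}

setMethod("show", "CohortDesign", function(object) {
  ct <- designCounts(object)
  cat("CohortDesign:", ct["union"], "participants\n")
  cat(sprintf("  per month %d/%d/%d; overlaps 1&2=%d 1&3=%d 2&3=%d; all=%d\n",
              ct["m1"], ct["m2"], ct["m3"], ct["m12"], ct["m13"], ct["m23"],
              ct["m123"]))
})
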