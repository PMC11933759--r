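#' @include AllGenerics.R
NULL

## trapezoidal integral on an ordered grid
trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
}

## deterministic 31-bit seed derived from a master seed and a key path,
## so that every participant/month/condition gets its own stable substream
deriveSeed <- function(master, ...) {
  key <- paste(c(format(master), ...), collapse = "/")
  h <- 0
  for (cc in utf8ToInt(key)) h <- (h * 31 + cc) %% 2147483647
  as.integer(h)
}

## run expr under a local RNG state; restores the caller's stream
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## 31-bit polynomial hash of a character scalar, as 8 hex digits
hashString <- function(x) {
  h <- 0
  for (cc in utf8ToInt(x)) h <- (h * 31 + cc) %% 2147483647
  sprintf("%08x", h)
}

stopIf <- function(cond, ...) if (cond) stop(sprintf(...), call. = FALSE)

recId <- function(participant, month, condition)
  sprintf("%s_m%d_%s", participant, as.integer(month), condition)
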