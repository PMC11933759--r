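#' @include io-edf.R
NULL

#' Write a recording to disk
#'
#' `"csv"` writes the zero-dependency long format (columns `participant`,
#' `month`, `condition`, `channel`, `sample_index`, `microvolts`, full
#' float precision, exact round-trip); `"edf"` writes 16-bit EDF via
#' [writeEDF()].
#'
#' @param rec an [EEGRecording-class].
#' @param path output file.
#' @param format `"csv"` or `"edf"`.
#' @return `path`, invisibly.
#' @export
writeRecording <- function(rec, path, format = c("csv", "edf")) {
  format <- match.arg(format)
  if (format == "edf") return(writeEDF(rec, path))
  stopifnot(is(rec, "EEGRecording"))
  n <- nrow(rec@samples)
  long <- data.frame(
    participant = rec@participantId, month = rec@month,
    condition = rec@condition,
    channel = rep(rec@channels, each = n),
    sample_index = rep(seq_len(n), times = length(rec@channels)),
    microvolts = sprintf("%.17g", as.vector(rec@samples)))
  attr(long, "fs") <- rec@fs
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs_hz=%g", rec@fs), con)
  utils::write.csv(long, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a recording from disk
#'
#' @param path input file.
#' @param format `"csv"`, `"edf"`, or `"auto"` (by file extension).
#' @return a validated [EEGRecording-class]. Missing channels, mismatched
#'   channel lengths, or an unparseable header fail with a message naming
#'   the file and field.
#' @export
readRecording <- function(path, format = c("auto", "csv", "edf")) {
  format <- match.arg(format)
  stopIf(!file.exists(path), "file not found: %s", path)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (format == "edf") {
    rec <- readEDF(path)
    checkChannels(rec, path)
    return(rec)
  }
  first <- readLines(path, n = 1)
  stopIf(!grepl("^# fs_hz=", first), "%s: missing '# fs_hz=' header line",
         path)
  fs <- as.numeric(sub("^# fs_hz=", "", first))
  stopIf(is.na(fs), "%s: unparseable fs_hz header", path)
  tab <- utils::read.csv(path, comment.char = "#")
  need <- c("participant", "month", "condition", "channel", "sample_index",
            "microvolts")
  miss <- setdiff(need, names(tab))
  stopIf(length(miss) > 0, "%s: missing column(s) %s", path,
         paste(miss, collapse = ", "))
  chans <- unique(tab$channel)
  lens <- vapply(chans, function(ch) sum(tab$channel == ch), integer(1))
  stopIf(length(unique(lens)) != 1,
         "%s: channels have mismatched lengths (%s)", path,
         paste(sprintf("%s=%d", chans, lens), collapse = ", "))
  samples <- vapply(chans, function(ch) {
    sub <- tab[tab$channel == ch, ]
    sub$microvolts[order(sub$sample_index)]
  }, numeric(lens[1]))
  dimnames(samples) <- NULL
  rec <- new("EEGRecording", participantId = as.character(tab$participant[1]),
             month = as.integer(tab$month[1]),
             condition = as.character(tab$condition[1]),
             channels = as.character(chans), samples = samples, fs = fs)
  checkChannels(rec, path)
  rec
}

checkChannels <- function(rec, path) {
  miss <- setdiff(c("FP1", "FP2"), rec@channels)
  stopIf(length(miss) > 0, "%s: missing channel(s) %s", path,
         paste(miss, collapse = ", "))
  invisible(rec)
}

#' Read a PSQI cohort table
#'
#' Tab- or comma-separated table with columns `participant`, `month`,
#' `psqi_c1` .. `psqi_c7`, `psqi_total`. Totals are recomputed and checked
#' against the file; integrity violations name the row.
#'
#' @param path input file.
#' @return validated data.frame (possibly empty, with a warning).
#' @export
readPsqiTable <- function(path) {
  stopIf(!file.exists(path), "file not found: %s", path)
  sep <- if (grepl("\t", readLines(path, n = 1)[1])) "\t" else ","
  tab <- tryCatch(utils::read.table(path, header = TRUE, sep = sep),
                  error = function(e) data.frame())
  if (nrow(tab) == 0) {
    warning(sprintf("%s: empty PSQI table", path))
    return(tab)
  }
  validatePsqiTable(tab)
  tab
}

#' Write a PSQI cohort table as TSV
#' @param tab validated PSQI data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePsqiTable <- function(tab, path) {
  validatePsqiTable(tab)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a cohort to a directory
#'
#' One recording file per participant-month-condition plus `psqi.tsv`.
#' Only time-mode cohorts can be exported as recordings.
#'
#' @param cohort a [SleepCohort-class] in `"time"` mode.
#' @param dir output directory (created if needed).
#' @param format recording format, `"csv"` or `"edf"`.
#' @return character vector of written files, invisibly.
#' @export
writeCohort <- function(cohort, dir, format = c("csv", "edf")) {
  format <- match.arg(format)
  stopIf(cohort@mode != "time",
         "only time-mode cohorts have exportable recordings")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (rid in sort(names(cohort@recordings))) {
    p <- file.path(dir, paste0(rid, ".", format))
    writeRecording(cohort@recordings[[rid]], p, format)
    files <- c(files, p)
  }
  pp <- file.path(dir, "psqi.tsv")
  writePsqiTable(cohort@psqi, pp)
  invisible(c(files, pp))
}
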