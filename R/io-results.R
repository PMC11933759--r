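#' @include io-csv.R
NULL

## fixed float format so identical bundles produce byte-identical files
formatTable <- function(tab) {
  for (nm in names(tab))
    if (is.numeric(tab[[nm]]) && !is.integer(tab[[nm]]))
      tab[[nm]] <- sprintf("%.10g", tab[[nm]])
  tab
}

#' Write a result bundle to a directory
#'
#' Tables as CSV with deterministic names, row order, and float format;
#' run metadata as JSON; and a manifest listing every artifact with its
#' MD5 checksum. Writing the same bundle twice yields byte-identical
#' files.
#'
#' @param bundle a [ResultBundle-class].
#' @param outDir output directory (created if needed).
#' @return data.frame manifest (file, md5), invisibly.
#' @export
writeResults <- function(bundle, outDir) {
  stopifnot(is(bundle, "ResultBundle"))
  validObject(bundle)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stopIf(file.access(outDir, 2) != 0, "directory not writable: %s", outDir)
  files <- character()
  for (nm in c("bandPower", "corrBands", "corrSpectrum", "bergerTests",
               "monthTests")) {
    tab <- slot(bundle, nm)
    if (nrow(tab) == 0) next
    p <- file.path(outDir, paste0(nm, ".csv"))
    utils::write.csv(formatTable(tab), p, row.names = FALSE, quote = FALSE)
    files <- c(files, p)
  }
  mp <- file.path(outDir, "metadata.json")
  jsonlite::write_json(bundle@meta, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, mp)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

setMethod("show", "ResultBundle", function(object) {
  cat("ResultBundle\n")
  cat(sprintf("  band powers: %d rows; band correlations: %d rows\n",
              nrow(object@bandPower), nrow(object@corrBands)))
  cat(sprintf("  correlation spectrum: %d rows; paired tests: %d + %d rows\n",
              nrow(object@corrSpectrum), nrow(object@bergerTests),
              nrow(object@monthTests)))
  if (!is.null(object@meta$seed))
    cat(sprintf("  seed %s, config %s\n", object@meta$seed,
                object@meta$configHash))
})
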