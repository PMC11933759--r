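#' @include stats.R
NULL

#' Default pipeline configuration
#'
#' Nested list of every stage parameter: cohort coupling and generator
#' settings, filter cutoffs, epoching, artifact thresholds, taper
#' settings, aperiodic fit range, analysis bands, and normalisation range.
#' Unknown keys are rejected by [validateConfig()].
#'
#' @return nested configuration list.
#' @export
defaultConfig <- function() {
  list(
    mode = "simulate",
    seed = 1L,
    verbose = FALSE,
    design = "default",
    simulate = list(mode = "time"),
    coupling = defaultCoupling(),
    generator = defaultGeneratorParams(),
    filter = list(f_lo = 0.5, f_hi = 30, order = 4),
    epoch = list(length_s = 4, overlap = 0),
    artifact = list(amp_threshold_uv = 150, z_threshold = 5),
    taper = list(nw = 3, k = 5),
    fit = list(range = c(3, 30), robust_iters = 2),
    bands = analysisBands(),
    total_band = c(0.5, 30),
    corr_spectrum = list(bin_width = 0.5, range = c(5, 30)),
    decompose = TRUE,
    paths = list(recordings = NULL, psqi = NULL, out = NULL))
}

#' Validate a configuration against the schema
#'
#' Recursively checks `config` against [defaultConfig()]: unknown keys are
#' rejected, missing keys are filled with defaults.
#'
#' @param config nested list (possibly partial).
#' @return the completed configuration.
#' @export
validateConfig <- function(config) {
  mergeInto <- function(def, usr, path = "") {
    stopIf(is.null(names(usr)) && length(usr) > 0 && is.list(usr),
           "config section '%s' must be named", path)
    unknown <- setdiff(names(usr), names(def))
    stopIf(length(unknown) > 0, "unknown config key(s): %s",
           paste(paste0(path, unknown), collapse = ", "))
    for (nm in names(usr)) {
      if (is.list(def[[nm]]) && is.list(usr[[nm]]) &&
          !is.data.frame(def[[nm]])) {
        def[[nm]] <- mergeInto(def[[nm]], usr[[nm]],
                               paste0(path, nm, "$"))
      } else if (nm %in% c("paths") || !is.null(usr[[nm]])) {
        val <- usr[[nm]]
        if (is.numeric(def[[nm]]) && !is.null(names(def[[nm]])) &&
            is.list(val))
          val <- unlist(val)
        def[[nm]] <- val
      }
    }
    def
  }
  cfg <- mergeInto(defaultConfig(), config)
  stopIf(!cfg$mode %in% c("simulate", "analyze"),
         "mode must be 'simulate' or 'analyze'")
  stopIf(!cfg$simulate$mode %in% c("time", "spectrum"),
         "simulate$mode must be 'time' or 'spectrum'")
  cfg
}

#' Load a configuration file
#' @param path YAML or JSON configuration file.
#' @return validated configuration list.
#' @export
loadConfig <- function(path) {
  stopIf(!file.exists(path), "config file not found: %s", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  validateConfig(cfg)
}

## FP-mean spectrum of one recording (either representation)
recordingSpectrum <- function(rec, cfg) {
  if (is(rec, "PowerSpectrum")) return(rec)
  filt <- bandpassFilter(rec, cfg$filter$f_lo, cfg$filter$f_hi,
                         cfg$filter$order)
  ep <- epochRecording(filt, cfg$epoch$length_s, cfg$epoch$overlap)
  ep <- rejectArtifacts(ep, cfg$artifact$amp_threshold_uv,
                        cfg$artifact$z_threshold)
  chans <- multitaperPSD(ep, nw = cfg$taper$nw, k = cfg$taper$k)
  ps <- averageChannels(chans[["FP1"]], chans[["FP2"]])
  ps@meta$participant <- rec@participantId
  ps@meta$month <- rec@month
  ps@meta$condition <- rec@condition
  ps@meta$rejection <- ep@rejectionStats
  ps
}

analyzeRecordings <- function(recordings, psqi, cfg, design = NULL) {
  logmsg <- function(...) if (isTRUE(cfg$verbose)) message(sprintf(...))
  bandRows <- list(); binRows <- list(); skipped <- character()
  logmsg("analysing %d recordings", length(recordings))
  for (rid in sort(names(recordings))) {
    ps <- recordingSpectrum(recordings[[rid]], cfg)
    meta <- ps@meta
    base <- data.frame(participant = meta$participant,
                       month = meta$month, condition = meta$condition)
    bins <- relativePowerSpectrum(ps, cfg$total_band,
                                  cfg$corr_spectrum$bin_width,
                                  cfg$corr_spectrum$range)
    binRows[[rid]] <- cbind(base[rep(1, nrow(bins)), , drop = FALSE], bins)
    dec <- NULL
    if (isTRUE(cfg$decompose)) {
      fit <- fitAperiodic(ps, cfg$fit$range, cfg$fit$robust_iters)
      if (!fit@converged) {
        warning(sprintf("aperiodic fit failed for %s; skipping recording",
                        rid))
        skipped <- c(skipped, rid)
        next
      }
      dec <- decomposeSpectrum(ps, fit, range = cfg$total_band)
    }
    for (b in names(cfg$bands)) {
      if (is.null(dec)) {
        rp <- relativePower(ps, cfg$bands[[b]], cfg$total_band)
        bandRows[[paste(rid, b)]] <- cbind(base, data.frame(
          band = b, component = "raw", relPower = rp))
      } else {
        cp <- componentBandPower(dec, cfg$bands[[b]], cfg$total_band)
        bandRows[[paste(rid, b)]] <- cbind(
          base[rep(1, 3), , drop = FALSE],
          data.frame(band = b, component = names(cp),
                     relPower = unname(cp)))
      }
    }
  }
  bandPower <- do.call(rbind, unname(bandRows))
  binPowers <- do.call(rbind, unname(binRows))
  rownames(bandPower) <- rownames(binPowers) <- NULL
  ord <- order(bandPower$participant, bandPower$month, bandPower$condition,
               bandPower$band, bandPower$component)
  bandPower <- bandPower[ord, ]
  rownames(bandPower) <- NULL
  completeIds <- if (!is.null(design)) completeSubgroup(design) else {
    tab <- table(unique(psqi[c("participant", "month")])$participant)
    names(tab)[tab == 3]
  }
  logmsg("band-power rows: %d; correlating against %d PSQI records",
         nrow(bandPower), nrow(psqi))
  corrBands <- bandCorrelations(bandPower, psqi, completeIds)
  corrSpectrum <- correlationSpectrum(binPowers, psqi)
  ## paired eyes-closed vs eyes-open tests per month (alpha band)
  berger <- list()
  alpha <- bandPower[bandPower$band == "alpha", ]
  for (m in sort(unique(alpha$month))) for (cmp in unique(alpha$component)) {
    cl <- alpha[alpha$month == m & alpha$component == cmp &
                  alpha$condition == "closed", ]
    op <- alpha[alpha$month == m & alpha$component == cmp &
                  alpha$condition == "open", ]
    common <- intersect(cl$participant, op$participant)
    if (length(common) < 2) next
    cl <- cl[match(common, cl$participant), ]
    op <- op[match(common, op$participant), ]
    berger[[length(berger) + 1L]] <- cbind(
      data.frame(month = m, band = "alpha", component = cmp),
      pairedT(cl$relPower, op$relPower))
  }
  bergerTests <- do.call(rbind, berger)
  ## cross-month stability, Bonferroni over the three month pairs
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  mt <- list()
  for (cond in sort(unique(alpha$condition))) {
    raw <- alpha[alpha$component == "raw" & alpha$condition == cond, ]
    rows <- list()
    for (pr in pairs) {
      a <- raw[raw$month == pr[1], ]; b <- raw[raw$month == pr[2], ]
      common <- intersect(a$participant, b$participant)
      if (length(common) < 2) next
      a <- a[match(common, a$participant), ]
      b <- b[match(common, b$participant), ]
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(condition = cond,
                   pair = sprintf("m%d-m%d", pr[1], pr[2])),
        pairedT(a$relPower, b$relPower))
    }
    rows <- do.call(rbind, rows)
    rows$pAdj <- bonferroni(rows$p, m = 3)
    mt[[length(mt) + 1L]] <- rows
  }
  monthTests <- do.call(rbind, mt)
  list(bandPower = bandPower, binPowers = binPowers, corrBands = corrBands,
       corrSpectrum = corrSpectrum, bergerTests = bergerTests,
       monthTests = monthTests, skipped = skipped)
}

#' Run the end-to-end pipeline
#'
#' `simulate` mode generates the synthetic cohort and analyses it;
#' `analyze` mode reads recordings and a PSQI table from
#' `config$paths`. Either way the stages are: spectra (preprocessing +
#' multitaper for time-series recordings), relative band powers,
#' aperiodic/periodic decomposition (optional), band and per-frequency
#' correlations against PSQI, paired eyes-open/closed tests, and
#' cross-month comparisons. Deterministic given `(config, seed)`.
#'
#' @param config configuration list (see [defaultConfig()]), validated
#'   before any computation.
#' @return a [ResultBundle-class]. If `config$paths$out` is set the
#'   bundle is also written there via [writeResults()].
#' @examples
#' cfg <- list(simulate = list(mode = "spectrum"), seed = 3)
#' bundle <- runPipeline(cfg)
#' subset(bundle@corrBands, grouping == "pooled" & band == "LA" &
#'        component == "raw" & subgroup == "all")
#' @export
runPipeline <- function(config = list()) {
  cfg <- validateConfig(config)
  design <- NULL
  if (cfg$mode == "simulate") {
    design <- if (identical(cfg$design, "default")) defaultCohortDesign()
      else cohortDesign(cfg$design)
    cohort <- generateCohort(design, cfg$coupling, cfg$generator,
                             seed = cfg$seed, mode = cfg$simulate$mode)
    recordings <- cohort@recordings
    psqi <- cohort@psqi
  } else {
    dir <- cfg$paths$recordings
    stopIf(is.null(dir) || !dir.exists(dir),
           "analyze mode requires paths$recordings")
    files <- sort(list.files(dir, pattern = "\\.(csv|edf)$",
                             full.names = TRUE))
    files <- files[basename(files) != "psqi.tsv"]
    stopIf(length(files) == 0, "no recordings found in %s", dir)
    recordings <- lapply(files, readRecording)
    names(recordings) <- vapply(recordings, function(r)
      recId(r@participantId, r@month, r@condition), character(1))
    stopIf(is.null(cfg$paths$psqi), "analyze mode requires paths$psqi")
    psqi <- readPsqiTable(cfg$paths$psqi)
  }
  res <- analyzeRecordings(recordings, psqi, cfg, design)
  cfgJson <- jsonlite::toJSON(cfg[setdiff(names(cfg), "paths")],
                              auto_unbox = TRUE, digits = NA)
  bundle <- new("ResultBundle", bandPower = res$bandPower,
                corrBands = res$corrBands, corrSpectrum = res$corrSpectrum,
                bergerTests = res$bergerTests, monthTests = res$monthTests,
                meta = list(configHash = hashString(as.character(cfgJson)),
                            seed = cfg$seed,
                            package = as.character(utils::packageVersion(
                              "sleepalpha")),
                            mode = cfg$mode, simulateMode = cfg$simulate$mode,
                            nRecordings = length(recordings),
                            nSkipped = length(res$skipped)))
  if (!is.null(cfg$paths$out)) writeResults(bundle, cfg$paths$out)
  bundle
}

#' Headline statistics of a run
#'
#' The statistics tracked across replicates: pooled (all-months,
#' all-participants) correlations between raw relative band power and
#' PSQI for the three alpha sub-bands per condition, and the per-month
#' paired eyes-closed vs eyes-open p-values per spectral component.
#'
#' @param bundle a [ResultBundle-class].
#' @return one-row data.frame.
#' @export
headlineStats <- function(bundle) {
  cb <- bundle@corrBands
  pick <- function(band, cond, what = "r") {
    row <- cb[cb$grouping == "pooled" & cb$subgroup == "all" &
                cb$component == "raw" & cb$band == band &
                cb$condition == cond, ]
    row[[what]][1]
  }
  out <- data.frame(
    r_la_closed = pick("LA", "closed"), r_la_open = pick("LA", "open"),
    r_ma_closed = pick("MA", "closed"), p_ma_closed = pick("MA", "closed", "p"),
    r_ha_closed = pick("HA", "closed"), p_ha_closed = pick("HA", "closed", "p"),
    p_ma_open = pick("MA", "open", "p"), p_ha_open = pick("HA", "open", "p"))
  bt <- bundle@bergerTests
  for (i in seq_len(nrow(bt)))
    out[[sprintf("p_%s_m%d", bt$component[i], bt$month[i])]] <- bt$p[i]
  out
}

#' Replicate a simulate-mode run over derived seeds
#'
#' Re-runs the pipeline `nReplicates` times with per-replicate seeds
#' derived from `seed` and summarises the headline statistics.
#'
#' @param config configuration list (simulate mode).
#' @param nReplicates number of replicates (>= 1).
#' @param seed integer master seed.
#' @return list: `perReplicate` (one row per run), `summary`
#'   (mean and sd per statistic).
#' @export
replicateSummary <- function(config = list(), nReplicates = 1, seed = 1) {
  stopIf(nReplicates < 1, "nReplicates must be >= 1")
  cfg <- validateConfig(config)
  stopIf(cfg$mode != "simulate", "replicateSummary requires simulate mode")
  rows <- lapply(seq_len(nReplicates), function(i) {
    cfg$seed <- deriveSeed(seed, "replicate", i)
    cbind(data.frame(replicate = i, seed = cfg$seed),
          headlineStats(runPipeline(cfg)))
  })
  per <- do.call(rbind, rows)
  stats <- setdiff(names(per), c("replicate", "seed"))
  list(perReplicate = per,
       summary = data.frame(
         statistic = stats,
         mean = vapply(per[stats], mean, numeric(1)),
         sd = vapply(per[stats], stats::sd, numeric(1)),
         row.names = NULL))
}
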