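#' Validate and assemble a study configuration
#'
#' Checks the full simulate-to-statistics configuration before any work is
#' done; the resolved configuration (with the seed) is written next to every
#' run's outputs.
#'
#' @param nDyads number of dyads (>= 1).
#' @param days number of days (>= 1).
#' @param conditions study conditions.
#' @param duration session length in seconds.
#' @param fs sampling rate in Hz.
#' @param baseStrength interaction coupling strength.
#' @param schedule per-day multipliers (scalar recycled).
#' @param leader `"human"` or `"dog"`.
#' @param lag coupling lag in samples.
#' @param band analysis band in Hz.
#' @param regions regions analysed for coupling endpoints.
#' @param gpdcOrder MVAR order or `"auto"`.
#' @param gpdcBand GPDC summary band in cycles/sample.
#' @param threshold artifact amplitude threshold in uV.
#' @param cutoff low-pass cutoff in Hz.
#' @param channelsPerRegion montage size control.
#' @param artifactFraction fraction of each session contaminated by injected
#'   artifacts (0 = clean).
#' @param useANN train and apply the wavelet-ANN artifact classifier.
#' @return validated config list of class `studyConfig`.
#' @export
studyConfig <- function(nDyads = 2, days = 5, conditions = STUDY_CONDITIONS,
                        duration = 60, fs = 500, baseStrength = 0.8,
                        schedule = logisticSchedule(days), leader = "human",
                        lag = 0, band = c(4, 30),
                        regions = c("frontal", "parietal"),
                        gpdcOrder = "auto", gpdcBand = c(0.01, 0.4),
                        threshold = 300, cutoff = 245,
                        channelsPerRegion = 4, artifactFraction = 0,
                        useANN = FALSE) {
  if (nDyads < 1) stop("config error: nDyads must be >= 1")
  if (days < 1) stop("config error: days must be >= 1")
  if (duration < 10) stop("config error: duration must be >= 10 s")
  if (fs < 200) stop("config error: fs must be >= 200 Hz")
  if (baseStrength < 0 || baseStrength > 1)
    stop("config error: baseStrength must lie in [0, 1]")
  if (length(schedule) == 1) schedule <- rep(schedule, days)
  if (length(schedule) < days) stop("config error: schedule shorter than days")
  conditions <- match.arg(conditions, STUDY_CONDITIONS, several.ok = TRUE)
  if (artifactFraction < 0 || artifactFraction > 0.5)
    stop("config error: artifactFraction must lie in [0, 0.5]")
  structure(as.list(environment()), class = "studyConfig")
}

#' Run the full pipeline on a simulated study
#'
#' Orchestrates simulate -> preprocess -> spectrogram -> coupling -> GPDC ->
#' TBR -> statistics with one configuration and one seed. Sessions are
#' realized one at a time. All tables are written as CSV under `outDir`
#' together with a machine-readable run manifest.
#'
#' @param config a [studyConfig] list.
#' @param outDir output directory (created if needed), or `NULL` to skip
#'   writing.
#' @param seed master integer seed.
#' @return (invisibly) list with `coupling` (long coupling table), `gpdc`
#'   (per-session directed summaries), `tbr` (per-session region TBR),
#'   `stats` (statistics-layer results) and `manifest`.
#' @export
runStudyPipeline <- function(config, outDir = NULL, seed = 1) {
  stopifnot(inherits(config, "studyConfig"))
  mh <- defaultMontage("human", config$channelsPerRegion)
  md <- defaultMontage("dog", config$channelsPerRegion)
  desc <- buildStudy(config$nDyads, config$days, config$conditions,
                     schedule = config$schedule,
                     baseStrength = config$baseStrength,
                     leader = config$leader, lag = config$lag,
                     duration = config$duration, fs = config$fs, seed = seed,
                     montageHuman = mh, montageDog = md, realize = FALSE)
  clf <- NULL
  if (isTRUE(config$useANN)) {
    tr <- makeArtifactTrainingSet(600, fs = config$fs,
                                  seed = childSeed(seed, 999))
    clf <- trainArtifactANN(tr$features, ifelse(tr$isArtifact, "artifact",
                                                "clean"),
                            seed = childSeed(seed, 998))
  }
  cRows <- gRows <- tRows <- list()
  for (d in desc) {
    sess <- realizeSession(d)$session
    if (config$artifactFraction > 0) {
      for (who in c("human", "dog")) {
        rec <- slot(sess, who)
        ev <- randomArtifactEvents(rec, config$artifactFraction,
                                   seed = childSeed(d$seed,
                                                    match(who, c("human", "dog"))))
        slot(sess, who) <- injectArtifacts(rec, ev,
                                           seed = childSeed(d$seed, 5))$recording
      }
    }
    pp <- preprocessDyad(sess, classifier = clf, threshold = config$threshold,
                         cutoff = config$cutoff)
    sess <- pp$session
    sh <- peakNormalize(multitaperSpectrogram(sess@human,
                                              freqRange = config$band))
    sdg <- peakNormalize(multitaperSpectrogram(sess@dog,
                                               freqRange = config$band))
    rawH <- multitaperSpectrogram(sess@human, freqRange = config$band)
    rawD <- multitaperSpectrogram(sess@dog, freqRange = config$band)
    mH <- regionSeriesMatrix(sh, config$band)
    mD <- regionSeriesMatrix(sdg, config$band)
    ib <- interbrainMatrix(seriesHuman = mH, seriesDog = mD)
    base <- data.frame(dyad = d$dyad, day = d$day, condition = d$condition,
                       seed = d$seed, fraction_removed = pp$report@fractionRemoved,
                       stringsAsFactors = FALSE)
    cRows[[length(cRows) + 1]] <- cbind(base, ib$table)
    nWin <- nrow(mH)
    for (rg in config$regions) {
      if (nWin >= 120 && !anyNA(mH[, rg]) && !anyNA(mD[, rg])) {
        g <- dyadGPDC(seriesHuman = mH[, rg], seriesDog = mD[, rg],
                      region = rg, order = config$gpdcOrder,
                      band = config$gpdcBand)
        gRows[[length(gRows) + 1]] <- cbind(base, data.frame(
          region = rg, human_to_dog = g$humanToDog,
          dog_to_human = g$dogToHuman,
          order = g$result@model@p, stringsAsFactors = FALSE))
      }
      for (who in c("human", "dog")) {
        spec <- if (who == "human") rawH else rawD
        usable <- length(usableChannels(spec@montage, rg)) > 0
        if (!usable) next
        tb <- tbr(spec, region = rg)
        tRows[[length(tRows) + 1]] <- cbind(base, data.frame(
          subject = who, region = rg, mean_tbr = mean(tb, na.rm = TRUE),
          stringsAsFactors = FALSE))
      }
    }
  }
  coupling <- do.call(rbind, cRows)
  gpdcTab <- if (length(gRows)) do.call(rbind, gRows) else NULL
  tbrTab <- if (length(tRows)) do.call(rbind, tRows) else NULL

  ## statistics layer on the primary endpoints
  statsOut <- list()
  prim <- coupling[coupling$primary & coupling$condition == "interaction", ]
  if (nrow(prim) && length(unique(prim$day)) >= 2) {
    for (rg in config$regions) {
      sub <- prim[prim$region_A == rg, ]
      if (length(unique(sub$day)) >= 2 && nrow(sub) >= 3) {
        er <- exposureRegression(sub$r, sub$day)
        statsOut[[paste0("exposure_r_", rg)]] <-
          list(beta = er$beta, sem = er$sem, p = er$p, n = er$n)
      }
      blocks <- tryCatch(
        stats::xtabs(r ~ dyad + day, data = sub), error = function(e) NULL)
      if (!is.null(blocks) && nrow(blocks) >= 2 && ncol(blocks) >= 2 &&
          all(table(sub$dyad, sub$day) == 1)) {
        statsOut[[paste0("friedman_r_", rg)]] <-
          friedmanBlocks(matrix(as.numeric(blocks), nrow(blocks)))
      }
    }
    pvals <- vapply(statsOut[grep("^exposure", names(statsOut))],
                    function(x) x$p, 0)
    if (length(pvals))
      statsOut$holm_sidak_exposure <- holmSidak(pvals)
  }
  manifest <- list(
    package = "dyadsync",
    version = as.character(utils::packageVersion("dyadsync")),
    seed = seed, timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    config = config[setdiff(names(config), "")])
  out <- list(coupling = coupling, gpdc = gpdcTab, tbr = tbrTab,
              stats = statsOut, manifest = manifest)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(coupling, file.path(outDir, "coupling_table.csv"),
                     row.names = FALSE)
    if (!is.null(gpdcTab))
      utils::write.csv(gpdcTab, file.path(outDir, "gpdc_table.csv"),
                       row.names = FALSE)
    if (!is.null(tbrTab))
      utils::write.csv(tbrTab, file.path(outDir, "tbr_table.csv"),
                       row.names = FALSE)
    jsonlite::write_json(statsOut, file.path(outDir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  invisible(out)
}
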