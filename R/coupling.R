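#' Pearson product-moment correlation
#'
#' Standard correlation across time windows with explicit degenerate-input
#' handling: series with zero variance yield `NA` (reported as missing, not
#' zero).
#'
#' @param x,y numeric series of equal length >= 3.
#' @return correlation coefficient in \[-1,1\], or `NA` with attribute
#'   `reason` for degenerate input.
#' @export
pearsonR <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) {
    out <- NA_real_; attr(out, "reason") <- "fewer than 3 paired values"
    return(out)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    out <- NA_real_; attr(out, "reason") <- "zero variance"
    return(out)
  }
  stats::cor(x, y)
}

#' Interbrain correlation matrix of one session
#'
#' Pearson correlation between every (human region, dog region) pair of
#' mean-normalized power series, computed across time windows on the shared
#' excised timeline. Homologous pairs (frontal-frontal, parietal-parietal)
#' are the primary endpoints. Regions without usable channels (dog temporal)
#' give missing values.
#'
#' @param session a preprocessed [DyadSession-class], or `NULL` if
#'   `seriesHuman` / `seriesDog` are given.
#' @param band analysis band in Hz.
#' @param seriesHuman,seriesDog optional precomputed windows x regions
#'   matrices (see [regionSeriesMatrix]); skips the spectral step.
#' @return list with `matrix` (4 x 4 human-region x dog-region correlations)
#'   and `table` (long-format data.frame rows: region_A, region_B, r,
#'   n_windows, primary).
#' @export
interbrainMatrix <- function(session = NULL, band = c(4, 30),
                             seriesHuman = NULL, seriesDog = NULL) {
  if (is.null(seriesHuman) || is.null(seriesDog)) {
    stopifnot(is(session, "DyadSession"))
    sh <- peakNormalize(multitaperSpectrogram(session@human, freqRange = band))
    sd_ <- peakNormalize(multitaperSpectrogram(session@dog, freqRange = band))
    seriesHuman <- regionSeriesMatrix(sh, band)
    seriesDog <- regionSeriesMatrix(sd_, band)
  }
  M <- matrix(NA_real_, length(REGIONS), length(REGIONS),
              dimnames = list(human = REGIONS, dog = REGIONS))
  rows <- list()
  for (ra in REGIONS) for (rb in REGIONS) {
    r <- pearsonR(seriesHuman[, ra], seriesDog[, rb])
    M[ra, rb] <- as.numeric(r)
    rows[[length(rows) + 1]] <- data.frame(
      region_A = ra, region_B = rb, r = as.numeric(r),
      n_windows = sum(is.finite(seriesHuman[, ra]) &
                        is.finite(seriesDog[, rb])),
      primary = ra == rb & ra %in% c("frontal", "parietal"),
      stringsAsFactors = FALSE)
  }
  list(matrix = M, table = do.call(rbind, rows))
}

#' Long-format coupling table for a list of sessions
#'
#' Runs the spectral + correlation chain on every session and stacks the
#' results with the session metadata — the input of the statistics layer.
#'
#' @param sessions list of preprocessed [DyadSession-class] objects.
#' @param band analysis band in Hz.
#' @return data.frame with columns dyad, day, condition, region_A, region_B,
#'   r, n_windows, primary.
#' @export
couplingTable <- function(sessions, band = c(4, 30)) {
  rows <- lapply(sessions, function(s) {
    tab <- interbrainMatrix(s, band)$table
    m <- s@meta
    cbind(data.frame(dyad = m$dyad %||% NA, day = m$day %||% NA,
                     condition = m$condition %||% NA,
                     stringsAsFactors = FALSE),
          tab)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cross-session pseudo-pair null for interbrain correlation
#'
#' Pairs each human's region series with the dog series of every *other*
#' session (all mismatched combinations, truncated to the shortest series)
#' to form the null distribution of correlations that would arise without
#' mutual engagement, and compares the genuine within-session correlations
#' against it with a two-sided Mann-Whitney test.
#'
#' @param sessions list of >= 2 preprocessed [DyadSession-class] objects
#'   (typically the same condition and day).
#' @param region region whose series are compared (default frontal).
#' @param band analysis band in Hz.
#' @return list with `real` (within-session r values), `null` (mismatched-
#'   pair r values, length `m^2 - m` for m sessions), and `test` (the
#'   Mann-Whitney [TestResult][mannWhitney] row).
#' @export
pseudoPairNull <- function(sessions, region = "frontal", band = c(4, 30)) {
  if (length(sessions) < 2) stop("need at least 2 sessions for a pseudo-pair null")
  ser <- lapply(sessions, function(s) {
    sh <- peakNormalize(multitaperSpectrogram(s@human, freqRange = band))
    sd_ <- peakNormalize(multitaperSpectrogram(s@dog, freqRange = band))
    list(h = regionPowerSeries(sh, region, band),
         d = regionPowerSeries(sd_, region, band))
  })
  L <- min(vapply(ser, function(x) length(x$h), 0L))
  m <- length(ser)
  real <- vapply(seq_len(m), function(i)
    as.numeric(pearsonR(ser[[i]]$h[1:L], ser[[i]]$d[1:L])), 0)
  null <- numeric(0)
  for (i in seq_len(m)) for (j in seq_len(m)) if (i != j)
    null <- c(null, as.numeric(pearsonR(ser[[i]]$h[1:L], ser[[j]]$d[1:L])))
  test <- mannWhitney(real, null)
  list(real = real, null = null, test = test)
}
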