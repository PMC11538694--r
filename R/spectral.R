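## package-local cache for DPSS tapers and calibration constants
.dyadsyncCache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal sequences (Slepian tapers)
#'
#' Computed from the standard symmetric tridiagonal eigenproblem; unit-energy
#' tapers, most-concentrated first. Cached per (n, nw, k).
#'
#' @param n taper length in samples.
#' @param nw time half-bandwidth product (default 4).
#' @param k number of tapers (default `2 * nw - 1`).
#' @return n x k matrix of tapers.
#' @export
dpssTapers <- function(n, nw = 4, k = 2 * nw - 1) {
  key <- sprintf("dpss_%d_%g_%d", n, nw, k)
  if (!is.null(.dyadsyncCache[[key]])) return(.dyadsyncCache[[key]])
  w <- nw / n
  t <- 0:(n - 1)
  M <- matrix(0, n, n)
  diag(M) <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  off <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  M[cbind(1:(n - 1), 2:n)] <- off
  M[cbind(2:n, 1:(n - 1))] <- off
  e <- eigen(M, symmetric = TRUE)
  V <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    v <- V[, j] / sqrt(sum(V[, j]^2))
    if (sum(v) < 0) v <- -v                 # sign convention
    V[, j] <- v
  }
  .dyadsyncCache[[key]] <- V
  V
}

#' Windowed multitaper power spectrogram
#'
#' Power spectra of consecutive non-overlapping windows (default 1 s),
#' averaged over `k` DPSS tapers with time half-bandwidth product `nw`, at
#' the integer frequencies spanned by `freqRange` (default 4-30 Hz, i.e. 27
#' one-hertz bins for a 1-s window). Values are one-sided power spectral
#' density in uV^2/Hz; a trailing partial window is dropped.
#'
#' @param rec a [Recording-class].
#' @param window window length in seconds.
#' @param nw time half-bandwidth product.
#' @param k number of tapers.
#' @param freqRange integer frequency range in Hz, `c(lo, hi)`.
#' @return a [Spectrogram-class] (windows x frequencies x channels).
#' @export
multitaperSpectrogram <- function(rec, window = 1, nw = 4, k = 2 * nw - 1,
                                  freqRange = c(4, 30)) {
  stopifnot(is(rec, "Recording"))
  fs <- rec@fs
  wlen <- round(window * fs)
  n <- ncol(rec@samples)
  if (n < wlen) stop("recording shorter than one window")
  nW <- n %/% wlen
  freqs <- seq(freqRange[1], freqRange[2])
  V <- dpssTapers(wlen, nw = nw, k = k)
  ## DFT at the analysis bins via real matrix products (fast for few bins)
  tt <- 0:(wlen - 1)
  ER <- cos(-2 * pi * outer(tt, freqs) / fs)
  EI <- sin(-2 * pi * outer(tt, freqs) / fs)
  nch <- nrow(rec@samples)
  P <- array(0, c(nW, length(freqs), nch),
             dimnames = list(NULL, freqs, rec@montage@channels))
  for (c in seq_len(nch)) {
    W <- matrix(rec@samples[c, seq_len(nW * wlen)], wlen, nW)
    ## stack tapered copies column-wise: wlen x (nW * k)
    TW <- matrix(0, wlen, nW * k)
    for (j in seq_len(k))
      TW[, ((j - 1) * nW + 1):(j * nW)] <- W * V[, j]
    re <- crossprod(ER, TW)
    im <- crossprod(EI, TW)
    mag <- re^2 + im^2                     # nbins x (nW * k)
    acc <- mag[, 1:nW, drop = FALSE]
    if (k > 1) for (j in 2:k)
      acc <- acc + mag[, ((j - 1) * nW + 1):(j * nW), drop = FALSE]
    P[, , c] <- t(acc / k * 2 / fs)        # one-sided PSD
  }
  new("Spectrogram", power = P, freqs = as.numeric(freqs),
      windowTimes = (seq_len(nW) - 1) * window, fs = fs,
      montage = rec@montage, normalized = FALSE, meta = rec@meta)
}

#' Per-frequency peak normalization
#'
#' Divides the power at each frequency (and channel) by its maximum over
#' windows, putting all frequencies on an equal footing; all values end up
#' in \[0,1\] with at least one 1 per frequency. All-zero columns are left
#' as zeros.
#'
#' @param spec a [Spectrogram-class].
#' @return the normalized [Spectrogram-class]. Idempotent and invariant to
#'   positive rescaling of the input.
#' @export
peakNormalize <- function(spec) {
  stopifnot(is(spec, "Spectrogram"))
  P <- spec@power
  mx <- apply(P, c(2, 3), max)
  mx[mx == 0] <- 1                          # 0/0 guard: zero columns stay 0
  out <- spec
  out@power <- sweep(P, c(2, 3), mx, "/")
  out@normalized <- TRUE
  out
}

#' Region-averaged power time series
#'
#' Mean normalized power over a region's usable channels and the band's
#' frequency bins, one value per window: the series that feeds both the
#' interbrain correlation and the directed-coupling analysis.
#'
#' @param spec a (typically peak-normalized) [Spectrogram-class].
#' @param region region label.
#' @param band frequency band in Hz, `c(lo, hi)` inclusive.
#' @return numeric series (one value per window), or `NA` series with
#'   attribute `skipped = TRUE` if the region has no usable channels (e.g.
#'   the dog temporal region).
#' @export
regionPowerSeries <- function(spec, region, band = c(4, 30)) {
  stopifnot(is(spec, "Spectrogram"))
  ch <- match(usableChannels(spec@montage, region), spec@montage@channels)
  nWin <- dim(spec@power)[1]
  if (!length(ch)) {
    out <- rep(NA_real_, nWin)
    attr(out, "skipped") <- TRUE
    return(out)
  }
  sel <- spec@freqs >= band[1] & spec@freqs <= band[2]
  sub <- spec@power[, sel, ch, drop = FALSE]
  apply(sub, 1, mean)
}

#' All region series of a session as a matrix
#'
#' @param spec a [Spectrogram-class].
#' @param band frequency band in Hz.
#' @return windows x regions matrix (NA columns for skipped regions).
#' @export
regionSeriesMatrix <- function(spec, band = c(4, 30)) {
  out <- sapply(REGIONS, function(r) regionPowerSeries(spec, r, band))
  colnames(out) <- REGIONS
  out
}

## in-band capture fraction of the multitaper estimator for a band,
## calibrated from its response to unit-power sinusoids on a fine grid
bandCapture <- function(band, fs, window = 1, nw = 4, k = 2 * nw - 1) {
  key <- sprintf("cap_%g_%g_%g_%g_%g_%d", band[1], band[2], fs, window, nw, k)
  if (!is.null(.dyadsyncCache[[key]])) return(.dyadsyncCache[[key]])
  wlen <- round(window * fs)
  V <- dpssTapers(wlen, nw = nw, k = k)
  bins <- seq(band[1], band[2])
  tt <- 0:(wlen - 1)
  ER <- cos(-2 * pi * outer(tt, bins) / fs)
  EI <- sin(-2 * pi * outer(tt, bins) / fs)
  grid <- seq(band[1], band[2], by = 0.25)
  cap <- vapply(grid, function(f0) {
    x <- sqrt(2) * sin(2 * pi * f0 * tt / fs + 0.7)   # unit power
    TW <- V * x
    s <- 0
    for (j in seq_len(k)) {
      re <- crossprod(ER, TW[, j]); im <- crossprod(EI, TW[, j])
      s <- s + sum(re^2 + im^2)
    }
    s / k * 2 / fs
  }, 0)
  .dyadsyncCache[[key]] <- mean(cap)
  mean(cap)
}

#' Band power per window
#'
#' Sum of the (unnormalized) power spectral density over the band's 1-Hz
#' bins, averaged over the requested channels — an estimate of the in-band
#' signal power in uV^2 (bin spacing 1 Hz).
#'
#' @param spec an unnormalized [Spectrogram-class].
#' @param band band in Hz `c(lo, hi)` inclusive.
#' @param channels channel labels (default: all usable channels).
#' @param leakageCorrection divide by the estimator's in-band capture
#'   fraction (see Details in [tbr]).
#' @return numeric vector, one value per window.
#' @export
bandPower <- function(spec, band, channels = NULL, leakageCorrection = FALSE) {
  stopifnot(is(spec, "Spectrogram"))
  if (spec@normalized)
    warning("band power from a peak-normalized spectrogram is unitless")
  if (is.null(channels))
    channels <- setdiff(spec@montage@channels, spec@montage@excluded)
  channels <- match(channels, spec@montage@channels)
  if (anyNA(channels)) stop("unknown channel labels")
  sel <- spec@freqs >= band[1] & spec@freqs <= band[2]
  bp <- apply(spec@power[, sel, channels, drop = FALSE], 1, function(m) sum(m)) /
    length(channels)
  if (leakageCorrection)
    bp <- bp / bandCapture(band, spec@fs, nw = 4)
  bp
}

#' Theta/beta ratio series
#'
#' Per-window ratio of theta-band (4-8 Hz) to beta-band (13-30 Hz) power, the
#' standard EEG attention index (higher = less attentive). With a 1-s window
#' and NW = 4 the multitaper spectral window is 8 Hz wide, so a narrow band
#' like theta loses a substantial share of its power to leakage; by default
#' each band sum is divided by the estimator's in-band capture fraction
#' (calibrated once from the estimator's response to unit sinusoids), which
#' makes designed band-power ratios recoverable.
#'
#' @param spec an unnormalized [Spectrogram-class].
#' @param channels channels to average (default: usable channels of a region
#'   or the whole montage).
#' @param region optional region label (overrides `channels`).
#' @param thetaBand,betaBand band limits in Hz.
#' @param leakageCorrection apply the capture-fraction correction.
#' @return numeric vector of per-window TBR values; windows with zero beta
#'   power are `NA` (attribute `nInvalid` counts them).
#' @export
tbr <- function(spec, channels = NULL, region = NULL,
                thetaBand = c(4, 8), betaBand = c(13, 30),
                leakageCorrection = TRUE) {
  stopifnot(is(spec, "Spectrogram"))
  if (!is.null(region)) {
    channels <- usableChannels(spec@montage, region)
    if (!length(channels)) stop(sprintf("no usable channels in region '%s'", region))
  }
  th <- bandPower(spec, thetaBand, channels, leakageCorrection)
  be <- bandPower(spec, betaBand, channels, leakageCorrection)
  bad <- be <= 0
  if (mean(!bad) < 0.9)
    warning("beta power is zero in more than 10% of windows")
  out <- ifelse(bad, NA_real_, th / be)
  attr(out, "nInvalid") <- sum(bad)
  out
}

#' Baseline-normalized TBR
#'
#' Divides a TBR series by the mean TBR of the same subject's no-interaction
#' baseline, so 1 means "as attentive as baseline" and values below 1 mean
#' increased attention.
#'
#' @param tbrSeries TBR series of the condition of interest.
#' @param baselineSeries TBR series of the baseline condition.
#' @return normalized series.
#' @export
normalizeTBR <- function(tbrSeries, baselineSeries) {
  b <- mean(baselineSeries, na.rm = TRUE)
  if (!is.finite(b) || b <= 0) stop("invalid TBR baseline")
  as.numeric(tbrSeries) / b
}
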