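#' Zero-phase Butterworth low-pass filter
#'
#' Applies the squared Butterworth magnitude response
#' `|H(f)|^2 = 1 / (1 + (f/fc)^(2 * order))` — the forward-backward
#' (zero-phase) convention — in the frequency domain with reflection padding.
#' DC gain is exactly 1. A cutoff above Nyquist is an error; a cutoff equal
#' to Nyquist is permitted with a warning (gain 0.25 at the band edge, i.e.
#' essentially a formality at fs = 500 Hz).
#'
#' @param rec a [Recording-class].
#' @param order filter order (default 10).
#' @param cutoff cutoff frequency in Hz (default 245).
#' @return the filtered [Recording-class].
#' @export
lowpassFilter <- function(rec, order = 10, cutoff = 245) {
  stopifnot(is(rec, "Recording"))
  nyq <- rec@fs / 2
  if (cutoff > nyq)
    stop(sprintf("cutoff %g Hz exceeds the Nyquist frequency (%g Hz)", cutoff, nyq))
  if (cutoff == nyq)
    warning(sprintf("cutoff equals the Nyquist frequency (%g Hz); the filter is near-allpass", nyq))
  X <- rec@samples
  n <- ncol(X)
  pad <- min(n - 1, 2 * round(rec@fs))
  ## reflect ends to suppress circular wrap-around
  idxL <- (pad + 1):2
  idxR <- (n - 1):(n - pad)
  nn <- n + 2 * pad
  f <- c(0:(floor(nn / 2)), -((ceiling(nn / 2) - 1):1)) * rec@fs / nn
  gain <- 1 / (1 + (abs(f) / cutoff)^(2 * order))   # |H|^2: zero-phase
  Y <- X
  for (c in seq_len(nrow(X))) {
    xp <- c(X[c, idxL], X[c, ], X[c, idxR])
    yp <- Re(stats::fft(stats::fft(xp) * gain, inverse = TRUE)) / nn
    Y[c, ] <- yp[(pad + 1):(pad + n)]
  }
  out <- rec
  out@samples <- Y
  out
}

#' Remove per-channel linear trends
#'
#' Least-squares line (intercept + slope) subtracted from every channel;
#' the output has zero mean and zero slope per channel.
#'
#' @param rec a [Recording-class].
#' @return the detrended [Recording-class].
#' @export
detrendRecording <- function(rec) {
  stopifnot(is(rec, "Recording"))
  n <- ncol(rec@samples)
  if (n < 2) stop("need at least 2 samples to detrend")
  t <- seq_len(n) - (n + 1) / 2          # centered time
  st2 <- sum(t^2)
  X <- rec@samples
  mu <- rowMeans(X)
  slope <- (X %*% t) / st2
  out <- rec
  out@samples <- X - outer(as.numeric(slope), t) - mu
  out
}

#' Flag windows containing large-amplitude samples
#'
#' Any whole window of `window` seconds containing a sample with
#' `|v| > threshold` on any analysis (non-excluded) channel is flagged on the
#' channel-agnostic shared timeline. The comparison is strict.
#'
#' @param rec a [Recording-class].
#' @param threshold amplitude threshold in microvolts (default 300).
#' @param window window length in seconds (default 1).
#' @return integer vector of flagged window indices (1-based), with
#'   attribute `nWindows`.
#' @export
detectAmplitudeArtifacts <- function(rec, threshold = 300, window = 1) {
  stopifnot(is(rec, "Recording"), threshold > 0)
  wlen <- round(window * rec@fs)
  n <- ncol(rec@samples)
  nW <- n %/% wlen
  use <- match(setdiff(rec@montage@channels, rec@montage@excluded),
               rec@montage@channels)
  X <- abs(rec@samples[use, seq_len(nW * wlen), drop = FALSE])
  ## max over channels then over samples within window
  colmax <- apply(X, 2, max)
  wmax <- vapply(seq_len(nW), function(w)
    max(colmax[((w - 1) * wlen + 1):(w * wlen)]), 0)
  flagged <- which(wmax > threshold)
  attr(flagged, "nWindows") <- nW
  flagged
}

#' Excise flagged windows and join the trace ends
#'
#' Removes the flagged whole windows from every channel and concatenates the
#' remaining segments (gaps are closed by joining, never interpolated).
#' Sample order outside the flags is preserved. Samples beyond the last whole
#' window are kept.
#'
#' @param rec a [Recording-class].
#' @param flagged integer indices of 1-s windows to remove (as returned by
#'   [detectAmplitudeArtifacts] or [detectArtifacts]).
#' @param window window length in seconds.
#' @return list with `recording` (shortened [Recording-class]) and `report`
#'   (an [ArtifactReport-class]).
#' @export
exciseAndJoin <- function(rec, flagged, window = 1) {
  stopifnot(is(rec, "Recording"))
  wlen <- round(window * rec@fs)
  n <- ncol(rec@samples)
  nW <- n %/% wlen
  flagged <- sort(unique(as.integer(flagged)))
  if (length(flagged) && (min(flagged) < 1 || max(flagged) > nW))
    stop("flagged windows out of bounds")
  if (length(flagged) == nW) stop("no usable data: all windows flagged")
  drop <- unlist(lapply(flagged, function(w) ((w - 1) * wlen + 1):(w * wlen)))
  keep <- if (length(drop)) setdiff(seq_len(n), drop) else seq_len(n)
  out <- rec
  out@samples <- rec@samples[, keep, drop = FALSE]
  out@validMask <- rec@validMask[keep]
  perKind <- c(total = length(flagged))
  report <- new("ArtifactReport", flagged = flagged, nWindows = as.integer(nW),
                fractionRemoved = length(flagged) / nW,
                perKind = as.integer(perKind))
  names(report@perKind) <- names(perKind)
  list(recording = out, report = report)
}

#' Combined artifact detector (amplitude rule + ANN)
#'
#' Unions the strict >300 uV amplitude rule with the wavelet-feature neural
#' network classifier, evaluated per channel per 1-s window; a window is
#' flagged if any analysis channel is classified artifactual.
#'
#' @param rec a [Recording-class].
#' @param classifier an artifact classifier from [trainArtifactANN], or
#'   `NULL` for the amplitude rule alone.
#' @param threshold amplitude threshold in microvolts.
#' @param window window length in seconds.
#' @param probThreshold posterior above which a channel "votes" artifact;
#'   the ANN flags a window when at least `minChannels` channels vote.
#' @param strictThreshold posterior above which a single channel suffices,
#'   provided that channel-window is also a variance outlier against the
#'   channel's own per-window spread (ratio outside
#'   `[1/varOutlierFactor^2, varOutlierFactor]`). The conjunction catches
#'   one-channel electrode faults — flat, step, or noisy segments are
#'   variance-extreme — without inheriting the posterior tail noise a plain
#'   single-channel threshold suffers across training runs.
#' @param minChannels concordant channels required at `probThreshold`.
#' @param varOutlierFactor upper ratio of window SD to the channel's median
#'   window SD regarded as an outlier (default 4; the lower bound is its
#'   squared reciprocal).
#' @return integer vector of flagged window indices with attributes
#'   `nWindows` and `perKind`.
#' @export
detectArtifacts <- function(rec, classifier = NULL, threshold = 300,
                            window = 1, probThreshold = 0.5,
                            strictThreshold = 0.9995, minChannels = 3,
                            varOutlierFactor = 4) {
  amp <- detectAmplitudeArtifacts(rec, threshold = threshold, window = window)
  nW <- attr(amp, "nWindows")
  annFlag <- integer()
  if (!is.null(classifier)) {
    ap <- annChannelProbs(rec, classifier, window = window)
    votes <- colSums(ap > probThreshold)
    use <- match(setdiff(rec@montage@channels, rec@montage@excluded),
                 rec@montage@channels)
    wlen <- round(window * rec@fs)
    X <- rec@samples[use, seq_len(nW * wlen), drop = FALSE]
    winSD <- sqrt(sapply(seq_len(nW), function(w) {
      seg <- X[, ((w - 1) * wlen + 1):(w * wlen), drop = FALSE]
      rowMeans(seg^2) - rowMeans(seg)^2
    }))
    if (is.null(dim(winSD))) winSD <- matrix(winSD, nrow = 1)
    medSD <- apply(winSD, 1, stats::median)
    ratio <- winSD / pmax(medSD, .Machine$double.eps)
    outlier <- ratio > varOutlierFactor | ratio < 1 / varOutlierFactor^2
    strict <- colSums(ap > strictThreshold & outlier) >= 1
    annFlag <- which(votes >= minChannels | strict)
  }
  flagged <- sort(union(as.integer(amp), annFlag))
  attr(flagged, "nWindows") <- nW
  attr(flagged, "perKind") <- c(amplitude = length(amp), ann = length(annFlag))
  flagged
}

#' Preprocess a dyad session
#'
#' Runs the cleaning chain on both subjects: low-pass filter, detrend,
#' artifact detection (amplitude rule plus optional ANN), then joint
#' excision. Flags are unioned across the two subjects so both traces lose
#' the same windows and stay aligned for interbrain analysis.
#'
#' @param session a [DyadSession-class].
#' @param classifier optional artifact classifier ([trainArtifactANN]).
#' @param threshold amplitude threshold (uV).
#' @param cutoff low-pass cutoff (Hz).
#' @param order low-pass filter order.
#' @return list with `session` (cleaned, shortened [DyadSession-class]) and
#'   `report` (joint [ArtifactReport-class]).
#' @export
preprocessDyad <- function(session, classifier = NULL, threshold = 300,
                           cutoff = 245, order = 10) {
  stopifnot(is(session, "DyadSession"))
  h <- detrendRecording(lowpassFilter(session@human, order, cutoff))
  d <- detrendRecording(lowpassFilter(session@dog, order, cutoff))
  fh <- detectArtifacts(h, classifier, threshold = threshold)
  fd <- detectArtifacts(d, classifier, threshold = threshold)
  joint <- sort(union(as.integer(fh), as.integer(fd)))
  nW <- attr(fh, "nWindows")
  eh <- exciseAndJoin(h, joint)
  ed <- exciseAndJoin(d, joint)
  out <- session
  out@human <- eh$recording
  out@dog <- ed$recording
  perKind <- attr(fh, "perKind") + attr(fd, "perKind")
  report <- new("ArtifactReport", flagged = joint, nWindows = as.integer(nW),
                fractionRemoved = length(joint) / nW,
                perKind = as.integer(perKind))
  names(report@perKind) <- names(perKind)
  list(session = out, report = report)
}
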