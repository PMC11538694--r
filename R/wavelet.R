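## Daubechies-4 (8-tap) orthonormal scaling filter
DB4_H <- c(0.230377813308855, 0.714846570552542, 0.630880767929590,
           -0.027983769416984, -0.187034811718881, 0.030841381835987,
           0.032883011666983, -0.010597401784997)

## one level of the periodic pyramid: x (even length) -> list(approx, detail)
dwtStep <- function(x, h) {
  n <- length(x)
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)      # quadrature mirror filter
  half <- n / 2
  a <- d <- numeric(half)
  idx <- outer(2 * seq_len(half) - 2, seq_len(L) - 1, "+") %% n + 1
  xm <- matrix(x[idx], half, L)
  a <- as.numeric(xm %*% h)
  d <- as.numeric(xm %*% g)
  list(approx = a, detail = d)
}

#' Discrete wavelet decomposition (periodic, Daubechies-4)
#'
#' Pyramid transform with the 8-tap Daubechies filter. The input is
#' zero-padded to the next power of two, which leaves the transform
#' orthonormal on the padded signal (energy is conserved exactly).
#'
#' @param x numeric vector.
#' @param levels decomposition depth (default 5).
#' @return list with `details` (list of detail coefficient vectors, finest
#'   first) and `approx` (coarsest approximation).
#' @export
dwt <- function(x, levels = 5) {
  n2 <- 2^ceiling(log2(length(x)))
  if (n2 > length(x)) x <- c(x, numeric(n2 - length(x)))
  if (2^levels > n2) stop("too many levels for this segment length")
  details <- vector("list", levels)
  a <- x
  for (l in seq_len(levels)) {
    s <- dwtStep(a, DB4_H)
    details[[l]] <- s$detail
    a <- s$approx
  }
  list(details = details, approx = a)
}

#' Wavelet + spectral features of a 1-s segment
#'
#' Per-channel feature vector used by the artifact classifier: relative
#' wavelet energies per level (finest detail first, coarse approximation
#' last), log variance, excess kurtosis, log peak amplitude, the share of
#' power near the mains frequencies (49-51 and 59-61 Hz), the share below
#' 4 Hz, the share above 30 Hz, and a zero-energy flag. A zero segment gets
#' all relative energies 0 and the flag set to 1 (defined 0/0 fallback).
#'
#' @param segment numeric vector (one channel) or channels x samples matrix;
#'   length must equal `fs` (one second).
#' @param fs sampling rate in Hz.
#' @param levels wavelet decomposition depth.
#' @param aggregate if `TRUE` and `segment` is a matrix, average the feature
#'   vectors over channels; otherwise return a channels x features matrix.
#' @return named numeric vector (or matrix) of features.
#' @export
waveletFeatures <- function(segment, fs = 500, levels = 5, aggregate = FALSE) {
  if (is.matrix(segment)) {
    F <- t(apply(segment, 1, waveletFeatures, fs = fs, levels = levels))
    if (aggregate) return(colMeans(F))
    return(F)
  }
  if (length(segment) < fs) stop("segment shorter than one second")
  x <- as.numeric(segment[seq_len(fs)])
  w <- dwt(x, levels = levels)
  en <- c(vapply(w$details, function(d) sum(d^2), 0), sum(w$approx^2))
  tot <- sum(en)
  zero <- as.numeric(tot <= .Machine$double.eps)
  rel <- if (zero) numeric(length(en)) else en / tot
  ## periodogram-based band shares
  P <- Mod(stats::fft(x))^2
  nf <- floor(fs / 2)
  freqs <- (0:(length(x) - 1)) * fs / length(x)
  pos <- freqs > 0 & freqs <= nf
  Pp <- P[pos]; fp <- freqs[pos]
  ptot <- sum(Pp)
  share <- function(sel) if (ptot <= 0) 0 else sum(Pp[sel]) / ptot
  lineShare <- share((fp >= 49 & fp <= 51) | (fp >= 59 & fp <= 61))
  lowShare <- share(fp < 4)
  hiShare <- share(fp > 30)
  v <- stats::var(x)
  kurt <- if (v <= 0) 0 else mean((x - mean(x))^4) / v^2 - 3
  out <- c(rel, log1p(v), kurt, log1p(max(abs(x))), lineShare, lowShare,
           hiShare, zero)
  names(out) <- c(paste0("e_d", seq_len(levels)), "e_a",
                  "logVar", "kurtosis", "logPeak", "lineShare", "lowShare",
                  "hiShare", "zeroFlag")
  out
}
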