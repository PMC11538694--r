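#' Generalized partial directed coherence from a fitted MVAR model
#'
#' For each frequency `f` (cycles/sample) the spectral coefficient matrix is
#' `Abar(f) = I - sum_r A_r exp(-i 2 pi f r)`. The innovation-variance
#' weighted, column-normalized GPDC is
#' `G[i<-j](f) = (|Abar_ij(f)| / sigma_i) / sqrt(sum_k |Abar_kj(f)|^2 / sigma_k^2)`
#' with `sigma_i^2 = SIG_ii`, so that `sum_i G[i<-j](f)^2 = 1` for every
#' source column j at every frequency. The transfer function
#' `H = Abar^{-1}`, spectral density `S = H SIG H^H` and magnitude-squared
#' coherence `C_ij = |S_ij|^2 / (S_ii S_jj)` are computed alongside.
#'
#' @param model an [MVARModel-class].
#' @param freqs frequency grid in cycles/sample (default 129 points over
#'   0-0.5).
#' @param band band summarized into `bandSummary` (cycles/sample).
#' @return a [GPDCResult-class].
#' @export
gpdc <- function(model, freqs = seq(0, 0.5, length.out = 129),
                 band = c(0.01, 0.4)) {
  stopifnot(is(model, "MVARModel"))
  if (!isTRUE(model@diagnostics$stable))
    warning("computing GPDC from an unstable MVAR fit")
  k <- model@k; p <- model@p
  SIG <- model@SIG
  sig <- sqrt(diag(SIG))
  if (any(sig <= 0)) stop("singular innovation covariance")
  nf <- length(freqs)
  G <- array(0, c(nf, k, k))
  H <- array(complex(real = 0), c(nf, k, k))
  S <- array(complex(real = 0), c(nf, k, k))
  C <- array(0, c(nf, k, k))
  I <- diag(k)
  for (fi in seq_len(nf)) {
    f <- freqs[fi]
    Abar <- I
    for (r in seq_len(p))
      Abar <- Abar - model@A[, , r] * exp(-2i * pi * f * r)
    ## GPDC: column-normalized, innovation-variance weighted
    W <- Mod(Abar) / sig                  # rows scaled by 1/sigma_i
    cn <- sqrt(colSums(W^2))
    G[fi, , ] <- sweep(W, 2, cn, "/")
    Hf <- tryCatch(solve(Abar), error = function(e)
      stop(sprintf("singular spectral coefficient matrix at f = %g", f)))
    Sf <- Hf %*% SIG %*% Conj(t(Hf))
    H[fi, , ] <- Hf
    S[fi, , ] <- Sf
    dS <- Re(diag(Sf))
    C[fi, , ] <- Mod(Sf)^2 / outer(dS, dS)
  }
  sel <- freqs >= band[1] & freqs <= band[2]
  bs <- apply(G[sel, , , drop = FALSE], c(2, 3), mean)
  dimnames(bs) <- list(to = colnames(model@SIG), from = colnames(model@SIG))
  out <- new("GPDCResult", G = G, freqs = freqs, bandSummary = bs,
             H = H, S = S, model = model, band = band)
  out@C <- C   # assigned post hoc: `C =` would partial-match new()'s Class arg
  out
}

#' Directed interbrain coupling of one dyad session
#'
#' Fits a bivariate MVAR to the (human, dog) region power series — sampled
#' at one value per second on the excised shared timeline — and summarizes
#' GPDC in both directions over the envelope-fluctuation band.
#'
#' @param session a preprocessed [DyadSession-class], or `NULL` when
#'   `seriesHuman`/`seriesDog` are supplied directly.
#' @param region `"frontal"` or `"parietal"` (any region with usable
#'   channels on both subjects).
#' @param order MVAR order or `"auto"` (BIC).
#' @param band summary band in cycles/sample of the 1 Hz-sampled envelope
#'   series.
#' @param minWindows minimum series length required (default 120).
#' @param seriesHuman,seriesDog optional precomputed region series.
#' @return list with `humanToDog`, `dogToHuman` (band-mean GPDC), and
#'   `result` (the full [GPDCResult-class]; series order is human = 1,
#'   dog = 2).
#' @export
dyadGPDC <- function(session = NULL, region = "frontal", order = "auto",
                     band = c(0.01, 0.4), minWindows = 120,
                     seriesHuman = NULL, seriesDog = NULL) {
  if (is.null(seriesHuman) || is.null(seriesDog)) {
    stopifnot(is(session, "DyadSession"))
    sh <- peakNormalize(multitaperSpectrogram(session@human))
    sd_ <- peakNormalize(multitaperSpectrogram(session@dog))
    seriesHuman <- regionPowerSeries(sh, region)
    seriesDog <- regionPowerSeries(sd_, region)
  }
  if (anyNA(seriesHuman) || anyNA(seriesDog))
    stop(sprintf("region '%s' has no usable series for both subjects", region))
  if (length(seriesHuman) < minWindows)
    stop(sprintf("insufficient windows: %d < %d", length(seriesHuman), minWindows))
  Y <- cbind(human = seriesHuman, dog = seriesDog)
  model <- fitMVAR(Y, p = order)
  colnames(model@SIG) <- rownames(model@SIG) <- colnames(Y)
  res <- gpdc(model, band = band)
  list(humanToDog = res@bandSummary[2, 1],
       dogToHuman = res@bandSummary[1, 2],
       result = res)
}
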