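#' Fit a multivariate autoregressive model
#'
#' Multivariate least squares on lagged regressors: each demeaned series is
#' regressed on `p` lags of all series; `SIG` is the residual covariance.
#' With `p = "auto"` the order is selected by BIC over `1..pmax` (all
#' candidates scored on the common sample aligned at `pmax`, the winner
#' refitted on the full sample). Stability is checked via the companion
#' matrix spectral radius.
#'
#' @param Y numeric matrix, time x series (k columns), or a vector.
#' @param p integer model order, or `"auto"`.
#' @param pmax maximum order considered for `"auto"` (default 20).
#' @param demean subtract column means first (default TRUE).
#' @return an [MVARModel-class]; a warning is raised (and
#'   `diagnostics$stable` set `FALSE`) for an unstable fit.
#' @export
fitMVAR <- function(Y, p = "auto", pmax = 20, demean = TRUE) {
  Y <- as.matrix(Y)
  k <- ncol(Y)
  n <- nrow(Y)
  if (demean) Y <- sweep(Y, 2, colMeans(Y))
  auto <- identical(p, "auto")
  if (auto) {
    pmax <- max(1, min(pmax, floor(n / (10 * k))))
    bics <- vapply(seq_len(pmax), function(pp)
      mvarBIC(Y, pp, align = pmax), 0)
    p <- which.min(bics)
  } else {
    p <- as.integer(p)
    bics <- NULL
  }
  if (n < 10 * k * p)
    warning(sprintf("short series: n = %d < 10*k*p = %d", n, 10 * k * p))
  fit <- mvarLS(Y, p)
  lam <- companionSpectralRadius(fit$A)
  stable <- lam < 1
  if (!stable) warning(sprintf("fitted MVAR is unstable (spectral radius %.3f)", lam))
  new("MVARModel", A = fit$A, SIG = fit$SIG, p = p, k = k, n = n,
      diagnostics = list(stable = stable, spectralRadius = lam,
                         bic = if (auto) bics[p] else mvarBIC(Y, p, align = p),
                         orderGrid = bics))
}

## least-squares VAR(p) fit on demeaned Y; returns A (k x k x p) and SIG
mvarLS <- function(Y, p, align = p) {
  k <- ncol(Y); n <- nrow(Y)
  if (n <= align + k * p) stop("rank-deficient design: series too short for this order")
  rows <- (align + 1):n
  X <- do.call(cbind, lapply(seq_len(p), function(r) Y[rows - r, , drop = FALSE]))
  Z <- Y[rows, , drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("rank-deficient regressors in MVAR fit")
  B <- qr.coef(qrX, Z)                     # (k*p) x k
  res <- Z - X %*% B
  SIG <- crossprod(res) / (nrow(Z) - k * p)
  SIG <- (SIG + t(SIG)) / 2
  A <- array(0, c(k, k, p))
  for (r in seq_len(p))
    A[, , r] <- t(B[((r - 1) * k + 1):(r * k), , drop = FALSE])
  list(A = A, SIG = SIG, res = res)
}

mvarBIC <- function(Y, p, align = p) {
  k <- ncol(Y)
  fit <- mvarLS(Y, p, align = align)
  neff <- nrow(Y) - align
  SIGml <- crossprod(fit$res) / neff
  dt <- determinant(SIGml, logarithm = TRUE)
  as.numeric(dt$modulus) + k * k * p * log(neff) / neff
}

companionSpectralRadius <- function(A) {
  k <- dim(A)[1]; p <- dim(A)[3]
  Comp <- matrix(0, k * p, k * p)
  for (r in seq_len(p)) Comp[1:k, ((r - 1) * k + 1):(r * k)] <- A[, , r]
  if (p > 1)
    Comp[(k + 1):(k * p), 1:(k * (p - 1))] <- diag(k * (p - 1))
  max(Mod(eigen(Comp, only.values = TRUE)$values))
}

#' Simulate a stable VAR process
#'
#' Utility for validation: draws `n` observations from
#' `y_t = sum_r A_r y_{t-r} + e_t` with Gaussian innovations.
#'
#' @param n length of the returned series (after burn-in).
#' @param A coefficient array k x k x p (a matrix is taken as p = 1).
#' @param SIG innovation covariance (default identity).
#' @param burn burn-in samples.
#' @return n x k matrix.
#' @export
simulateVAR <- function(n, A, SIG = NULL, burn = 200) {
  if (is.matrix(A)) A <- array(A, c(nrow(A), ncol(A), 1))
  k <- dim(A)[1]; p <- dim(A)[3]
  if (is.null(SIG)) SIG <- diag(k)
  Lc <- chol(SIG)
  N <- n + burn
  E <- matrix(stats::rnorm(N * k), N, k) %*% Lc
  Y <- matrix(0, N, k)
  for (t in (p + 1):N) {
    acc <- E[t, ]
    for (r in seq_len(p)) acc <- acc + A[, , r] %*% Y[t - r, ]
    Y[t, ] <- acc
  }
  Y[(burn + 1):N, , drop = FALSE]
}
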