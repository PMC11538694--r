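# independent brute-force oracles shared across test files

# Friedman statistic from the rank formula with midranks and tie correction
bruteFriedman <- function(m) {
  R <- t(apply(m, 1, rank))
  n <- nrow(m); k <- ncol(m)
  Rj <- colSums(R)
  num <- (12 / (n * k * (k + 1))) * sum((Rj - n * (k + 1) / 2)^2)
  ties <- apply(m, 1, function(row) {
    tt <- table(row); sum(tt^3 - tt)
  })
  corr <- 1 - sum(ties) / (n * k * (k^2 - 1))
  if (corr == 0) return(0)
  num / corr
}

# exact two-sided Mann-Whitney p by enumerating group assignments of the
# observed values and counting pair wins (a different computational path
# from the implementation, which enumerates rank sums)
bruteMW <- function(x, y) {
  v <- c(x, y)
  nx <- length(x)
  uStat <- function(ix) {
    a <- v[ix]; b <- v[-ix]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  Uobs <- uStat(seq_len(nx))
  mu <- nx * length(y) / 2
  cols <- utils::combn(length(v), nx)
  Us <- apply(cols, 2, uStat)
  mean(abs(Us - mu) >= abs(Uobs - mu) - 1e-12)
}

# hand product-moment correlation
brutePearson <- function(x, y) {
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  num / den
}
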