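test_that("white noise fits to a near-zero AR coefficient", {
  set.seed(61)
  m <- fitMVAR(matrix(rnorm(2000), ncol = 1), p = 1)
  expect_lt(abs(m@A[1, 1, 1]), 0.1)
})

test_that("a known VAR(2) is recovered by least squares", {
  A <- array(0, c(2, 2, 2))
  A[, , 1] <- matrix(c(0.5, 0.2, -0.1, 0.4), 2)
  A[, , 2] <- matrix(c(-0.2, 0.1, 0.15, -0.25), 2)
  set.seed(62)
  Y <- simulateVAR(5000, A)
  m <- fitMVAR(Y, p = 2)
  # oracle: the generating coefficients
  expect_lt(max(abs(m@A - A)), 0.05)
  expect_true(m@diagnostics$stable)
  expect_equal(m@SIG, t(m@SIG))
})

test_that("BIC selects the generating order for VAR(3) data", {
  A <- array(0, c(2, 2, 3))
  A[, , 1] <- matrix(c(0.4, 0.1, 0, 0.3), 2)
  A[, , 3] <- matrix(c(0.25, -0.2, 0.15, 0.2), 2)
  hits <- 0
  for (i in 1:25) {
    set.seed(600 + i)
    Y <- simulateVAR(2000, A)
    m <- fitMVAR(Y, p = "auto")
    hits <- hits + (m@p == 3)
  }
  expect_gte(hits / 25, 0.8)
})

test_that("unstable models are flagged with a warning", {
  A <- matrix(c(1.05, 0, 0, 0.2), 2)
  SIG <- diag(2)
  mdl <- suppressWarnings(
    new("MVARModel", A = array(A, c(2, 2, 1)), SIG = SIG, p = 1, k = 2,
        n = 100, diagnostics = list(stable = FALSE,
                                    spectralRadius = 1.05)))
  expect_warning(gpdc(mdl), "unstable")
  expect_warning(fitMVAR(matrix(rnorm(15), ncol = 1), p = 2), "short")
})

test_that("GPDC of independent AR processes has no cross terms", {
  A <- array(0, c(2, 2, 1))
  A[1, 1, 1] <- 0.6; A[2, 2, 1] <- -0.4
  set.seed(64)
  Y <- simulateVAR(10000, A)
  m <- fitMVAR(Y, p = 1)
  g <- gpdc(m)
  offdiag <- c(g@G[, 1, 2], g@G[, 2, 1])
  expect_lt(max(offdiag), 0.05)
})

test_that("unidirectional VAR(1) gives the closed-form directed pattern", {
  A <- array(0, c(2, 2, 1))
  A[1, 1, 1] <- 0.5; A[2, 1, 1] <- 0.5; A[2, 2, 1] <- 0.3
  mdl <- new("MVARModel", A = A, SIG = diag(2), p = 1, k = 2, n = 1e4,
             diagnostics = list(stable = TRUE, spectralRadius = 0.5))
  g <- gpdc(mdl)
  expect_gt(bandSummary(g)[2, 1], 0.3)      # 1 -> 2 present
  expect_lt(bandSummary(g)[1, 2], 0.05)     # 2 -> 1 absent
})

test_that("GPDC columns are exactly unit-normalized and all bounds hold", {
  set.seed(65)
  for (i in 1:5) {
    k <- sample(2:4, 1)
    A <- array(rnorm(k * k * 2, sd = 0.15), c(k, k, 2))
    Y <- simulateVAR(1500, A, SIG = diag(runif(k, 0.5, 2)))
    m <- fitMVAR(Y, p = 2)
    g <- gpdc(m)
    cn <- apply(g@G^2, c(1, 3), sum)
    expect_lt(max(abs(cn - 1)), 1e-10)
    expect_true(all(g@G >= 0 & g@G <= 1))
    expect_true(all(g@C >= 0 & g@C <= 1 + 1e-12))
    diags <- apply(g@S, 1, function(Sf) Re(diag(matrix(Sf, m@k))))
    expect_true(all(diags >= 0))
  }
})

test_that("time-shuffling one series destroys directed coupling", {
  A <- array(0, c(2, 2, 1))
  A[1, 1, 1] <- 0.5; A[2, 1, 1] <- 0.5; A[2, 2, 1] <- 0.3
  set.seed(66)
  Y <- simulateVAR(2000, A)
  Y[, 1] <- sample(Y[, 1])
  g <- gpdc(fitMVAR(Y, p = 1))
  expect_lt(bandSummary(g)[2, 1], 0.1)
  expect_lt(bandSummary(g)[1, 2], 0.1)
})

test_that("GPDC from estimated coefficients converges to the truth with n", {
  A <- array(0, c(2, 2, 1))
  A[1, 1, 1] <- 0.5; A[2, 1, 1] <- 0.5; A[2, 2, 1] <- 0.3
  truth <- gpdc(new("MVARModel", A = A, SIG = diag(2), p = 1, k = 2,
                    n = 1e4, diagnostics = list(stable = TRUE,
                                                spectralRadius = 0.5)))
  err <- function(n, seed) {
    set.seed(seed)
    g <- gpdc(fitMVAR(simulateVAR(n, A), p = 1))
    mean(abs(g@G - truth@G))
  }
  e2 <- mean(sapply(1:12, function(i) err(2000, 660 + i)))
  e8 <- mean(sapply(1:12, function(i) err(8000, 690 + i)))
  expect_lt(e8, e2)
})

test_that("dyadGPDC recovers the designed leader and validates inputs", {
  m <- testMontages(1)
  d <- generateDyad(couplingSpec(0.8, leader = "human", lag = 1000),
                    duration = 150, seed = 67,
                    montageHuman = m$human, montageDog = m$dog)
  g <- dyadGPDC(d$session, region = "frontal")
  expect_gt(g$humanToDog, g$dogToHuman)
  expect_error(dyadGPDC(seriesHuman = rnorm(50), seriesDog = rnorm(50),
                        region = "frontal"), "insufficient")
  expect_error(dyadGPDC(d$session, region = "temporal"), "usable")
})
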