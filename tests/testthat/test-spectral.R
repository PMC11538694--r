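test_that("DPSS tapers are orthonormal and band-concentrated", {
  V <- dpssTapers(500, nw = 4, k = 7)
  expect_equal(crossprod(V), diag(7), tolerance = 1e-8,
               ignore_attr = TRUE)
  # the leading taper concentrates its energy inside +/- NW/N
  h <- abs(fft(c(V[, 1], numeric(7500))))^2
  f <- (0:7999) / 8000 * 500
  expect_gt(sum(h[f <= 4 | f >= 496]) / sum(h), 0.999)
})

test_that("spectrogram of zero input is zero; short input errors", {
  rec <- makeTestRecording(numeric(1000))
  sp <- multitaperSpectrogram(rec)
  expect_true(all(sp@power == 0))
  expect_equal(dim(sp@power), c(2, 27, 1))
  expect_error(multitaperSpectrogram(makeTestRecording(numeric(300))),
               "shorter")
})

test_that("a 10 Hz tone concentrates in the main lobe around its bin", {
  t <- (0:(10 * 500 - 1)) / 500
  sp <- multitaperSpectrogram(makeTestRecording(sin(2 * pi * 10 * t)))
  P <- sp@power[, , 1]
  # the NW = 4 spectral window is ~flat over +/- 4 Hz: the per-window
  # maximum must fall inside the main lobe, with essentially all band
  # power inside it
  peaks <- sp@freqs[apply(P, 1, which.max)]
  expect_true(all(abs(peaks - 10) <= 4))
  lobe <- rowSums(P[, abs(sp@freqs - 10) <= 4])
  expect_true(all(lobe / rowSums(P) > 0.99))
})

test_that("white-noise PSD level matches the averaged-periodogram oracle", {
  set.seed(21)
  x <- rnorm(300 * 500, sd = 2)
  sp <- multitaperSpectrogram(makeTestRecording(x))
  mtLevel <- mean(sp@power)
  # oracle: averaged periodogram of the same data at the same bins
  W <- matrix(x, 500)
  pg <- apply(Mod(mvfft(W))^2 / 500, 1, mean) * 2 / 500
  pgLevel <- mean(pg[5:31])
  expect_equal(mtLevel, pgLevel, tolerance = 0.1)
  # and both match the flat theoretical level 2 sigma^2 / fs
  expect_equal(mtLevel, 2 * 4 / 500, tolerance = 0.1)
})

test_that("in-band multitaper power matches time-domain variance (Parseval)", {
  set.seed(22)
  for (i in 1:5) {
    x <- dyadsync:::bandCarrier(30 * 500, 500) * runif(1, 1, 20)
    sp <- multitaperSpectrogram(makeTestRecording(x))
    tot <- mean(apply(sp@power[, , 1], 1, sum))    # 1 Hz bins: sum = integral
    expect_equal(tot, var(x), tolerance = 0.15)
  }
})

test_that("window accounting: floor(duration) windows survive", {
  rec <- makeTestRecording(rnorm(5.7 * 500))
  expect_equal(dim(multitaperSpectrogram(rec)@power)[1], 5)
})

test_that("peak normalization divides each frequency by its maximum", {
  P <- array(0, c(3, 2, 1))
  P[, 1, 1] <- c(2, 4, 8)
  P[, 2, 1] <- c(1, 1, 0.5)
  sp <- new("Spectrogram", power = P, freqs = c(4, 5), windowTimes = 0:2,
            fs = 500, montage = makeTestRecording(rnorm(500))@montage,
            normalized = FALSE, meta = list())
  out <- peakNormalize(sp)
  expect_equal(out@power[, 1, 1], c(0.25, 0.5, 1))
  expect_true(all(apply(out@power, c(2, 3), max) == 1))
  # idempotent and scale invariant
  expect_equal(peakNormalize(out)@power, out@power)
  sp2 <- sp; sp2@power <- sp@power * 37.5
  expect_equal(peakNormalize(sp2)@power, out@power)
})

test_that("zero-power frequencies survive normalization as zeros", {
  P <- array(0, c(3, 2, 1))
  P[, 1, 1] <- c(2, 4, 8)
  sp <- new("Spectrogram", power = P, freqs = c(4, 5), windowTimes = 0:2,
            fs = 500, montage = makeTestRecording(rnorm(500))@montage,
            normalized = FALSE, meta = list())
  out <- peakNormalize(sp)
  expect_true(all(out@power[, 2, 1] == 0))
})

test_that("region series average channels and bins as documented", {
  set.seed(23)
  rec <- makeTestRecording(rnorm(20 * 500))
  sp <- peakNormalize(multitaperSpectrogram(rec))
  # single channel, full band: identical to the channel's bin average
  expect_equal(regionPowerSeries(sp, "frontal"),
               apply(sp@power[, , 1], 1, mean))
  # two channels with power s and 3 s at all frequencies average to 2 s
  P <- sp@power[, , 1]
  sp2 <- new("Spectrogram", power = array(c(P, 3 * P), c(dim(P), 2)),
             freqs = sp@freqs, windowTimes = sp@windowTimes, fs = 500,
             montage = makeTestRecording(matrix(rnorm(1000), 2))@montage,
             normalized = FALSE, meta = list())
  expect_equal(regionPowerSeries(sp2, "frontal"),
               2 * apply(P, 1, mean))
})

test_that("regions without usable channels are skipped explicitly", {
  m <- testMontages(1)
  d <- generateDyad(couplingSpec(0), duration = 10, seed = 2,
                    montageHuman = m$human, montageDog = m$dog)
  sp <- multitaperSpectrogram(dogRecording(d$session))
  out <- regionPowerSeries(sp, "temporal")
  expect_true(all(is.na(out)))
  expect_true(attr(out, "skipped"))
})

test_that("designed theta:beta ratios are recovered by the TBR", {
  ch <- paste0("C", 1:4)
  mont <- new("Montage", channels = ch,
              regions = stats::setNames(rep("frontal", 4), ch),
              excluded = character())
  for (r in c(0.5, 2)) {
    meds <- sapply(1:5, function(i) {
      set.seed(childSeed(41, round(10 * r), i))
      X <- t(sapply(1:4, function(c)
        sqrt(r) * dyadsync:::bandCarrier(30 * 500, 500, c(4, 8), roll = 0) +
          dyadsync:::bandCarrier(30 * 500, 500, c(13, 30), roll = 0)))
      rec <- new("Recording", samples = X, fs = 500, montage = mont,
                 validMask = rep(TRUE, 15000), meta = list())
      median(tbr(multitaperSpectrogram(rec), region = "frontal"),
             na.rm = TRUE)
    })
    expect_equal(median(meds), r, tolerance = 0.1)
  }
})

test_that("the two-tone worked example gives TBR near 4", {
  # oracle: sinusoid power A^2/2 -> theta 2.0 vs beta 0.5
  t <- (0:(30 * 500 - 1)) / 500
  set.seed(42)
  x <- 2 * sin(2 * pi * 6 * t) + sin(2 * pi * 20 * t) + rnorm(length(t), sd = 0.01)
  v <- median(tbr(multitaperSpectrogram(makeTestRecording(x)),
                  channels = "C1"), na.rm = TRUE)
  expect_equal(v, 4, tolerance = 0.1)
})

test_that("TBR normalization against its own baseline averages to one", {
  set.seed(43)
  x <- dyadsync:::bandCarrier(20 * 500, 500) * 15 + rnorm(20 * 500, sd = 3)
  rec <- makeTestRecording(x)
  tb <- tbr(multitaperSpectrogram(rec), channels = "C1")
  expect_equal(mean(normalizeTBR(tb, tb), na.rm = TRUE), 1, tolerance = 1e-10)
})
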