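test_that("low-pass filter has unit DC gain and leaves in-band tones untouched", {
  rec <- makeTestRecording(rep(5, 5000))
  out <- lowpassFilter(rec)
  expect_lt(max(abs(sampleMatrix(out) - 5)), 1e-10)

  t <- (0:4999) / 500
  x <- sin(2 * pi * 10 * t)
  rec10 <- makeTestRecording(x)
  y <- sampleMatrix(lowpassFilter(rec10))[1, ]
  core <- 1000:4000                        # away from the padded edges
  atten <- 1 - sd(y[core]) / sd(x[core])
  # oracle: squared analytic Butterworth magnitude at 10/245 Hz
  expect_lt(abs(atten), 1 - 1 / (1 + (10 / 245)^20) + 0.01)
  expect_lt(abs(atten), 0.01)
})

test_that("cutoff at Nyquist warns, above Nyquist errors with the Nyquist value", {
  rec <- makeTestRecording(rnorm(2000))
  expect_warning(lowpassFilter(rec, cutoff = 250), "Nyquist")
  expect_error(lowpassFilter(rec, cutoff = 251), "Nyquist")
})

test_that("filter output stays finite for finite input", {
  set.seed(1)
  x <- rnorm(3000) * 1e6
  x[100] <- 1e9                             # impulse-like excursion
  out <- sampleMatrix(lowpassFilter(makeTestRecording(x)))
  expect_true(all(is.finite(out)))
})

test_that("detrending removes lines exactly and recovers superposed signals", {
  t <- seq_len(1000)
  rec <- makeTestRecording(3 + 2 * t)
  out <- sampleMatrix(detrendRecording(rec))
  expect_lt(max(abs(out)), 1e-8)

  s <- sin(2 * pi * 7 * t / 500)
  rec2 <- makeTestRecording(s + 5 - 0.3 * t)
  out2 <- sampleMatrix(detrendRecording(rec2))[1, ]
  # oracle: the sinusoid itself (its own tiny lsq line removed)
  sline <- lm(s ~ t)
  expect_lt(max(abs(out2 - residuals(sline))), 1e-9)

  set.seed(2)
  rec3 <- makeTestRecording(rnorm(5000))
  out3 <- sampleMatrix(detrendRecording(rec3))[1, ]
  expect_lt(abs(coef(lm(out3 ~ t, data = list(t = seq_along(out3))))[2]), 1e-12)
})

test_that("amplitude rule flags exactly the windows with strict >300 uV samples", {
  x <- rep(100, 10 * 500)
  expect_length(detectAmplitudeArtifacts(makeTestRecording(x)), 0)

  x[2.5 * 500] <- 400                       # t = 2.5 s, window [2,3) = index 3
  fl <- detectAmplitudeArtifacts(makeTestRecording(x))
  expect_identical(as.integer(fl), 3L)

  x2 <- rep(100, 10 * 500); x2[1250] <- 300
  expect_length(detectAmplitudeArtifacts(makeTestRecording(x2)), 0)
  x2[1250] <- 300.0001
  expect_length(detectAmplitudeArtifacts(makeTestRecording(x2)), 1)
})

test_that("excision removes flagged windows, joins ends, and keeps the books", {
  set.seed(3)
  x <- rnorm(10 * 500)
  rec <- makeTestRecording(x)
  idOut <- exciseAndJoin(rec, integer(0))
  expect_identical(sampleMatrix(idOut$recording), sampleMatrix(rec))
  expect_equal(idOut$report@fractionRemoved, 0)

  out <- exciseAndJoin(rec, 3L)             # drop window [2, 3)
  expect_equal(ncol(sampleMatrix(out$recording)), 9 * 500)
  # the sample formerly at t = 3.0 s now sits at t = 2.0 s
  expect_identical(sampleMatrix(out$recording)[1, 2 * 500 + 1], x[3 * 500 + 1])
  # mask bookkeeping: flagged + kept = total
  expect_equal(length(out$report@flagged) * 500 +
                 ncol(sampleMatrix(out$recording)), 10 * 500)
  expect_error(exciseAndJoin(rec, 1:10), "no usable data")
  expect_error(exciseAndJoin(rec, 11L), "out of bounds")
})

test_that("excision is idempotent: re-detection after excision finds nothing", {
  set.seed(4)
  x <- rnorm(20 * 500, sd = 50)
  x[(5 * 500):(5 * 500 + 100)] <- 500
  rec <- makeTestRecording(x)
  fl <- detectAmplitudeArtifacts(rec)
  expect_gt(length(fl), 0)
  cleaned <- exciseAndJoin(rec, fl)$recording
  expect_length(detectAmplitudeArtifacts(cleaned), 0)
})

test_that("joint dyad preprocessing keeps the two subjects aligned", {
  m <- testMontages(1)
  d <- generateDyad(couplingSpec(0.5), duration = 30, seed = 21,
                    montageHuman = m$human, montageDog = m$dog)
  sess <- d$session
  ev <- artifactEvent("ocular", "Fp1", onset = 10, duration = 2,
                      amplitude = 450)
  sess@human <- injectArtifacts(sess@human, list(ev), seed = 1)$recording
  pp <- preprocessDyad(sess)
  expect_equal(ncol(sampleMatrix(pp$session@human)),
               ncol(sampleMatrix(pp$session@dog)))
  expect_gt(pp$report@fractionRemoved, 0)
  expect_lte(pp$report@fractionRemoved, 1)
})

test_that("detector recovers the injected contamination fraction", {
  clf <- getTestClassifier()
  m <- testMontages(4)
  d <- generateDyad(couplingSpec(0.5), duration = 120, seed = 55,
                    montageHuman = m$human, montageDog = m$dog)
  rec <- humanRecording(d$session)
  ev <- randomArtifactEvents(rec, targetFraction = 0.15, nEvents = 3,
                             seed = 2)
  inj <- injectArtifacts(rec, ev, seed = 2)
  trueFrac <- mean(colSums(inj$mask) > 0)
  fl <- detectArtifacts(inj$recording, clf)
  rep <- exciseAndJoin(inj$recording, fl)$report
  expect_lt(abs(rep@fractionRemoved - trueFrac), 0.05)
})
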