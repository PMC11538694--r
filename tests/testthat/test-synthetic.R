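test_that("identical seeds give bit-identical sessions, different seeds differ", {
  m <- testMontages(1)
  a <- generateDyad(couplingSpec(0.5), duration = 12, seed = 5,
                    montageHuman = m$human, montageDog = m$dog)
  b <- generateDyad(couplingSpec(0.5), duration = 12, seed = 5,
                    montageHuman = m$human, montageDog = m$dog)
  c <- generateDyad(couplingSpec(0.5), duration = 12, seed = 6,
                    montageHuman = m$human, montageDog = m$dog)
  expect_identical(sampleMatrix(humanRecording(a$session)),
                   sampleMatrix(humanRecording(b$session)))
  expect_identical(sampleMatrix(dogRecording(a$session)),
                   sampleMatrix(dogRecording(b$session)))
  expect_false(identical(sampleMatrix(humanRecording(a$session)),
                         sampleMatrix(humanRecording(c$session))))
})

test_that("zero strength gives independent envelopes, strength one identical", {
  m <- testMontages(1)
  rs <- sapply(1:3, function(i) {
    d <- generateDyad(couplingSpec(0), duration = 300, seed = 100 + i,
                      montageHuman = m$human, montageDog = m$dog)
    cor(d$truth@envelopes$human["frontal", ],
        d$truth@envelopes$dog["frontal", ])
  })
  expect_lt(abs(mean(rs)), 0.1)
  d1 <- generateDyad(couplingSpec(1), duration = 300, seed = 9,
                     montageHuman = m$human, montageDog = m$dog)
  expect_gt(cor(d1$truth@envelopes$human["frontal", ],
                d1$truth@envelopes$dog["frontal", ]), 0.8)
})

test_that("the leader's envelope precedes the follower's by the set lag", {
  m <- testMontages(1)
  lag <- 250
  d <- generateDyad(couplingSpec(0.9, leader = "human", lag = lag),
                    duration = 120, seed = 12,
                    montageHuman = m$human, montageDog = m$dog)
  eh <- d$truth@envelopes$human["frontal", ]
  ed <- d$truth@envelopes$dog["frontal", ]
  # oracle: argmax of the sample cross-correlation of the latent envelopes
  cc <- stats::ccf(ed, eh, lag.max = 600, plot = FALSE)
  peak <- cc$lag[which.max(cc$acf)]
  expect_gt(peak, 0)                       # human leads
  expect_lt(abs(peak - lag), 60)           # near the designed 250 samples
})

test_that("coupling strength maps monotonically onto latent envelope correlation", {
  m <- testMontages(1)
  strengths <- c(0, 0.25, 0.5, 0.75, 1)
  means <- sapply(strengths, function(s) {
    mean(sapply(1:20, function(i) {
      d <- generateDyad(couplingSpec(s), duration = 60,
                        seed = childSeed(31, round(100 * s), i),
                        montageHuman = m$human, montageDog = m$dog)
      cor(d$truth@envelopes$human["frontal", ],
          d$truth@envelopes$dog["frontal", ])
    }))
  })
  expect_true(all(diff(means) > 0))
})

test_that("clean synthetic EEG concentrates power in the 4-30 Hz band over >40 Hz", {
  m <- testMontages(1)
  d <- generateDyad(couplingSpec(0.5), duration = 30, seed = 3,
                    montageHuman = m$human, montageDog = m$dog)
  rec <- humanRecording(d$session)
  sp <- multitaperSpectrogram(rec, freqRange = c(1, 245))
  P <- apply(sp@power[, , 1], 2, mean)
  inBand <- sum(P[sp@freqs >= 4 & sp@freqs <= 30])
  high <- sum(P[sp@freqs > 40])
  expect_gt(inBand / (inBand + high), 0.8)
})

test_that("montages validate region coverage and channel mapping", {
  expect_error(new("Montage", channels = c("A", "B"),
                   regions = c(A = "frontal"), excluded = character()),
               "mapped")
  mont <- defaultMontage("dog")
  expect_identical(usableChannels(mont, "temporal"), character(0))
  expect_length(usableChannels(mont, "frontal"), 4)
  badH <- defaultMontage("human")
  badH@channels <- badH@channels[badH@regions[badH@channels] != "occipital"]
  expect_error(generateDyad(couplingSpec(0), duration = 10, seed = 1,
                            montageHuman = badH),
               "zero channels")
})

test_that("artifact injection is local, masked, and identity for empty events", {
  m <- testMontages(2)
  d <- generateDyad(couplingSpec(0), duration = 20, seed = 8,
                    montageHuman = m$human, montageDog = m$dog)
  rec <- humanRecording(d$session)
  out0 <- injectArtifacts(rec, list(), seed = 1)
  expect_identical(sampleMatrix(out0$recording), sampleMatrix(rec))
  expect_false(any(out0$mask))

  ev <- artifactEvent("emg", usableChannels(montage(rec), "frontal"),
                      onset = 5, duration = 3, amplitude = 120)
  out <- injectArtifacts(rec, list(ev), seed = 1)
  changed <- sampleMatrix(out$recording) != sampleMatrix(rec)
  expect_true(all(changed[!out$mask] == FALSE))   # untouched outside support
  expect_true(any(changed))
  idx <- which(out$mask, arr.ind = TRUE)
  expect_true(all(idx[, 2] >= 5 * 500 + 1 & idx[, 2] <= 8 * 500))
})

test_that("a full-length line event dominates the channel periodogram at 50 Hz", {
  m <- testMontages(1)
  d <- generateDyad(couplingSpec(0), duration = 20, seed = 4,
                    montageHuman = m$human, montageDog = m$dog)
  rec <- humanRecording(d$session)
  ev <- artifactEvent("line", channelNames(rec)[1], onset = 0,
                      duration = 20, amplitude = 120)
  out <- injectArtifacts(rec, list(ev), seed = 2)
  x <- sampleMatrix(out$recording)[1, ]
  # oracle: periodogram peak location
  P <- Mod(stats::fft(x))^2
  fgrid <- (seq_along(x) - 1) * 500 / length(x)
  sel <- fgrid > 1 & fgrid < 250
  expect_equal(fgrid[sel][which.max(P[sel])], 50, tolerance = 0.01)
})

test_that("an ocular event of 400 uV pushes samples past the 300 uV rule", {
  m <- testMontages(2)
  d <- generateDyad(couplingSpec(0), duration = 20, seed = 6,
                    montageHuman = m$human, montageDog = m$dog)
  rec <- humanRecording(d$session)
  ev <- artifactEvent("ocular", usableChannels(montage(rec), "frontal"),
                      onset = 4, duration = 4, amplitude = 400)
  out <- injectArtifacts(rec, list(ev), seed = 3)
  seg <- sampleMatrix(out$recording)[, (4 * 500 + 1):(8 * 500)]
  expect_gt(max(abs(seg)), 300)
})

test_that("unknown artifact kinds and out-of-bounds events are rejected", {
  m <- testMontages(1)
  d <- generateDyad(couplingSpec(0), duration = 10, seed = 2,
                    montageHuman = m$human, montageDog = m$dog)
  rec <- humanRecording(d$session)
  expect_error(artifactEvent("blink", "Fp1", 1, 1, 100), "unknown artifact kind")
  ev <- artifactEvent("emg", "Fp1", onset = 9.5, duration = 5, amplitude = 50)
  ev@onset <- 20
  expect_error(injectArtifacts(rec, list(ev), seed = 1), "outside")
})

test_that("study designs produce the right sessions with scheduled strengths", {
  m <- testMontages(1)
  desc <- buildStudy(2, 5, schedule = c(0.1, 0.3, 0.5, 0.7, 0.9),
                     duration = 10, seed = 1, realize = FALSE,
                     montageHuman = m$human, montageDog = m$dog)
  expect_length(desc, 2 * 5 * 3)
  inter <- Filter(function(d) d$condition == "interaction" & d$dyad == 1, desc)
  mult <- vapply(inter, function(d) d$multiplier, 0)
  expect_true(all(diff(mult[order(vapply(inter, function(d) d$day, 0))]) > 0))
  ctrl <- Filter(function(d) d$condition != "interaction", desc)
  expect_true(all(vapply(ctrl, function(d) d$strength, 0) == 0))
  # determinism of descriptors and realization
  desc2 <- buildStudy(2, 5, schedule = c(0.1, 0.3, 0.5, 0.7, 0.9),
                      duration = 10, seed = 1, realize = FALSE,
                      montageHuman = m$human, montageDog = m$dog)
  expect_identical(vapply(desc, function(d) d$seed, 0L),
                   vapply(desc2, function(d) d$seed, 0L))
  s1 <- realizeSession(desc[[3]])
  s2 <- realizeSession(desc2[[3]])
  expect_identical(sampleMatrix(humanRecording(s1$session)),
                   sampleMatrix(humanRecording(s2$session)))
})

test_that("a logistic schedule saturates: days 7-10 sit within 5% of the asymptote", {
  sch <- logisticSchedule(10, t0 = 4, k = 1)
  expect_true(all(sch[7:10] >= 0.95 * 1))
  expect_true(all(diff(sch) > 0))
})
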