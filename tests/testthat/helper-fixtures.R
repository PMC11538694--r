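# shared fixtures, built in code at test time

# single-channel recording from a numeric vector
makeTestRecording <- function(x, fs = 500, region = "frontal") {
  x <- as.matrix(x)
  if (ncol(x) > nrow(x)) x <- t(x)
  nch <- ncol(x)
  ch <- paste0("C", seq_len(nch))
  regions <- stats::setNames(rep(region, nch), ch)
  mont <- new("Montage", channels = ch, regions = regions,
              excluded = character())
  new("Recording", samples = t(x), fs = fs, montage = mont,
      validMask = rep(TRUE, nrow(x)), meta = list())
}

# small montages for fast simulated sessions
testMontages <- function(channelsPerRegion = 1) {
  list(human = defaultMontage("human", channelsPerRegion),
       dog = defaultMontage("dog", channelsPerRegion))
}

# frontal-frontal interbrain r of one simulated session
sessionFrontalR <- function(strength, seed, duration = 120,
                            channelsPerRegion = 1, lag = 0, day = 1,
                            schedule = 1) {
  m <- testMontages(channelsPerRegion)
  d <- generateDyad(couplingSpec(strength, lag = lag, schedule = schedule),
                    duration = duration, seed = seed, day = day,
                    montageHuman = m$human, montageDog = m$dog)
  s <- d$session
  sh <- peakNormalize(multitaperSpectrogram(humanRecording(s)))
  sdg <- peakNormalize(multitaperSpectrogram(dogRecording(s)))
  as.numeric(pearsonR(regionPowerSeries(sh, "frontal"),
                      regionPowerSeries(sdg, "frontal")))
}

# labelled segments + trained classifier, built once and reused across files
.testClfCache <- new.env()
getTestTrainingSet <- function() {
  if (is.null(.testClfCache$set))
    .testClfCache$set <- makeArtifactTrainingSet(2000, seed = 101)
  .testClfCache$set
}
getTestClassifier <- function() {
  if (is.null(.testClfCache$clf)) {
    tr <- getTestTrainingSet()
    idx <- trainTestSplit(nrow(tr$features))
    .testClfCache$clf <- trainArtifactANN(
      tr$features[idx, ],
      ifelse(tr$isArtifact[idx], "artifact", "clean"), seed = 7)
  }
  .testClfCache$clf
}
# deterministic 75/25 split, balanced over the alternating label layout
trainTestSplit <- function(n) {
  set.seed(424242)
  sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.75, 0.25))
}
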