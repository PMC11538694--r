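## clean single-channel 1-s segment drawn from the same signal family as the
## simulator: enveloped 4-30 Hz carrier + 1/f background + sensor noise.
## the 1/f background is drawn from a 30-s trace so the segment carries the
## sub-hertz drift a window cut from a long recording would have
cleanSegment <- function(fs = 500) {
  env <- exp(ENV_SIGMA * latentAR1(fs, fs) - ENV_SIGMA^2)
  drift <- pinkNoise(30 * fs, sd = 8)
  o <- sample.int(29 * fs, 1)
  17 * stats::runif(1, 0.8, 1.25) * env * bandCarrier(fs, fs) +
    drift[o:(o + fs - 1)] + stats::rnorm(fs, sd = 2)
}

#' Build a labelled artifact training set
#'
#' Generates `n` single-channel 1-s segments: half clean, half with one
#' injected artifact of a random class (ocular, EMG, cardiac, line,
#' electrode) at class-typical amplitude, then extracts [waveletFeatures].
#'
#' @param n number of segments.
#' @param fs sampling rate in Hz.
#' @param seed integer seed.
#' @param kinds artifact classes to draw from.
#' @return list with `features` (n x p matrix), `label` (factor with level
#'   `"clean"` plus the artifact kinds) and `isArtifact` (logical).
#' @export
makeArtifactTrainingSet <- function(n = 2000, fs = 500, seed = 1,
                                    kinds = ARTIFACT_KINDS) {
  set.seed(childSeed(seed, 21))
  labels <- character(n)
  feats <- NULL
  for (i in seq_len(n)) {
    x <- cleanSegment(fs)
    if (i %% 2 == 0) {
      kind <- sample(kinds, 1)
      amp <- switch(kind, ocular = stats::runif(1, 350, 500),
                    emg = stats::runif(1, 50, 150),
                    cardiac = stats::runif(1, 150, 250),
                    line = stats::runif(1, 40, 80),
                    electrode = stats::runif(1, 250, 400))
      wf <- artifactWaveform(kind, fs, fs, amp, 1)
      x <- if (is.null(wf$replace)) x + wf$add[1, ] else wf$replace[1, ]
      labels[i] <- kind
    } else {
      labels[i] <- "clean"
    }
    f <- waveletFeatures(x, fs = fs)
    if (is.null(feats)) feats <- matrix(0, n, length(f),
                                        dimnames = list(NULL, names(f)))
    feats[i, ] <- f
  }
  list(features = feats,
       label = factor(labels, levels = c("clean", kinds)),
       isArtifact = labels != "clean")
}

#' Train the artifact neural-network classifier
#'
#' Single-hidden-layer network (softmax outputs over clean + artifact
#' classes) on standardized wavelet features; training is reproducible given
#' the seed and inference is deterministic.
#'
#' @param features n x p feature matrix from [waveletFeatures].
#' @param label factor of segment labels; must contain at least two classes.
#' @param hidden hidden units (default 32).
#' @param decay weight decay (regularization).
#' @param maxit maximum optimizer iterations.
#' @param seed integer seed for weight initialization.
#' @return an object of class `artifactANN` with `predictArtifact` support.
#' @export
trainArtifactANN <- function(features, label, hidden = 32, decay = 1e-3,
                             maxit = 300, seed = 1) {
  label <- droplevels(factor(label))
  if (nlevels(label) < 2)
    stop("degenerate training set: need at least two classes")
  ctr <- colMeans(features)
  scl <- apply(features, 2, stats::sd)
  scl[scl == 0] <- 1
  Z <- scale(features, center = ctr, scale = scl)
  set.seed(childSeed(seed, 31))
  fit <- nnet::nnet(Z, nnet::class.ind(label), size = hidden, decay = decay,
                    maxit = maxit, softmax = TRUE, trace = FALSE,
                    MaxNWts = 20000)
  structure(list(fit = fit, center = ctr, scale = scl,
                 levels = levels(label)),
            class = "artifactANN")
}

#' Posterior probabilities from the artifact classifier
#'
#' @param classifier an `artifactANN` object.
#' @param features feature matrix (columns as in training).
#' @return matrix of class posteriors (columns = classes); attribute
#'   `artifactProb` holds `1 - P(clean)` per row.
#' @export
predictArtifact <- function(classifier, features) {
  stopifnot(inherits(classifier, "artifactANN"))
  if (is.null(dim(features)))
    features <- matrix(features, 1, dimnames = list(NULL, names(features)))
  Z <- scale(features[, names(classifier$center), drop = FALSE],
             center = classifier$center, scale = classifier$scale)
  pr <- stats::predict(classifier$fit, Z)
  colnames(pr) <- classifier$levels
  ap <- if ("clean" %in% classifier$levels) 1 - pr[, "clean"] else
    rowSums(pr)
  attr(pr, "artifactProb") <- as.numeric(ap)
  pr
}

## per-channel, per-window artifact posteriors: channels x windows matrix
annChannelProbs <- function(rec, classifier, window = 1) {
  wlen <- round(window * rec@fs)
  nW <- ncol(rec@samples) %/% wlen
  use <- match(setdiff(rec@montage@channels, rec@montage@excluded),
               rec@montage@channels)
  X <- rec@samples[use, , drop = FALSE]
  featList <- vector("list", nW)
  for (w in seq_len(nW)) {
    seg <- X[, ((w - 1) * wlen + 1):(w * wlen), drop = FALSE]
    featList[[w]] <- waveletFeatures(seg, fs = rec@fs)
  }
  F <- do.call(rbind, featList)              # (nW * nchan) x p
  pr <- predictArtifact(classifier, F)
  matrix(attr(pr, "artifactProb"), nrow = length(use))
}

## per-window max artifact probability over analysis channels
annWindowProbs <- function(rec, classifier, window = 1) {
  apply(annChannelProbs(rec, classifier, window), 2, max)
}

#' Area under the ROC curve
#'
#' Rank-statistic (Mann-Whitney) formulation; used to evaluate the artifact
#' detector against ground-truth labels.
#'
#' @param scores numeric scores (higher = more artifact-like).
#' @param labels logical or 0/1 vector of true labels.
#' @return AUROC in \[0,1\].
#' @export
aurocScore <- function(scores, labels) {
  labels <- as.logical(labels)
  r <- rank(scores)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
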