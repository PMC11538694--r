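#' @import methods
NULL

REGIONS <- c("frontal", "parietal", "temporal", "occipital")

#' Electrode montage
#'
#' Maps channel labels to scalp regions. Channels listed in `excluded` are
#' generated and stored but skipped by region-level analyses (e.g. the dog
#' temporal channels, whose signal quality is compromised by the temporalis
#' muscle).
#'
#' @slot channels character vector of channel labels.
#' @slot regions named character vector, one region per channel; values are
#'   `"frontal"`, `"parietal"`, `"temporal"` or `"occipital"`.
#' @slot excluded character vector of channel labels excluded from analysis.
#' @export
setClass("Montage", representation(
  channels = "character",
  regions = "character",
  excluded = "character"
))

setValidity("Montage", function(object) {
  msg <- character()
  if (!all(object@channels %in% names(object@regions)))
    msg <- c(msg, "every channel must be mapped to a region")
  if (!all(object@regions %in% REGIONS))
    msg <- c(msg, sprintf("regions must be one of: %s", paste(REGIONS, collapse = ", ")))
  if (anyDuplicated(object@channels))
    msg <- c(msg, "duplicate channel labels")
  if (!all(object@excluded %in% object@channels))
    msg <- c(msg, "excluded channels must be part of the montage")
  if (length(msg)) msg else TRUE
})

#' Interbrain coupling specification for the simulator
#'
#' @slot strength named numeric in \[0,1\], one entry per region; the latent
#'   band-power envelopes of the two subjects in that (homologous) region pair
#'   are mixed so that their correlation equals the strength.
#' @slot leader `"human"` or `"dog"`: whose envelope precedes the other's.
#' @slot lag non-negative integer lag in samples by which the leader's
#'   envelope precedes the follower's.
#' @slot schedule numeric vector of per-day strength multipliers (>= 0);
#'   index d scales the coupling on day d.
#' @export
setClass("CouplingSpec", representation(
  strength = "numeric",
  leader = "character",
  lag = "numeric",
  schedule = "numeric"
))

setValidity("CouplingSpec", function(object) {
  msg <- character()
  if (!all(names(object@strength) %in% REGIONS))
    msg <- c(msg, "strength must be named by region")
  if (any(object@strength < 0 | object@strength > 1))
    msg <- c(msg, "strength must lie in [0, 1]")
  if (!object@leader %in% c("human", "dog"))
    msg <- c(msg, "leader must be 'human' or 'dog'")
  if (length(object@lag) != 1 || object@lag < 0 || object@lag != round(object@lag))
    msg <- c(msg, "lag must be a single non-negative integer (samples)")
  if (length(object@schedule) && any(object@schedule < 0))
    msg <- c(msg, "schedule multipliers must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Single-subject multichannel EEG recording
#'
#' @slot samples numeric matrix, channels x time, in microvolts.
#' @slot fs sampling rate in Hz.
#' @slot montage a [Montage-class].
#' @slot validMask logical vector, one entry per sample; `FALSE` marks
#'   samples flagged as artifactual.
#' @slot meta list of session metadata (subject, role, condition, day, dyad).
#' @export
setClass("Recording", representation(
  samples = "matrix",
  fs = "numeric",
  montage = "Montage",
  validMask = "logical",
  meta = "list"
))

setValidity("Recording", function(object) {
  msg <- character()
  if (nrow(object@samples) != length(object@montage@channels))
    msg <- c(msg, "sample matrix must have one row per montage channel")
  if (length(object@validMask) != ncol(object@samples))
    msg <- c(msg, "validMask length must equal the number of samples")
  if (length(object@fs) != 1 || object@fs <= 0)
    msg <- c(msg, "fs must be a positive scalar")
  if (anyNA(object@samples))
    msg <- c(msg, "samples must not contain NA")
  if (length(msg)) msg else TRUE
})

#' Paired recordings of one hyperscanning session
#'
#' @slot human the human-role [Recording-class].
#' @slot dog the dog-role [Recording-class].
#' @slot meta list: dyad, day, condition, and any simulator annotations.
#' @export
setClass("DyadSession", representation(
  human = "Recording",
  dog = "Recording",
  meta = "list"
))

setValidity("DyadSession", function(object) {
  msg <- character()
  if (abs(object@human@fs - object@dog@fs) > 1e-9)
    msg <- c(msg, "both subjects must share one sampling rate")
  if (ncol(object@human@samples) != ncol(object@dog@samples))
    msg <- c(msg, "both subjects must have the same number of samples")
  if (length(msg)) msg else TRUE
})

#' Ground truth attached to simulated sessions
#'
#' @slot artifactMask list with elements `human` and `dog`; each is a logical
#'   channels x time matrix marking injected artifact samples (may be empty).
#' @slot strength named numeric: the true per-region envelope correlation
#'   realized in this session (already includes the day schedule).
#' @slot leader `"human"` or `"dog"`.
#' @slot lag lag in samples.
#' @slot envelopes list with elements `human` and `dog`: region x time
#'   matrices of the latent band-power envelopes before mixing into carriers.
#' @export
setClass("SyntheticGroundTruth", representation(
  artifactMask = "list",
  strength = "numeric",
  leader = "character",
  lag = "numeric",
  envelopes = "list"
))

#' One injected artifact event
#'
#' @slot kind one of `"ocular"`, `"emg"`, `"cardiac"`, `"line"`, `"electrode"`.
#' @slot channels character vector of affected channel labels.
#' @slot onset onset in seconds from recording start.
#' @slot duration duration in seconds.
#' @slot amplitude characteristic amplitude in microvolts (> 0).
#' @export
setClass("ArtifactEvent", representation(
  kind = "character",
  channels = "character",
  onset = "numeric",
  duration = "numeric",
  amplitude = "numeric"
))

ARTIFACT_KINDS <- c("ocular", "emg", "cardiac", "line", "electrode")

setValidity("ArtifactEvent", function(object) {
  msg <- character()
  if (!object@kind %in% ARTIFACT_KINDS)
    msg <- c(msg, sprintf("unknown artifact kind '%s'", object@kind))
  if (object@amplitude <= 0) msg <- c(msg, "amplitude must be > 0")
  if (object@onset < 0 || object@duration <= 0)
    msg <- c(msg, "event must have onset >= 0 and duration > 0")
  if (length(msg)) msg else TRUE
})

#' Windowed multitaper power spectrogram
#'
#' @slot power numeric array, windows x frequencies x channels. Units are
#'   uV^2/Hz before normalization, unitless afterwards.
#' @slot freqs integer frequency bins in Hz.
#' @slot windowTimes start time (s) of each window on the (possibly excised)
#'   timeline.
#' @slot fs sampling rate of the source recording.
#' @slot montage the source [Montage-class].
#' @slot normalized `TRUE` after per-frequency peak normalization.
#' @slot meta metadata carried over from the source recording.
#' @export
setClass("Spectrogram", representation(
  power = "array",
  freqs = "numeric",
  windowTimes = "numeric",
  fs = "numeric",
  montage = "Montage",
  normalized = "logical",
  meta = "list"
))

setValidity("Spectrogram", function(object) {
  msg <- character()
  d <- dim(object@power)
  if (length(d) != 3) msg <- c(msg, "power must be a 3-d array (window x freq x channel)")
  else {
    if (d[2] != length(object@freqs)) msg <- c(msg, "freqs length must match dim 2")
    if (d[1] != length(object@windowTimes)) msg <- c(msg, "windowTimes must match dim 1")
    if (min(object@power) < 0) msg <- c(msg, "power must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Artifact detection / excision report
#'
#' @slot flagged integer indices of flagged 1-s windows (channel-agnostic
#'   shared timeline).
#' @slot nWindows total number of whole windows in the inspected recording.
#' @slot fractionRemoved proportion of the windowed timeline removed.
#' @slot perKind named integer counts of flagged windows per detector source.
#' @export
setClass("ArtifactReport", representation(
  flagged = "integer",
  nWindows = "integer",
  fractionRemoved = "numeric",
  perKind = "integer"
))

setValidity("ArtifactReport", function(object) {
  if (object@fractionRemoved < 0 || object@fractionRemoved > 1)
    "fractionRemoved must lie in [0, 1]" else TRUE
})

#' Fitted multivariate autoregressive model
#'
#' @slot A coefficient array k x k x p; `A[i, j, r]` is the influence of
#'   series j at lag r on series i.
#' @slot SIG innovation (residual) covariance, k x k.
#' @slot p model order.
#' @slot k number of series.
#' @slot n number of time points used in the fit.
#' @slot diagnostics list: `stable`, `spectralRadius`, `bic`, `orderGrid`.
#' @export
setClass("MVARModel", representation(
  A = "array",
  SIG = "matrix",
  p = "numeric",
  k = "numeric",
  n = "numeric",
  diagnostics = "list"
))

setValidity("MVARModel", function(object) {
  msg <- character()
  if (!isTRUE(all.equal(object@SIG, t(object@SIG), tolerance = 1e-8)))
    msg <- c(msg, "SIG must be symmetric")
  if (min(eigen(object@SIG, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    msg <- c(msg, "SIG must be positive semi-definite")
  if (length(msg)) msg else TRUE
})

#' Generalized partial directed coherence result
#'
#' @slot G numeric array, frequencies x k x k; `G[f, i, j]` is the directed
#'   coupling j -> i, in \[0,1\], column-normalized so that
#'   `sum_i G[f, i, j]^2 == 1` for every source j and frequency f.
#' @slot freqs frequency grid in cycles/sample of the modelled series.
#' @slot bandSummary k x k matrix of band-mean G (j -> i in `[i, j]`).
#' @slot H complex array: transfer function, frequencies x k x k.
#' @slot S complex array: spectral density matrix, frequencies x k x k.
#' @slot C numeric array: magnitude-squared coherence, frequencies x k x k.
#' @slot model the fitted [MVARModel-class].
#' @slot band the frequency band summarized.
#' @export
setClass("GPDCResult", representation(
  G = "array",
  freqs = "numeric",
  bandSummary = "matrix",
  H = "array",
  S = "array",
  C = "array",
  model = "MVARModel",
  band = "numeric"
))
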