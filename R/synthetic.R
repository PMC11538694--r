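#' Deterministic child seeds
#'
#' Mixes a master seed with integer indices through a 31-bit linear
#' congruential step so that every simulator component draws from its own
#' reproducible stream. All derived seeds stay below 2^31.
#'
#' @param seed master integer seed.
#' @param ... further integer indices (dyad, day, condition index, ...).
#' @return a single integer seed.
#' @export
childSeed <- function(seed, ...) {
  idx <- c(...)
  h <- as.numeric(seed) %% 2147483647
  for (i in idx) {
    h <- (h * 69069 + as.numeric(i) + 1) %% 2147483647
  }
  as.integer(h)
}

#' Default 16-channel montage
#'
#' Sixteen channels, four per region, labelled after the international 10/20
#' layout. The dog montage carries the same labels but excludes the temporal
#' channels from analysis: the canine temporalis muscle prevents usable EEG
#' from that region.
#'
#' @param species `"human"` or `"dog"`.
#' @param channelsPerRegion channels generated per region (default 4).
#' @return a [Montage-class].
#' @export
defaultMontage <- function(species = c("human", "dog"), channelsPerRegion = 4) {
  species <- match.arg(species)
  base <- list(
    frontal  = c("Fp1", "Fp2", "F3", "F4"),
    parietal = c("P3", "P4", "Pz", "POz"),
    temporal = c("T7", "T8", "TP7", "TP8"),
    occipital = c("O1", "O2", "PO7", "PO8")
  )
  stopifnot(channelsPerRegion >= 1, channelsPerRegion <= 4)
  base <- lapply(base, function(ch) ch[seq_len(channelsPerRegion)])
  channels <- unlist(base, use.names = FALSE)
  regions <- rep(names(base), each = channelsPerRegion)
  names(regions) <- channels
  excluded <- if (species == "dog") base$temporal else character()
  new("Montage", channels = channels, regions = regions, excluded = excluded)
}

#' Construct a coupling specification
#'
#' @param strength named numeric in \[0,1\]: target latent-envelope
#'   correlation per (homologous) region pair. Unnamed scalar couples frontal
#'   and parietal at that strength, with temporal/occipital independent.
#' @param leader `"human"` or `"dog"`.
#' @param lag lag in samples by which the leader's envelope precedes the
#'   follower's.
#' @param schedule per-day strength multipliers (day 1, 2, ...); defaults to
#'   a constant 1.
#' @return a [CouplingSpec-class].
#' @export
couplingSpec <- function(strength = 0, leader = "human", lag = 0,
                         schedule = 1) {
  if (is.null(names(strength))) {
    stopifnot(length(strength) == 1)
    strength <- c(frontal = unname(strength), parietal = unname(strength),
                  temporal = 0, occipital = 0)
  }
  full <- stats::setNames(numeric(length(REGIONS)), REGIONS)
  full[names(strength)] <- strength
  new("CouplingSpec", strength = full, leader = leader, lag = as.numeric(lag),
      schedule = as.numeric(schedule))
}

#' Logistic day schedule
#'
#' Multiplier `1 / (1 + exp(-k (day - t0)))`, a saturating familiarity curve.
#' With the defaults (`t0 = 4`, `k = 1`) the schedule crosses 95% of its
#' asymptote at day `t0 + log(19)/k` (about day 7).
#'
#' @param days number of days.
#' @param t0 midpoint day.
#' @param k growth rate per day.
#' @export
logisticSchedule <- function(days, t0 = 4, k = 1) {
  1 / (1 + exp(-k * (seq_len(days) - t0)))
}

## ---- internal signal primitives ------------------------------------------

## AR(1) latent with unit stationary variance; time constant tau seconds.
latentAR1 <- function(n, fs, tau = 1.5) {
  phi <- exp(-1 / (fs * tau))
  innov <- stats::rnorm(n, sd = sqrt(1 - phi^2))
  as.numeric(stats::filter(innov, phi, method = "recursive",
                           init = stats::rnorm(1)))
}

## band-limited (4-30 Hz) unit-variance Gaussian carrier, synthesized in the
## frequency domain with raised-cosine band edges (roll Hz roll-off;
## roll = 0 gives ideal brick-wall support)
bandCarrier <- function(n, fs, band = c(4, 30), roll = 0.5) {
  nf <- n %/% 2
  f <- seq_len(nf) * fs / n
  if (roll <= 0) roll <- 1e-9
  amp <- numeric(nf)
  inb <- f >= band[1] & f <= band[2]
  amp[inb] <- 1
  lo <- f >= band[1] - roll & f < band[1]
  amp[lo] <- 0.5 * (1 + cos(pi * (band[1] - f[lo]) / roll))
  hi <- f > band[2] & f <= band[2] + roll
  amp[hi] <- 0.5 * (1 + cos(pi * (f[hi] - band[2]) / roll))
  spec <- complex(real = stats::rnorm(nf), imaginary = stats::rnorm(nf)) * amp
  full <- complex(real = numeric(n))
  full[2:(nf + 1)] <- spec
  full[n:(n - nf + 2)] <- Conj(spec[seq_len(nf - 1)])
  x <- Re(stats::fft(full, inverse = TRUE))
  x / stats::sd(x)
}

## 1/f-shaped noise with given sd, via spectral shaping
pinkNoise <- function(n, sd = 1) {
  nf <- n %/% 2
  f <- seq_len(nf)
  amp <- 1 / sqrt(f)
  ph <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = ph)
  full <- complex(real = numeric(n))
  full[2:(nf + 1)] <- spec
  full[n:(n - nf + 2)] <- Conj(spec[seq_len(nf - 1)])
  x <- Re(stats::fft(full, inverse = TRUE))
  x <- x - mean(x)
  x / stats::sd(x) * sd
}

## log-envelope sd: controls depth of band-power fluctuations
ENV_SIGMA <- 0.6

#' Generate one synthetic dyad session
#'
#' Builds paired 16-channel EEG-like recordings whose 4-30 Hz band-power
#' envelopes are coupled region-by-region with known strength and direction.
#' Each region of each subject has a latent log-envelope (smoothed AR(1),
#' time constant ~1.5 s); for a coupled region the follower's log-envelope is
#' `s * leader(t - lag) + sqrt(1 - s^2) * own(t)`, so the latent correlation
#' equals the strength `s` exactly and the leader precedes by `lag` samples.
#' Channel signals are the region envelope modulating an independent 4-30 Hz
#' carrier, plus 1/f background and sensor noise.
#'
#' @param spec a [CouplingSpec-class].
#' @param duration session length in seconds (>= 10).
#' @param fs sampling rate in Hz (>= 200; default 500).
#' @param seed integer seed; identical seeds give bit-identical sessions.
#' @param day day index used to look up the schedule multiplier.
#' @param montageHuman,montageDog montages (defaults: [defaultMontage]).
#' @param meta extra metadata stored in the session.
#' @return list with elements `session` ([DyadSession-class]) and `truth`
#'   ([SyntheticGroundTruth-class]).
#' @examples
#' d <- generateDyad(couplingSpec(0.8), duration = 20, seed = 1)
#' d$session
#' @export
generateDyad <- function(spec, duration = 300, fs = 500, seed = 1, day = 1,
                         montageHuman = defaultMontage("human"),
                         montageDog = defaultMontage("dog"),
                         meta = list()) {
  stopifnot(is(spec, "CouplingSpec"))
  if (duration < 10) stop("duration must be at least 10 s")
  if (fs < 200) stop("fs must be at least 200 Hz")
  for (r in REGIONS) {
    if (!length(montageHuman@channels[montageHuman@regions[montageHuman@channels] == r]) ||
        !length(montageDog@channels[montageDog@regions[montageDog@channels] == r]))
      stop(sprintf("montage has zero channels in region '%s'", r))
  }
  n <- round(duration * fs)
  lag <- spec@lag
  mult <- if (length(spec@schedule) >= day) spec@schedule[day] else
    spec@schedule[length(spec@schedule)]
  s <- spec@strength * mult
  s[s > 1] <- 1

  set.seed(childSeed(seed, 101))
  ## latent log-envelopes per region: leader drawn with `lag` extra samples
  zLead <- zFoll <- matrix(0, length(REGIONS), n,
                           dimnames = list(REGIONS, NULL))
  for (ri in seq_along(REGIONS)) {
    zl <- latentAR1(n + lag, fs)
    zo <- latentAR1(n, fs)
    sr <- s[REGIONS[ri]]
    zLead[ri, ] <- zl[(lag + 1):(lag + n)]
    zFoll[ri, ] <- sr * zl[1:n] + sqrt(1 - sr^2) * zo
  }
  if (spec@leader == "human") {
    zH <- zLead; zD <- zFoll
  } else {
    zD <- zLead; zH <- zFoll
  }
  envH <- exp(ENV_SIGMA * zH - ENV_SIGMA^2)   # E[env^2] = 1
  envD <- exp(ENV_SIGMA * zD - ENV_SIGMA^2)

  synthSubject <- function(mont, env, subSeed) {
    set.seed(subSeed)
    reg <- mont@regions[mont@channels]
    X <- matrix(0, length(mont@channels), n,
                dimnames = list(mont@channels, NULL))
    for (ci in seq_along(mont@channels)) {
      gain <- stats::runif(1, 0.8, 1.25)
      carrier <- bandCarrier(n, fs)
      X[ci, ] <- 17 * gain * env[reg[ci], ] * carrier +
        pinkNoise(n, sd = 8) + stats::rnorm(n, sd = 2)
    }
    X
  }
  XH <- synthSubject(montageHuman, envH, childSeed(seed, 102))
  XD <- synthSubject(montageDog, envD, childSeed(seed, 103))

  mkRec <- function(X, mont, role) {
    new("Recording", samples = X, fs = fs, montage = mont,
        validMask = rep(TRUE, n),
        meta = c(list(role = role), meta))
  }
  smeta <- c(meta, list(seed = seed))
  if (!"day" %in% names(smeta)) smeta$day <- day
  session <- new("DyadSession",
                 human = mkRec(XH, montageHuman, "human"),
                 dog = mkRec(XD, montageDog, "dog"),
                 meta = smeta)
  truth <- new("SyntheticGroundTruth",
               artifactMask = list(),
               strength = s, leader = spec@leader, lag = lag,
               envelopes = list(human = envH, dog = envD))
  list(session = session, truth = truth)
}

## ---- artifacts ------------------------------------------------------------

#' Construct an artifact event
#'
#' @param kind artifact class: `"ocular"`, `"emg"`, `"cardiac"`, `"line"` or
#'   `"electrode"`.
#' @param channels affected channel labels.
#' @param onset onset in seconds.
#' @param duration duration in seconds.
#' @param amplitude characteristic amplitude in microvolts.
#' @return an [ArtifactEvent-class].
#' @export
artifactEvent <- function(kind, channels, onset, duration, amplitude) {
  new("ArtifactEvent", kind = kind, channels = channels, onset = onset,
      duration = duration, amplitude = amplitude)
}

## waveform of one event, length m samples at rate fs; `rng` state is the
## caller's. Returns a matrix nchan x m to ADD, plus an optional replacement.
artifactWaveform <- function(kind, m, fs, amplitude, nchan, lineFreq = 50) {
  tt <- seq_len(m) / fs
  add <- matrix(0, nchan, m)
  replace <- NULL
  if (kind == "ocular") {
    ## blink-like: positive lobe followed by a shallower negative trough,
    ## repeated every ~1.5-3 s; low-frequency (< 4 Hz) by construction
    period <- stats::runif(1, 1.5, 3)
    shape <- numeric(m)
    onsets <- seq(0.05, max(0.051, m / fs - 0.4), by = period)
    for (o in onsets) {
      idx <- tt - o
      shape <- shape + exp(-((idx - 0.10) / 0.06)^2) -
        0.6 * exp(-((idx - 0.28) / 0.10)^2)
    }
    w <- amplitude * shape
    for (c in seq_len(nchan)) add[c, ] <- w * stats::runif(1, 0.85, 1)
  } else if (kind == "emg") {
    bf <- signal::butter(4, c(30, min(120, fs / 2 * 0.9)) / (fs / 2), "pass")
    for (c in seq_len(nchan)) {
      x <- signal::filtfilt(bf, stats::rnorm(m + fs))[(fs / 2 + 1):(fs / 2 + m)]
      add[c, ] <- amplitude / 3 * x / stats::sd(x)
    }
  } else if (kind == "cardiac") {
    rate <- stats::runif(1, 1, 2)             # beats per second
    beat <- seq(0.05, m / fs, by = 1 / rate)
    shape <- numeric(m)
    for (b in beat) {
      idx <- tt - b
      shape <- shape + exp(-(idx / 0.015)^2) - 0.7 * exp(-((idx - 0.035) / 0.02)^2)
    }
    w <- amplitude * shape
    for (c in seq_len(nchan)) add[c, ] <- w * stats::runif(1, 0.9, 1)
  } else if (kind == "line") {
    ph <- stats::runif(1, 0, 2 * pi)
    w <- amplitude * sin(2 * pi * lineFreq * tt + ph)
    for (c in seq_len(nchan)) add[c, ] <- w
  } else if (kind == "electrode") {
    sub <- sample(c("step", "flat", "noisy"), 1)
    if (sub == "step") {
      w <- rep(amplitude, m)
      ramp <- seq_len(min(m, 25))
      w[ramp] <- amplitude * ramp / length(ramp)
      for (c in seq_len(nchan)) add[c, ] <- w
    } else if (sub == "flat") {
      replace <- matrix(stats::rnorm(nchan, sd = 0.1), nchan, m)
    } else {
      for (c in seq_len(nchan)) add[c, ] <- stats::rnorm(m, sd = amplitude / 2)
    }
  } else {
    stop(sprintf("unknown artifact kind '%s'", kind))
  }
  list(add = add, replace = replace)
}

#' Inject artifacts into a recording
#'
#' Modifies the signal only inside the event supports and returns the
#' modified recording together with the exact sample mask. Waveforms follow
#' the standard EEG artifact taxonomy: ocular events are low-frequency
#' blink-shaped deflections (positive lobe then negative trough) on the given
#' channels; EMG is band-limited noise above 30 Hz; cardiac events are
#' periodic sharp biphasic deflections at 1-2 Hz; line noise is a pure
#' sinusoid at 50 Hz (configurable to 60); electrode faults are steps, flat
#' traces, or high-variance segments.
#'
#' @param rec a [Recording-class].
#' @param events list of [ArtifactEvent-class] objects.
#' @param seed integer seed controlling the event waveform randomness.
#' @param lineFreq mains frequency in Hz for `"line"` events.
#' @return list with elements `recording` (modified copy) and `mask`
#'   (logical channels x time matrix of injected samples).
#' @export
injectArtifacts <- function(rec, events, seed = 1, lineFreq = 50) {
  stopifnot(is(rec, "Recording"))
  X <- rec@samples
  n <- ncol(X)
  fs <- rec@fs
  mask <- matrix(FALSE, nrow(X), n, dimnames = dimnames(X))
  set.seed(childSeed(seed, 7))
  for (ev in events) {
    stopifnot(is(ev, "ArtifactEvent"))
    i0 <- floor(ev@onset * fs) + 1
    i1 <- min(n, floor((ev@onset + ev@duration) * fs))
    if (i0 < 1 || i0 > n || i1 < i0)
      stop("artifact event lies outside the recording")
    chIdx <- match(ev@channels, rec@montage@channels)
    if (anyNA(chIdx)) stop("event channels not in montage")
    m <- i1 - i0 + 1
    wf <- artifactWaveform(ev@kind, m, fs, ev@amplitude, length(chIdx),
                           lineFreq = lineFreq)
    if (is.null(wf$replace)) {
      X[chIdx, i0:i1] <- X[chIdx, i0:i1] + wf$add
    } else {
      X[chIdx, i0:i1] <- wf$replace
    }
    mask[chIdx, i0:i1] <- TRUE
  }
  out <- rec
  out@samples <- X
  list(recording = out, mask = mask)
}

#' Draw a random set of artifact events
#'
#' Helper for building labelled contamination: events of the five classes
#' with class-typical channels, durations and amplitudes, covering
#' approximately `targetFraction` of the recording.
#'
#' @param rec a [Recording-class].
#' @param targetFraction fraction of the timeline to cover (approximate).
#' @param nEvents number of events.
#' @param seed integer seed.
#' @param kinds artifact classes to draw from.
#' @return list of [ArtifactEvent-class].
#' @export
randomArtifactEvents <- function(rec, targetFraction = 0.15, nEvents = 5,
                                 seed = 1, kinds = ARTIFACT_KINDS) {
  set.seed(childSeed(seed, 11))
  dur <- durationSec(rec)
  mont <- rec@montage
  evDur <- targetFraction * dur / nEvents
  ## one event per equal slot, uniform within the slot: non-overlapping
  slotLen <- dur / nEvents
  if (evDur > slotLen) stop("targetFraction too high for this many events")
  onsets <- (seq_len(nEvents) - 1) * slotLen +
    stats::runif(nEvents, 0, slotLen - evDur)
  events <- vector("list", nEvents)
  for (i in seq_len(nEvents)) {
    kind <- sample(kinds, 1)
    ch <- switch(kind,
      ocular = usableChannels(mont, "frontal"),
      emg = unique(c(mont@channels[mont@regions[mont@channels] == "temporal"],
                     usableChannels(mont, "frontal"))),
      cardiac = mont@channels,
      line = mont@channels,
      electrode = sample(mont@channels, 1))
    amp <- switch(kind, ocular = stats::runif(1, 350, 500),
                  emg = stats::runif(1, 90, 150),
                  cardiac = stats::runif(1, 150, 250),
                  line = stats::runif(1, 40, 80),
                  electrode = stats::runif(1, 250, 400))
    events[[i]] <- artifactEvent(kind, ch, onsets[i], evDur, amp)
  }
  events
}

## ---- study designs --------------------------------------------------------

STUDY_CONDITIONS <- c("separate", "same_room", "interaction")

#' Build a multi-day, multi-condition study
#'
#' Emulates the repeated-familiarization design: each dyad is recorded once
#' per day in each condition. Only the interaction condition is coupled; the
#' separate-room and same-room-no-interaction controls have strength 0. The
#' interaction strength on day d is `schedule[d] * baseStrength` per region.
#'
#' @param nDyads number of dyads (>= 1).
#' @param days number of days (>= 1).
#' @param conditions subset of `c("separate", "same_room", "interaction")`.
#' @param schedule per-day multipliers (length `days`, recycled if scalar).
#' @param baseStrength named or scalar region strength passed to
#'   [couplingSpec] (scalar couples frontal + parietal).
#' @param leader,lag coupling direction and lag in samples.
#' @param duration,fs session length (s) and sampling rate (Hz).
#' @param seed master seed; sessions use deterministic child seeds.
#' @param montageHuman,montageDog montages.
#' @param realize if `TRUE` (default) return realized sessions; if `FALSE`
#'   return lightweight descriptors that [realizeSession] can expand one at a
#'   time (large designs do not fit in memory all at once).
#' @return list of `list(session, truth)` (realized) or descriptor rows.
#' @export
buildStudy <- function(nDyads, days, conditions = STUDY_CONDITIONS,
                       schedule = rep(1, days), baseStrength = 0.8,
                       leader = "human", lag = 0, duration = 300, fs = 500,
                       seed = 1,
                       montageHuman = defaultMontage("human"),
                       montageDog = defaultMontage("dog"),
                       realize = TRUE) {
  stopifnot(nDyads >= 1, days >= 1)
  conditions <- match.arg(conditions, STUDY_CONDITIONS, several.ok = TRUE)
  if (length(schedule) == 1) schedule <- rep(schedule, days)
  stopifnot(length(schedule) >= days, all(schedule >= 0))
  desc <- list()
  idx <- 0
  for (dy in seq_len(nDyads)) for (d in seq_len(days))
    for (ci in seq_along(conditions)) {
      idx <- idx + 1
      cond <- conditions[ci]
      desc[[idx]] <- list(
        dyad = dy, day = d, condition = cond,
        strength = if (cond == "interaction") baseStrength else 0,
        multiplier = if (cond == "interaction") schedule[d] else 0,
        leader = leader, lag = lag, duration = duration, fs = fs,
        seed = childSeed(seed, dy, d, ci),
        montageHuman = montageHuman, montageDog = montageDog)
    }
  if (!realize) return(desc)
  lapply(desc, realizeSession)
}

#' Realize one study-session descriptor
#'
#' @param d a descriptor produced by `buildStudy(..., realize = FALSE)`.
#' @return list with `session` and `truth` as in [generateDyad].
#' @export
realizeSession <- function(d) {
  spec <- couplingSpec(d$strength, leader = d$leader, lag = d$lag,
                       schedule = d$multiplier)
  generateDyad(spec, duration = d$duration, fs = d$fs, seed = d$seed,
               day = 1,   # multiplier already resolved into the schedule
               montageHuman = d$montageHuman, montageDog = d$montageDog,
               meta = list(dyad = d$dyad, day = d$day,
                           condition = d$condition))
}
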