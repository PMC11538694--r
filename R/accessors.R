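#' @rdname Montage-class
#' @export
setMethod("channelNames", "Montage", function(x) x@channels)

#' @rdname Montage-class
#' @export
setMethod("regionOf", "Montage", function(x) x@regions[x@channels])

#' @rdname Montage-class
#' @export
setMethod("nChannels", "Montage", function(x) length(x@channels))

#' @rdname usableChannels
#' @export
setMethod("usableChannels", "Montage", function(x, region) {
  ch <- x@channels[x@regions[x@channels] == region]
  setdiff(ch, x@excluded)
})

#' @rdname Recording-class
#' @export
setMethod("samplingRate", "Recording", function(x) x@fs)

#' @rdname Recording-class
#' @export
setMethod("sampleMatrix", "Recording", function(x) x@samples)

#' @rdname Recording-class
#' @export
setMethod("montage", "Recording", function(x) x@montage)

#' @rdname Recording-class
#' @export
setMethod("recordingMeta", "Recording", function(x) x@meta)

#' @rdname Recording-class
#' @export
setMethod("channelNames", "Recording", function(x) x@montage@channels)

#' @rdname DyadSession-class
#' @export
setMethod("humanRecording", "DyadSession", function(x) x@human)

#' @rdname DyadSession-class
#' @export
setMethod("dogRecording", "DyadSession", function(x) x@dog)

#' @rdname durationSec
#' @export
setMethod("durationSec", "Recording", function(x) ncol(x@samples) / x@fs)

#' @rdname durationSec
#' @export
setMethod("durationSec", "DyadSession", function(x) durationSec(x@human))

#' @rdname bandSummary
#' @export
setMethod("bandSummary", "GPDCResult", function(x) x@bandSummary)

setMethod("show", "Montage", function(object) {
  tab <- table(factor(object@regions[object@channels], levels = REGIONS))
  cat(sprintf("Montage: %d channels (%s)\n", length(object@channels),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  if (length(object@excluded))
    cat("  excluded from analysis:", paste(object@excluded, collapse = ", "), "\n")
})

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(object@samples), ncol(object@samples), object@fs,
              ncol(object@samples) / object@fs))
  m <- object@meta
  if (length(m))
    cat(sprintf("  meta: %s\n",
                paste(sprintf("%s=%s", names(m), vapply(m, function(v)
                  paste(format(v), collapse = ","), "")), collapse = " ")))
  nf <- sum(!object@validMask)
  if (nf) cat(sprintf("  %d samples flagged invalid\n", nf))
})

setMethod("show", "DyadSession", function(object) {
  m <- object@meta
  fmt <- function(v) if (is.null(v)) "?" else format(v)
  cat(sprintf("DyadSession (dyad=%s day=%s condition=%s): %.1f s @ %g Hz\n",
              fmt(m$dyad), fmt(m$day), fmt(m$condition),
              durationSec(object), object@human@fs))
})

setMethod("show", "Spectrogram", function(object) {
  d <- dim(object@power)
  cat(sprintf("Spectrogram: %d windows x %d freqs (%g-%g Hz) x %d channels%s\n",
              d[1], d[2], min(object@freqs), max(object@freqs), d[3],
              if (object@normalized) " [peak-normalized]" else ""))
})

setMethod("show", "MVARModel", function(object) {
  cat(sprintf("MVARModel: k=%d series, order p=%d, n=%d, spectral radius %.3f%s\n",
              object@k, object@p, object@n,
              object@diagnostics$spectralRadius,
              if (isTRUE(object@diagnostics$stable)) " (stable)" else " (UNSTABLE)"))
})

setMethod("show", "GPDCResult", function(object) {
  cat(sprintf("GPDCResult: k=%d, %d frequencies, band [%g, %g] cycles/sample\n",
              dim(object@G)[2], length(object@freqs), object@band[1], object@band[2]))
  cat("Band-mean G (column j -> row i):\n")
  print(round(object@bandSummary, 4))
})

setMethod("show", "ArtifactReport", function(object) {
  cat(sprintf("ArtifactReport: %d/%d windows flagged (%.1f%%)\n",
              length(object@flagged), object@nWindows,
              100 * object@fractionRemoved))
  if (length(object@perKind))
    cat("  by source:", paste(sprintf("%s=%d", names(object@perKind),
                                      object@perKind), collapse = ", "), "\n")
})
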