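#' @rdname Montage-class
#' @param object,x an object.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname Montage-class
#' @export
setGeneric("regionOf", function(x) standardGeneric("regionOf"))

#' @rdname Montage-class
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' Usable channels of a region
#'
#' Channels of `x` assigned to `region` and not excluded from analysis.
#'
#' @param x a [Montage-class] or an object carrying one.
#' @param region region label.
#' @export
setGeneric("usableChannels", function(x, region) standardGeneric("usableChannels"))

#' @rdname Recording-class
#' @param x a Recording.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname Recording-class
#' @export
setGeneric("sampleMatrix", function(x) standardGeneric("sampleMatrix"))

#' @rdname Recording-class
#' @export
setGeneric("montage", function(x) standardGeneric("montage"))

#' @rdname Recording-class
#' @export
setGeneric("recordingMeta", function(x) standardGeneric("recordingMeta"))

#' @rdname DyadSession-class
#' @param x a DyadSession.
#' @export
setGeneric("humanRecording", function(x) standardGeneric("humanRecording"))

#' @rdname DyadSession-class
#' @export
setGeneric("dogRecording", function(x) standardGeneric("dogRecording"))

#' Duration of a recording or session in seconds
#' @param x a Recording or DyadSession.
#' @export
setGeneric("durationSec", function(x) standardGeneric("durationSec"))

#' Band-summary matrix of a directed-coupling result
#' @param x a [GPDCResult-class].
#' @export
setGeneric("bandSummary", function(x) standardGeneric("bandSummary"))
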