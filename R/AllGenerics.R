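#' Accessors for recording and beat objects
#'
#' Small accessor family for the package's S4 containers: raw ADC samples,
#' channel metadata, sampling rate, R-peak indices/times and template
#' matrices.  Slots should be reached through these rather than with `@`.
#'
#' @param object A [RawRecording-class], [BeatSeries-class] or
#'   [BeatTemplateSet-class].
#' @param ... Additional arguments for methods.
#' @return The requested component; see the individual methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(object, ...) standardGeneric("samples"))

#' @rdname accessors
#' @export
setGeneric("channels", function(object, ...) standardGeneric("channels"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object, ...)
  standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("deviceId", function(object, ...) standardGeneric("deviceId"))

#' @rdname accessors
#' @export
setGeneric("channelData", function(object, which, ...)
  standardGeneric("channelData"))

#' @rdname accessors
#' @export
setGeneric("channelRoles", function(object, ...)
  standardGeneric("channelRoles"))

#' @rdname accessors
#' @export
setGeneric("nBeats", function(object, ...) standardGeneric("nBeats"))

#' @rdname accessors
#' @export
setGeneric("rIndices", function(object, ...) standardGeneric("rIndices"))

#' @rdname accessors
#' @export
setGeneric("rTimes", function(object, ...) standardGeneric("rTimes"))

#' @rdname accessors
#' @export
setGeneric("beatLabels", function(object, ...) standardGeneric("beatLabels"))

#' @rdname accessors
#' @export
setGeneric("beatLabels<-", function(object, value)
  standardGeneric("beatLabels<-"))

#' @rdname accessors
#' @export
setGeneric("templateMatrix", function(object, ...)
  standardGeneric("templateMatrix"))

#' @rdname accessors
#' @export
setGeneric("meanTemplate", function(object, ...)
  standardGeneric("meanTemplate"))

#' @rdname accessors
#' @export
setGeneric("tpPercent", function(object, ...) standardGeneric("tpPercent"))

#' @rdname accessors
#' @export
setGeneric("keptBeats", function(object, ...) standardGeneric("keptBeats"))

#' @rdname accessors
#' @export
setGeneric("beatIndex", function(object, ...) standardGeneric("beatIndex"))
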