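#' @rdname accessors
#' @aliases samples,RawRecording-method
setMethod("samples", "RawRecording", function(object, ...) object@samples)

#' @rdname accessors
#' @aliases channels,RawRecording-method
setMethod("channels", "RawRecording", function(object, ...) object@channels)

#' @rdname accessors
#' @aliases samplingRate,RawRecording-method
setMethod("samplingRate", "RawRecording", function(object, ...) object@fs)

#' @rdname accessors
#' @aliases deviceId,RawRecording-method
setMethod("deviceId", "RawRecording", function(object, ...) object@deviceId)

#' @rdname accessors
#' @aliases channelRoles,RawRecording-method
setMethod("channelRoles", "RawRecording", function(object, ...) {
  vapply(object@channels, function(ch) ch@role, character(1))
})

#' @rdname accessors
#' @aliases channelData,RawRecording-method
#' @details `channelData(rec, which)` accepts a channel name, a column
#'   index, or a role string (first matching channel); it returns the
#'   integer count vector of that channel.
setMethod("channelData", "RawRecording", function(object, which, ...) {
  j <- .resolveChannel(object, which)
  object@samples[, j]
})

.resolveChannel <- function(rec, which) {
  nm <- vapply(rec@channels, function(ch) ch@name, character(1))
  roles <- vapply(rec@channels, function(ch) ch@role, character(1))
  if (is.numeric(which)) {
    j <- as.integer(which)
    if (j < 1L || j > length(nm))
      stop("channel index out of range: ", which, call. = FALSE)
    return(j)
  }
  j <- match(which, nm)
  if (is.na(j)) j <- match(which, roles)
  if (is.na(j))
    stop("no channel with name or role '", which, "' in device '",
         rec@deviceId, "' (channels: ", paste(nm, collapse = ", "), ")",
         call. = FALSE)
  j
}

#' Channel spec lookup
#'
#' @param rec A [RawRecording-class].
#' @param which Channel name, role, or column index.
#' @return The matching [ChannelSpec-class].
#' @export
channelSpecOf <- function(rec, which) rec@channels[[.resolveChannel(rec, which)]]

setMethod("show", "RawRecording", function(object) {
  cat(sprintf("RawRecording '%s': %d samples x %d channels @ %g Hz\n",
              object@deviceId, nrow(object@samples),
              ncol(object@samples), object@fs))
  for (ch in object@channels)
    cat(sprintf("  %-12s role=%-10s %d-bit vcc=%gV gain=%g\n",
                ch@name, ch@role, ch@adcBits, ch@vcc, ch@gain))
})

setMethod("show", "ChannelSpec", function(object) {
  cat(sprintf("ChannelSpec '%s' (%s): %d-bit, vcc=%g V, gain=%g\n",
              object@name, object@role, object@adcBits, object@vcc,
              object@gain))
})

#' @rdname accessors
#' @aliases nBeats,BeatSeries-method
setMethod("nBeats", "BeatSeries", function(object, ...)
  length(object@rIndices))

#' @rdname accessors
#' @aliases rIndices,BeatSeries-method
setMethod("rIndices", "BeatSeries", function(object, ...) object@rIndices)

#' @rdname accessors
#' @aliases rTimes,BeatSeries-method
#' @details `rTimes()` returns beat times in seconds, with sample 1 at
#'   time 0.
setMethod("rTimes", "BeatSeries", function(object, ...)
  (object@rIndices - 1L) / object@fs)

#' @rdname accessors
#' @aliases beatLabels,BeatSeries-method
setMethod("beatLabels", "BeatSeries", function(object, ...) object@labels)

#' @rdname accessors
#' @aliases beatLabels<-,BeatSeries-method
setReplaceMethod("beatLabels", "BeatSeries", function(object, value) {
  object@labels <- as.character(value)
  validObject(object)
  object
})

#' @rdname accessors
#' @aliases samplingRate,BeatSeries-method
setMethod("samplingRate", "BeatSeries", function(object, ...) object@fs)

setMethod("show", "BeatSeries", function(object) {
  n <- length(object@rIndices)
  cat(sprintf("BeatSeries: %d beats @ %g Hz (%d normal, %d outlier)\n",
              n, object@fs, sum(object@labels == "normal"),
              sum(object@labels == "outlier")))
})

#' @rdname accessors
#' @aliases templateMatrix,BeatTemplateSet-method
setMethod("templateMatrix", "BeatTemplateSet", function(object, ...)
  object@templates)

#' @rdname accessors
#' @aliases meanTemplate,BeatTemplateSet-method
setMethod("meanTemplate", "BeatTemplateSet", function(object, ...)
  colMeans(object@templates))

#' @rdname accessors
#' @aliases tpPercent,BeatTemplateSet-method
setMethod("tpPercent", "BeatTemplateSet", function(object, ...)
  object@tpPercent)

#' @rdname accessors
#' @aliases keptBeats,BeatTemplateSet-method
setMethod("keptBeats", "BeatTemplateSet", function(object, ...) object@kept)

#' @rdname accessors
#' @aliases beatIndex,BeatTemplateSet-method
setMethod("beatIndex", "BeatTemplateSet", function(object, ...)
  object@beatIndex)

#' @rdname accessors
#' @aliases samplingRate,BeatTemplateSet-method
setMethod("samplingRate", "BeatTemplateSet", function(object, ...) object@fs)

#' @rdname accessors
#' @aliases nBeats,BeatTemplateSet-method
setMethod("nBeats", "BeatTemplateSet", function(object, ...)
  nrow(object@templates))

setMethod("show", "BeatTemplateSet", function(object) {
  cat(sprintf(
    "BeatTemplateSet: %d beats x %d samples (window -%g/+%g ms @ %g Hz)\n",
    nrow(object@templates), ncol(object@templates), object@window[1],
    object@window[2], object@fs))
  if (length(object@kept))
    cat(sprintf("  DMEAN-classified: %d kept, %d outlier\n",
                sum(object@kept), sum(!object@kept)))
  if (length(object@dropped))
    cat(sprintf("  %d beat(s) dropped at record edges\n",
                length(object@dropped)))
})
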