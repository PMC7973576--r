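#' @import methods
NULL

.CHANNEL_ROLES <- c("ecg_ref", "ecg_exp", "led", "luminosity")

#' Channel specification
#'
#' Describes one acquisition channel: its name, functional role, ADC
#' resolution, supply voltage and analog gain.  The count-to-millivolt
#' conversion in [adcToMillivolts()] is parameterized entirely by this
#' object.
#'
#' @slot name Channel name (e.g. `"ECG_REF"`, `"A4"`).
#' @slot role One of `"ecg_ref"`, `"ecg_exp"`, `"led"`, `"luminosity"`.
#' @slot adcBits ADC resolution in bits (counts span `[0, 2^adcBits - 1]`).
#' @slot vcc Supply voltage in volts.
#' @slot gain Dimensionless analog amplification factor.
#'
#' @seealso [channelSpec()] for the user-facing constructor.
#' @exportClass ChannelSpec
setClass("ChannelSpec",
  representation(
    name = "character",
    role = "character",
    adcBits = "integer",
    vcc = "numeric",
    gain = "numeric"
  ),
  prototype(adcBits = 10L, vcc = 3.3, gain = 11000)
)

setValidity("ChannelSpec", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(object@role) != 1L || !object@role %in% .CHANNEL_ROLES)
    msg <- c(msg, sprintf("'role' must be one of: %s",
                          paste(.CHANNEL_ROLES, collapse = ", ")))
  if (length(object@adcBits) != 1L || is.na(object@adcBits) ||
      object@adcBits < 1L)
    msg <- c(msg, "'adcBits' must be a single integer >= 1")
  if (length(object@vcc) != 1L || !is.finite(object@vcc) || object@vcc <= 0)
    msg <- c(msg, "'vcc' must be a single positive number")
  if (length(object@gain) != 1L || !is.finite(object@gain) ||
      object@gain <= 0)
    msg <- c(msg, "'gain' must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a ChannelSpec
#'
#' @param name Channel name.
#' @param role Channel role: `"ecg_ref"` (reference ECG), `"ecg_exp"`
#'   (experimental ECG), `"led"` (synchronization emitter) or
#'   `"luminosity"` (synchronization receiver).
#' @param adcBits ADC resolution in bits.  Default 10.
#' @param vcc Supply voltage in volts.  Default 3.3.
#' @param gain Analog gain.  Default 11000.
#'
#' @return A [ChannelSpec-class] object.
#' @examples
#' channelSpec("ECG_REF", "ecg_ref")
#' @export
channelSpec <- function(name, role, adcBits = 10L, vcc = 3.3, gain = 11000) {
  new("ChannelSpec", name = as.character(name), role = as.character(role),
      adcBits = as.integer(adcBits), vcc = as.numeric(vcc),
      gain = as.numeric(gain))
}

#' Raw multichannel recording
#'
#' Integer ADC samples for one acquisition device, one column per channel,
#' together with the per-channel [ChannelSpec-class] metadata, the sampling
#' frequency and a device identifier.  Objects are created by
#' [rawRecording()], [readRecording()] or [generatePair()].
#'
#' @slot samples Integer matrix, samples x channels (ADC counts).
#' @slot channels List of [ChannelSpec-class], one per column.
#' @slot fs Sampling frequency in Hz.
#' @slot deviceId Device identifier string.
#' @slot meta Free-form metadata list (e.g. the generator seed).
#'
#' @exportClass RawRecording
setClass("RawRecording",
  representation(
    samples = "matrix",
    channels = "list",
    fs = "numeric",
    deviceId = "character",
    meta = "list"
  ),
  prototype(meta = list())
)

setValidity("RawRecording", function(object) {
  msg <- character()
  if (!is.numeric(object@samples))
    msg <- c(msg, "'samples' must be a numeric (integer) matrix")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "'fs' must be a single positive number")
  if (length(object@deviceId) != 1L)
    msg <- c(msg, "'deviceId' must be a single string")
  if (ncol(object@samples) != length(object@channels))
    msg <- c(msg, "number of sample columns must equal number of channels")
  for (j in seq_along(object@channels)) {
    ch <- object@channels[[j]]
    if (!is(ch, "ChannelSpec")) {
      msg <- c(msg, sprintf("channel %d is not a ChannelSpec", j))
      next
    }
    if (nrow(object@samples)) {
      v <- object@samples[, j]
      hi <- 2^ch@adcBits - 1
      bad <- which(!is.finite(v) | v < 0 | v > hi | v != round(v))
      if (length(bad))
        msg <- c(msg, sprintf(
          "channel '%s': sample value %s at row %d outside ADC range [0, %d]",
          ch@name, format(v[bad[1]]), bad[1], hi))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a RawRecording
#'
#' @param samples Integer matrix (samples x channels, ADC counts).
#' @param channels List of [ChannelSpec-class] objects, one per column.
#' @param fs Sampling frequency (Hz).
#' @param deviceId Device identifier.
#' @param meta Optional metadata list.
#'
#' @return A [RawRecording-class].
#' @export
rawRecording <- function(samples, channels, fs, deviceId = "device",
                         meta = list()) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "integer"
  colnames(samples) <- vapply(channels, function(ch) ch@name, character(1))
  new("RawRecording", samples = samples, channels = channels,
      fs = as.numeric(fs), deviceId = as.character(deviceId), meta = meta)
}

#' Series of detected heartbeats
#'
#' R-peak sample indices for one ECG channel, with a per-beat label that is
#' `"normal"` after detection and may be demoted to `"outlier"` by
#' [dmeanClassify()].  Only normal beats enter the NN-interval series used
#' for heart-rate-variability analysis.
#'
#' @slot rIndices Strictly increasing 1-based sample indices of R peaks.
#' @slot fs Sampling frequency in Hz.
#' @slot labels Character vector, one of `"normal"`/`"outlier"` per beat.
#'
#' @exportClass BeatSeries
setClass("BeatSeries",
  representation(
    rIndices = "integer",
    fs = "numeric",
    labels = "character"
  )
)

setValidity("BeatSeries", function(object) {
  msg <- character()
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "'fs' must be a single positive number")
  if (length(object@rIndices) > 1L && any(diff(object@rIndices) <= 0))
    msg <- c(msg, "'rIndices' must be strictly increasing")
  if (length(object@labels) != length(object@rIndices))
    msg <- c(msg, "'labels' must have one entry per beat")
  if (length(object@labels) && !all(object@labels %in% c("normal", "outlier")))
    msg <- c(msg, "labels must be 'normal' or 'outlier'")
  if (length(msg)) msg else TRUE
})

#' Construct a BeatSeries
#'
#' @param rIndices Strictly increasing R-peak sample indices (1-based).
#' @param fs Sampling frequency (Hz).
#' @param labels Optional per-beat labels; defaults to all `"normal"`.
#'
#' @return A [BeatSeries-class].
#' @export
beatSeries <- function(rIndices, fs, labels = NULL) {
  rIndices <- as.integer(rIndices)
  if (is.null(labels)) labels <- rep("normal", length(rIndices))
  new("BeatSeries", rIndices = rIndices, fs = as.numeric(fs),
      labels = as.character(labels))
}

#' Fixed-window beat templates
#'
#' One row per complete heartbeat waveform, extracted around each R peak
#' with a fixed pre/post window.  [dmeanClassify()] fills the
#' `tpPercent`/`kept` slots with the DMEAN outlier decision.
#'
#' @slot templates Numeric matrix, beats x window samples (mV).
#' @slot fs Sampling frequency (Hz).
#' @slot window Length-2 numeric, (pre, post) window in ms around R.
#' @slot beatIndex Integer indices into the originating beat series for
#'   each template row (beats truncated at the record edges are absent).
#' @slot dropped Integer indices of beats dropped for lacking full window
#'   support.
#' @slot tpPercent Per-beat true-positive percentage from DMEAN (empty
#'   until classified).
#' @slot kept Logical per-beat keep decision (empty until classified).
#'
#' @exportClass BeatTemplateSet
setClass("BeatTemplateSet",
  representation(
    templates = "matrix",
    fs = "numeric",
    window = "numeric",
    beatIndex = "integer",
    dropped = "integer",
    tpPercent = "numeric",
    kept = "logical"
  ),
  prototype(tpPercent = numeric(), kept = logical(), dropped = integer())
)

setValidity("BeatTemplateSet", function(object) {
  msg <- character()
  if (length(object@window) != 2L || any(object@window < 0))
    msg <- c(msg, "'window' must be two non-negative numbers (pre, post) ms")
  if (nrow(object@templates) != length(object@beatIndex))
    msg <- c(msg, "'beatIndex' must have one entry per template row")
  if (length(object@tpPercent) &&
      length(object@tpPercent) != nrow(object@templates))
    msg <- c(msg, "'tpPercent' must have one entry per template row")
  if (length(object@kept) && length(object@kept) != nrow(object@templates))
    msg <- c(msg, "'kept' must have one entry per template row")
  if (length(msg)) msg else TRUE
})
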