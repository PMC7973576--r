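#' Read a plain-text acquisition file
#'
#' Parses the package's text format: three `#`-prefixed header lines (a
#' `BEGIN HEADER` sentinel, one JSON object, an `END HEADER` sentinel)
#' followed by tab-separated integer ADC counts, one column per channel.
#' The JSON header carries `fs` (Hz), `bits`, `channels` (array of
#' `{"name","role"}`), `device_id`, and optionally per-channel `gain` and
#' `vcc` plus a generator `seed`.
#'
#' @param path Path to the file.
#' @return A [RawRecording-class]; round-trips bit-exactly with
#'   [writeRecording()].
#' @examples
#' rec <- rawRecording(matrix(c(510L, 512L, 515L), ncol = 1),
#'                     list(channelSpec("ECG_REF", "ecg_ref")), fs = 1000)
#' f <- tempfile(fileext = ".txt")
#' writeRecording(rec, f)
#' identical(samples(readRecording(f)), samples(rec))
#' @export
readRecording <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "r", encoding = "UTF-8")
  on.exit(close(con))
  head3 <- readLines(con, n = 3L)
  if (length(head3) < 3L || !identical(head3[1], "# BEGIN HEADER") ||
      !startsWith(head3[2], "# ") || !identical(head3[3], "# END HEADER"))
    stop("malformed header in '", path,
         "': expected '# BEGIN HEADER', '# {json}', '# END HEADER'",
         call. = FALSE)
  hdr <- tryCatch(
    jsonlite::fromJSON(sub("^# ", "", head3[2]), simplifyVector = TRUE),
    error = function(e) stop("malformed JSON header in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  for (key in c("fs", "bits", "channels", "device_id"))
    if (is.null(hdr[[key]]))
      stop("header of '", path, "' lacks required key '", key, "'",
           call. = FALSE)
  chtab <- hdr$channels
  nch <- nrow(chtab)
  bits <- rep_len(as.integer(hdr$bits), nch)
  gain <- rep_len(if (is.null(hdr$gain)) 11000 else as.numeric(hdr$gain), nch)
  vcc <- rep_len(if (is.null(hdr$vcc)) 3.3 else as.numeric(hdr$vcc), nch)
  chans <- lapply(seq_len(nch), function(j)
    channelSpec(chtab$name[j], chtab$role[j], bits[j], vcc[j], gain[j]))

  vals <- scan(con, what = integer(), sep = "\t", quiet = TRUE)
  if (length(vals) %% nch != 0L)
    stop("body of '", path, "' is not a whole number of ", nch,
         "-column rows", call. = FALSE)
  mat <- matrix(vals, ncol = nch, byrow = TRUE)
  for (j in seq_len(nch)) {
    hi <- 2^bits[j] - 1
    bad <- which(mat[, j] < 0L | mat[, j] > hi)
    if (length(bad))
      stop("value ", mat[bad[1], j], " at row ", bad[1], ", channel '",
           chtab$name[j], "' outside ADC range [0, ", hi, "]",
           call. = FALSE)
  }
  meta <- if (!is.null(hdr$seed)) list(seed = as.integer(hdr$seed)) else list()
  rawRecording(mat, chans, fs = as.numeric(hdr$fs),
               deviceId = as.character(hdr$device_id), meta = meta)
}

#' Write a recording to the plain-text acquisition format
#'
#' Emits the `#`-prefixed JSON header followed by the tab-separated integer
#' body with a terminating newline.  Output bytes are deterministic for a
#' given recording, so repeated writes are byte-identical.
#'
#' @param rec A [RawRecording-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [readRecording()]
#' @export
writeRecording <- function(rec, path) {
  stopifnot(is(rec, "RawRecording"))
  validObject(rec)
  bits <- vapply(rec@channels, function(ch) ch@adcBits, integer(1))
  gain <- vapply(rec@channels, function(ch) ch@gain, numeric(1))
  vcc <- vapply(rec@channels, function(ch) ch@vcc, numeric(1))
  squash <- function(x) if (length(unique(x)) == 1L) x[1] else x
  hdr <- list(
    fs = rec@fs,
    bits = squash(bits),
    channels = data.frame(
      name = vapply(rec@channels, function(ch) ch@name, character(1)),
      role = vapply(rec@channels, function(ch) ch@role, character(1))),
    device_id = rec@deviceId,
    gain = squash(gain),
    vcc = squash(vcc))
  if (!is.null(rec@meta$seed)) hdr$seed <- rec@meta$seed
  json <- jsonlite::toJSON(hdr, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("# BEGIN HEADER", paste0("# ", json), "# END HEADER"),
             con, sep = "\n")
  if (nrow(rec@samples))
    writeLines(do.call(paste,
                       c(asplit(rec@samples, 2), list(sep = "\t"))),
               con, sep = "\n")
  invisible(path)
}

#' Convert ADC counts to millivolts
#'
#' Applies the symmetric single-supply transfer convention
#' `mV = ((counts / 2^bits) - 0.5) * vcc / gain * 1000`: the ADC midpoint
#' maps to 0 mV and the mapping is strictly increasing in counts.
#'
#' @param counts Integer ADC counts within `[0, 2^bits - 1]`.
#' @param spec A [ChannelSpec-class] supplying bits, vcc and gain.
#' @return Numeric vector of millivolt values at the electrode (i.e.
#'   referred to the amplifier input).
#' @examples
#' adcToMillivolts(512L, channelSpec("E", "ecg_ref"))  # 0 mV at mid-scale
#' @export
adcToMillivolts <- function(counts, spec) {
  stopifnot(is(spec, "ChannelSpec"))
  hi <- 2^spec@adcBits - 1
  if (any(counts < 0 | counts > hi))
    stop("counts outside ADC range [0, ", hi, "]", call. = FALSE)
  (counts / 2^spec@adcBits - 0.5) * spec@vcc / spec@gain * 1000
}

# Inverse transfer: millivolts to (clipped, rounded) ADC counts.
millivoltsToAdc <- function(mv, spec) {
  hi <- 2^spec@adcBits - 1
  counts <- round((mv / 1000 * spec@gain / spec@vcc + 0.5) * 2^spec@adcBits)
  as.integer(pmin(pmax(counts, 0), hi))
}

#' Streaming throughput of the acquisition link
#'
#' Data rate of a fixed-size frame emitted once per sample:
#' `fs * frameBytes * 8 / 1000` kbit/s.  A 1 kHz acquisition packed in
#' 7-byte frames streams at 56 kbit/s.
#'
#' @param fs Sampling frequency (Hz).
#' @param frameBytes Frame size in bytes.
#' @return Data rate in kbit/s.
#' @examples
#' streamRate(1000, 7)  # 56
#' @export
streamRate <- function(fs, frameBytes) {
  .assertScalar(fs, "fs")
  .assertScalar(frameBytes, "frameBytes")
  fs * frameBytes * 8 / 1000
}
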