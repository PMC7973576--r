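#' Detect synchronization pulse onsets
#'
#' Thresholds an LED or luminosity channel at the midpoint between its 5th
#' and 95th percentiles and returns rising-edge crossings, enforcing a
#' 100 ms refractory period between onsets.
#'
#' @param signal Integer (or numeric) channel samples.
#' @param fs Sampling frequency, Hz.
#' @return Integer vector of 1-based onset sample indices.
#' @examples
#' x <- rep(c(0, 0, 1000, 1000, 0, 0), each = 200)
#' detectPulses(x, fs = 1000)
#' @export
detectPulses <- function(signal, fs) {
  .assertScalar(fs, "fs")
  if (length(signal) < 2L)
    stop("signal must have at least 2 samples", call. = FALSE)
  q <- stats::quantile(signal, c(0.05, 0.95), names = FALSE, type = 7)
  if (q[2] <= q[1])
    stop("no pulses detectable: channel is flat ",
         "(5th and 95th percentiles coincide)", call. = FALSE)
  theta <- (q[1] + q[2]) / 2
  above <- signal >= theta
  rising <- which(above[-1] & !above[-length(above)]) + 1L
  if (!length(rising))
    stop("no pulses detectable: no rising edge crosses the threshold",
         call. = FALSE)
  refractory <- round(0.1 * fs)
  onsets <- rising[1]
  for (i in rising[-1])
    if (i - onsets[length(onsets)] > refractory) onsets <- c(onsets, i)
  as.integer(onsets)
}

#' Estimate the inter-device offset from pulse onsets
#'
#' Greedily matches each pulse on one device to its nearest unused pulse on
#' the other, then reports the median of the matched index differences
#' (device B minus device A) and, as a jitter figure, the median absolute
#' deviation of those differences about their median.  The median
#' estimator tolerates a pulse missed by either device.
#'
#' @param onsetsA,onsetsB Onset indices from [detectPulses()] for
#'   devices A and B.
#' @return A list with `offset` (samples), `jitter` (samples) and
#'   `nMatched`.
#' @examples
#' estimateOffset(c(100, 1100), c(150, 1150))  # offset 50
#' @export
estimateOffset <- function(onsetsA, onsetsB) {
  if (!length(onsetsA) || !length(onsetsB))
    stop("alignment error: need at least one pulse onset per device",
         call. = FALSE)
  cand <- expand.grid(a = seq_along(onsetsA), b = seq_along(onsetsB))
  cand$d <- abs(onsetsB[cand$b] - onsetsA[cand$a])
  cand <- cand[order(cand$d), ]
  usedA <- logical(length(onsetsA))
  usedB <- logical(length(onsetsB))
  diffs <- numeric()
  for (r in seq_len(nrow(cand))) {
    ia <- cand$a[r]; ib <- cand$b[r]
    if (!usedA[ia] && !usedB[ib]) {
      usedA[ia] <- usedB[ib] <- TRUE
      diffs <- c(diffs, onsetsB[ib] - onsetsA[ia])
    }
  }
  if (!length(diffs))
    stop("alignment error: zero matched pulse pairs", call. = FALSE)
  med <- stats::median(diffs)
  list(offset = med, jitter = stats::median(abs(diffs - med)),
       nMatched = length(diffs))
}

#' Trim two recordings to their common time support
#'
#' Given the estimated offset (device B minus device A, in samples), drops
#' the non-overlapping head/tail of each recording so that sample `i` of
#' the trimmed A and sample `i` of the trimmed B refer to the same
#' instant.
#'
#' @param recA,recB [RawRecording-class] objects with equal sampling rate.
#' @param offset Offset in samples as returned by [estimateOffset()].
#' @return A list with trimmed `deviceA` and `deviceB`, equal lengths.
#' @export
alignRecordings <- function(recA, recB, offset) {
  stopifnot(is(recA, "RawRecording"), is(recB, "RawRecording"))
  if (recA@fs != recB@fs)
    stop("recordings have different sampling rates", call. = FALSE)
  offset <- as.integer(round(offset))
  nA <- nrow(recA@samples)
  nB <- nrow(recB@samples)
  # device B sample j covers the same instant as device A sample j - offset
  lo <- max(1L, 1L - offset)
  hi <- min(nA, nB - offset)
  if (hi < lo)
    stop("alignment error: recordings do not overlap at offset ", offset,
         call. = FALSE)
  a <- recA
  b <- recB
  a@samples <- recA@samples[lo:hi, , drop = FALSE]
  b@samples <- recB@samples[(lo + offset):(hi + offset), , drop = FALSE]
  list(deviceA = a, deviceB = b)
}
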