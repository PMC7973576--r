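#' Match R peaks across two aligned beat series
#'
#' Greedy nearest-neighbor matching in time: candidate reference and
#' experimental beats within `toleranceMs` of each other are paired in
#' order of increasing time difference, each beat used at most once.  The
#' QRS count ratio `deltaQrsPercent = 100 * nExp / nRef` is computed on
#' the full series before matching, so values above 100% (spurious extra
#' detections) are legal.
#'
#' @param ref,exp [BeatSeries-class] objects on a common clock (i.e.
#'   after [alignRecordings()]).
#' @param toleranceMs Matching tolerance in ms (default 150, half the
#'   shortest plausible RR interval).
#' @return A list of class `"MatchedBeats"` with `pairs` (two-column
#'   matrix of ref/exp beat numbers), `unmatchedRef`, `unmatchedExp`,
#'   `toleranceMs` and `deltaQrsPercent`.
#' @export
matchRPeaks <- function(ref, exp, toleranceMs = 150) {
  stopifnot(is(ref, "BeatSeries"), is(exp, "BeatSeries"))
  if (!nBeats(ref))
    stop("reference series has no beats: QRS percentage undefined",
         call. = FALSE)
  tolS <- toleranceMs / 1000
  tr <- rTimes(ref)
  te <- rTimes(exp)
  # candidate pairs: for each exp beat its flanking ref beats
  cand <- NULL
  if (length(te)) {
    below <- findInterval(te, tr)
    cand <- rbind(cbind(below, seq_along(te)),
                  cbind(below + 1L, seq_along(te)))
    cand <- cand[cand[, 1] >= 1L & cand[, 1] <= length(tr), , drop = FALSE]
    dt <- abs(tr[cand[, 1]] - te[cand[, 2]])
    keep <- dt <= tolS
    cand <- cand[keep, , drop = FALSE]
    dt <- dt[keep]
    o <- order(dt)
    cand <- cand[o, , drop = FALSE]
  }
  usedR <- logical(length(tr))
  usedE <- logical(length(te))
  pairs <- matrix(integer(), 0, 2, dimnames = list(NULL, c("ref", "exp")))
  for (r in seq_len(NROW(cand))) {
    ir <- cand[r, 1]; ie <- cand[r, 2]
    if (!usedR[ir] && !usedE[ie]) {
      usedR[ir] <- usedE[ie] <- TRUE
      pairs <- rbind(pairs, cand[r, , drop = FALSE])
    }
  }
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  structure(list(
    pairs = pairs,
    unmatchedRef = which(!usedR),
    unmatchedExp = which(!usedE),
    toleranceMs = toleranceMs,
    deltaQrsPercent = 100 * length(te) / length(tr)),
    class = "MatchedBeats")
}

#' Instantaneous heart rate from a beat series
#'
#' Computes `HR = 60000 / RR(ms)` for every pair of consecutive beats
#' inside a contiguous run of normal-labeled beats; runs with fewer than
#' two beats contribute nothing.  Values outside the 60--100 BPM resting
#' band are kept but flagged.
#'
#' @param series A [BeatSeries-class].
#' @return A data.frame with `time` (s, at the second beat of each pair),
#'   `hrBpm` and logical `inBand`; zero rows when fewer than two usable
#'   beats exist.
#' @export
instantaneousHR <- function(series) {
  stopifnot(is(series, "BeatSeries"))
  t <- rTimes(series)
  normal <- beatLabels(series) == "normal"
  out <- data.frame(time = numeric(), hrBpm = numeric(),
                    inBand = logical())
  if (length(t) < 2L) return(out)
  ok <- normal[-length(t)] & normal[-1]
  if (!any(ok)) return(out)
  rr <- diff(t)[ok]
  hr <- 60 / rr
  data.frame(time = t[-1][ok], hrBpm = hr,
             inBand = hr >= 60 & hr <= 100)
}

#' Heart-rate difference over matched beats
#'
#' For each pair of successive matched beats, the instantaneous heart
#' rate is computed on each device from its own beat times and the
#' difference (experimental minus reference) is taken; the mean and
#' sample standard deviation of those differences are returned.
#'
#' @param ref,exp The [BeatSeries-class] objects that were matched.
#' @param matches A `"MatchedBeats"` result from [matchRPeaks()].
#' @return A list with `dhrMean`, `dhrSd` (BPM) and `n` (number of
#'   matched HR pairs).
#' @export
deltaHR <- function(ref, exp, matches) {
  stopifnot(inherits(matches, "MatchedBeats"))
  p <- matches$pairs
  if (nrow(p) < 2L)
    stop("undefined heart-rate difference: fewer than 2 matched beats",
         call. = FALSE)
  tr <- rTimes(ref)[p[, "ref"]]
  te <- rTimes(exp)[p[, "exp"]]
  hrR <- 60 / diff(tr)
  hrE <- 60 / diff(te)
  d <- hrE - hrR
  list(dhrMean = mean(d), dhrSd = stats::sd(d), n = length(d))
}

#' Signal detection error
#'
#' Percentage of an unfiltered ADC channel lost to saturation or gross
#' corruption.  A sample counts as lost when it lies in a run of at least
#' `minRunMs` consecutive samples clamped at an ADC rail (0 or
#' `2^adcBits - 1`), or inside a segment whose running `sdWindowS`-second
#' standard deviation exceeds `sdFactor` times the channel-wide median of
#' that statistic (rail-clamped runs are masked out of the running
#' statistic first).  A clean stationary channel scores 0%.
#'
#' @param raw Integer ADC counts (unfiltered).
#' @param adcBits ADC resolution in bits.
#' @param fs Sampling frequency, Hz.
#' @param minRunMs Minimum clamped-run length counted as saturation, ms.
#' @param sdWindowS Running-SD window, seconds.
#' @param sdFactor Multiple of the median running SD flagged as corrupt.
#' @return SDE as a percentage in `[0, 100]`.
#' @export
signalDetectionError <- function(raw, adcBits, fs, minRunMs = 50,
                                 sdWindowS = 1, sdFactor = 5) {
  n <- length(raw)
  if (!n) stop("undefined SDE: empty input", call. = FALSE)
  .assertScalar(fs, "fs")
  hi <- 2^adcBits - 1
  code <- integer(n)
  code[raw <= 0L] <- 1L
  code[raw >= hi] <- 2L
  r <- rle(code)
  minRun <- max(1L, round(minRunMs / 1000 * fs))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  clamped <- logical(n)
  for (k in which(r$values != 0L & r$lengths >= minRun))
    clamped[starts[k]:ends[k]] <- TRUE

  corrupt <- logical(n)
  w <- round(sdWindowS * fs)
  if (w >= 3L && n >= 2L * w) {
    x <- as.numeric(raw)
    valid <- as.numeric(!clamped)
    x0 <- x * valid
    cnt <- movingAverage(valid, w) * w
    mu <- movingAverage(x0, w) * w / pmax(cnt, 1)
    ex2 <- movingAverage(x0^2, w) * w / pmax(cnt, 1)
    v <- pmax(ex2 - mu^2, 0)
    rsd <- sqrt(v)
    rsd[cnt < 0.8 * w] <- NA          # windows dominated by clamped runs
    medSd <- stats::median(rsd, na.rm = TRUE)
    if (is.finite(medSd) && medSd > 0)
      corrupt <- !is.na(rsd) & rsd > sdFactor * medSd
  }
  100 * sum(clamped | corrupt) / n
}

#' Welch's unpaired two-sample t-test
#'
#' Two-sided p-value of the unpaired t-test without the equal-variance
#' assumption, as used to compare the per-device heart-rate
#' distributions.
#'
#' @param a,b Numeric samples (each of length >= 2; at least one must be
#'   non-constant).
#' @return The two-sided p-value.
#' @export
unpairedTTest <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("undefined t-test: each sample needs >= 2 values", call. = FALSE)
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    stop("undefined t-test: both samples are constant", call. = FALSE)
  stats::t.test(a, b, var.equal = FALSE)$p.value
}

#' Table-2-style comparison statistics for one channel pair
#'
#' Convenience wrapper combining [matchRPeaks()], [instantaneousHR()],
#' [deltaHR()], [signalDetectionError()] and [unpairedTTest()] into the
#' per-channel comparison row: QRS count ratio, per-device HR mean/SD,
#' HR-difference mean/SD, SDE and the Welch p-value.
#'
#' @param ref,exp [BeatSeries-class] objects on a common clock.
#' @param rawExp Unfiltered ADC counts of the experimental channel (for
#'   the SDE); `NULL` omits the SDE.
#' @param adcBits ADC resolution of `rawExp`.
#' @param toleranceMs Matching tolerance, ms.
#' @return A list of class `"ComparisonStats"`.
#' @export
compareChannels <- function(ref, exp, rawExp = NULL, adcBits = 10,
                            toleranceMs = 150) {
  m <- matchRPeaks(ref, exp, toleranceMs)
  hrR <- instantaneousHR(ref)$hrBpm
  hrE <- instantaneousHR(exp)$hrBpm
  d <- deltaHR(ref, exp, m)
  sde <- if (is.null(rawExp)) NA_real_ else
    signalDetectionError(rawExp, adcBits, samplingRate(exp))
  p <- tryCatch(unpairedTTest(hrR, hrE), error = function(e) NA_real_)
  structure(list(
    deltaQrsPercent = m$deltaQrsPercent,
    hrRefMean = mean(hrR), hrRefSd = stats::sd(hrR),
    hrExpMean = mean(hrE), hrExpSd = stats::sd(hrE),
    dhrMean = d$dhrMean, dhrSd = d$dhrSd,
    sdePercent = sde, pValue = p,
    nMatched = nrow(m$pairs), matches = m), class = "ComparisonStats")
}
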