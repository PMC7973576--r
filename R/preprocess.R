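#' Design the linear-phase FIR band-pass filter
#'
#' Designs a symmetric (type I linear-phase) band-pass FIR with
#' `order + 1` taps by constrained weighted least squares on a dense
#' frequency grid, with an exact null at DC.  The band edges are treated
#' as nominal corners: the passband proper runs from `5/3 * low` to
#' `8/9 * high`, the stopbands end at `low / 3` and begin at
#' `49/45 * high`, and the regions between are left as don't-care
#' transitions.  At the default order 300, band (3, 45) Hz and fs 1 kHz
#' this yields unit gain (within about 0.25 dB) over 10--40 Hz, better
#' than -40 dB at 0.5 Hz and better than -70 dB at 100 Hz.
#'
#' @param order Filter order (number of taps minus one); must be even.
#' @param band Length-2 numeric, (low, high) corner frequencies in Hz.
#' @param fs Sampling frequency, Hz.
#' @return Numeric vector of `order + 1` symmetric tap coefficients.
#' @seealso [applyFilter()]
#' @examples
#' taps <- designBandpass(300, c(3, 45), 1000)
#' all.equal(taps, rev(taps))
#' @export
designBandpass <- function(order = 300, band = c(3, 45), fs = 1000) {
  .assertScalar(fs, "fs")
  if (order %% 2 != 0 || order < 4)
    stop("order must be an even integer >= 4 (type I linear phase)",
         call. = FALSE)
  low <- band[1]; high <- band[2]
  if (!(low > 0 && low < high && high < fs / 2))
    stop("band must satisfy 0 < low < high < fs/2", call. = FALSE)
  M <- order / 2
  f <- seq(0, fs / 2, length.out = 4001)
  passLo <- 5 / 3 * low
  passHi <- 8 / 9 * high
  stopLo <- low / 3
  stopHi <- 49 / 45 * high
  D <- as.numeric(f >= passLo & f <= passHi)
  W <- numeric(length(f))
  W[f <= stopLo] <- 10
  W[f >= passLo & f <= passHi] <- 1
  W[f >= stopHi] <- 10
  keep <- W > 0
  A <- cos(outer(2 * pi * f[keep] / fs, 0:M))
  Aw <- A * W[keep]
  G <- crossprod(Aw)
  g <- crossprod(Aw, D[keep] * W[keep])
  cvec <- rep(1, M + 1)            # H(0) = sum of cosine-basis weights
  Gi <- solve(G)
  lam <- as.numeric((crossprod(cvec, Gi %*% g)) /
                    (crossprod(cvec, Gi %*% cvec)))
  a <- as.numeric(Gi %*% (g - lam * cvec))
  c(rev(a[-1]) / 2, a[1], a[-1] / 2)
}

#' Magnitude response of an FIR filter
#'
#' @param taps FIR tap coefficients.
#' @param f Frequencies (Hz) at which to evaluate.
#' @param fs Sampling frequency, Hz.
#' @return Magnitude of the frequency response at each `f` (single pass;
#'   the zero-phase application in [applyFilter()] squares it).
#' @export
filterGain <- function(taps, f, fs) {
  k <- seq_along(taps) - 1
  vapply(f, function(fq)
    Mod(sum(taps * exp(-2i * pi * fq / fs * k))), numeric(1))
}

#' Apply an FIR filter with zero phase
#'
#' Forward-backward application: the signal is reflection-padded at both
#' ends, convolved with the taps, reversed, convolved again and reversed
#' back, so the net phase is exactly zero and R-peak latencies are not
#' biased.  The output has the length of the input; the net magnitude
#' response is the square of the single-pass response.
#'
#' @param x Numeric signal (mV).
#' @param taps FIR coefficients from [designBandpass()].
#' @return Filtered signal, same length as `x`.
#' @export
applyFilter <- function(x, taps) {
  nt <- length(taps)
  n <- length(x)
  if (n <= nt)
    stop("signal length (", n, ") must exceed the filter length (", nt,
         ")", call. = FALSE)
  pad <- nt
  # FFT convolution at a 2-3-5-smooth length (awkward lengths make the
  # mixed-radix FFT quadratic)
  convOpen <- function(a, b) {
    L <- length(a) + length(b) - 1L
    Lp <- stats::nextn(L, c(2L, 3L, 5L))
    fa <- stats::fft(c(a, numeric(Lp - length(a))))
    fb <- stats::fft(c(b, numeric(Lp - length(b))))
    Re(stats::fft(fa * fb, inverse = TRUE))[seq_len(L)] / Lp
  }
  onePass <- function(v) {
    ext <- c(2 * v[1] - v[(pad + 1):2],       # reflected head
             v,
             2 * v[n] - v[(n - 1):(n - pad)]) # reflected tail
    full <- convOpen(ext, taps)
    # the group-delay-centered slice recovers the original support
    full[(pad + (nt - 1) / 2 + 1):(pad + (nt - 1) / 2 + n)]
  }
  rev(onePass(rev(onePass(x))))
}

#' Hamilton R-peak detection
#'
#' Implements the open-source Hamilton QRS detection rules on a
#' band-passed ECG: band-limited differentiation and rectification, an
#' 80 ms moving-window integration, adaptive dual thresholds maintained
#' from running medians of the last eight QRS and noise peak heights
#' (threshold = noise + 0.3125 * (QRS - noise)), a 200 ms refractory
#' period, T-wave discrimination within 360 ms of the previous detection
#' (rejected when the local slope falls below half the previous QRS
#' slope), and a search-back pass triggered at 1.5 times the running mean
#' RR interval accepting the best skipped peak above half the threshold.
#' Each detection is refined to the local extremum of the input signal.
#'
#' @param x Band-passed ECG signal, mV.
#' @param fs Sampling frequency, Hz (>= 100).
#' @return Integer vector of R-peak sample indices (possibly empty).
#' @seealso [beatSeries()], [extractTemplates()]
#' @export
detectRPeaks <- function(x, fs) {
  .assertScalar(fs, "fs")
  if (fs < 100) stop("fs must be >= 100 Hz", call. = FALSE)
  n <- length(x)
  if (n < round(0.3 * fs) || all(x == x[1])) return(integer())

  # band-limited differentiation: a 25 ms smoother confines the
  # derivative to the 8-16 Hz QRS energy band before rectification
  sm <- movingAverage(x, max(1L, round(0.025 * fs)))
  absDeriv <- abs(c(0, diff(sm)))
  w <- max(1L, round(0.08 * fs))
  ma <- movingAverageCausal(absDeriv, w)

  # candidate peaks: local maxima of the integrated signal
  up <- diff(ma) > 0
  cand <- which(c(FALSE, up[-length(up)] & !up[-1], FALSE))
  if (!length(cand)) return(integer())
  h <- ma[cand]

  refr <- round(0.2 * fs)
  twin <- round(0.36 * fs)
  learn <- min(n, round(2 * fs))
  qrsBuf <- rep(max(ma[seq_len(learn)]) * 0.6, 8)
  noiseBuf <- rep(stats::median(ma[seq_len(learn)]), 8)
  rrBuf <- rep(round(0.8 * fs), 8)

  slopeAt <- function(i) max(absDeriv[max(1L, i - w):i])

  peaks <- integer()
  lastQRS <- -n
  lastSlope <- Inf
  skipped <- integer()      # sub-threshold candidates since the last QRS
  th <- function() {
    nq <- stats::median(noiseBuf)
    nq + 0.3125 * (stats::median(qrsBuf) - nq)
  }
  acceptQRS <- function(i, height) {
    qrsBuf <<- c(qrsBuf[-1], height)
    if (length(peaks)) rrBuf <<- c(rrBuf[-1], i - lastQRS)
    peaks <<- c(peaks, i)
    lastQRS <<- i
    lastSlope <<- slopeAt(i)
    skipped <<- integer()
  }

  for (ci in seq_along(cand)) {
    i <- cand[ci]
    height <- h[ci]
    if (i - lastQRS <= refr) next
    isT <- (i - lastQRS <= twin) && (slopeAt(i) < 0.5 * lastSlope)
    if (!isT && height > th()) {
      acceptQRS(i, height)
    } else {
      noiseBuf <- c(noiseBuf[-1], height)
      skipped <- c(skipped, i)
      # search-back: overdue beat at 1.5x the running RR estimate
      if (length(peaks) && (i - lastQRS) > 1.5 * mean(rrBuf) &&
          length(skipped)) {
        sh <- ma[skipped]
        best <- which.max(sh)
        if (sh[best] > 0.5 * th()) {
          j <- skipped[best]
          later <- skipped[skipped > j]
          acceptQRS(j, sh[best])
          skipped <- later
        }
      }
    }
  }
  if (!length(peaks)) return(integer())

  # refine each detection to the R apex in the input signal; the causal
  # integrator lags the QRS, so look back one window plus 10 ms
  back <- as.integer(w + round(0.01 * fs))
  fwd <- as.integer(round(0.01 * fs))
  refined <- vapply(peaks, function(i) {
    lo <- max(1L, i - back)
    hi <- min(n, i + fwd)
    lo + which.max(abs(x[lo:hi])) - 1L
  }, integer(1))
  refined <- sort(unique(refined))
  # drop refinements collapsing within the refractory of a prior beat
  if (length(refined) > 1L)
    refined <- refined[c(TRUE, diff(refined) > refr)]
  refined
}

#' Extract fixed-window beat templates
#'
#' Cuts one fixed-length waveform per R peak, `window[1]` ms before to
#' `window[2]` ms after the fiducial sample.  Beats whose window is not
#' fully supported by the record are dropped and reported in the
#' `dropped` slot.
#'
#' @param x Band-passed ECG signal, mV.
#' @param rIdx Integer R-peak sample indices (or a [BeatSeries-class]).
#' @param fs Sampling frequency, Hz.
#' @param window Length-2 numeric, (pre, post) in ms.  Default
#'   `c(200, 400)` covers the full P-QRS-T complex at rest.
#' @return A [BeatTemplateSet-class].
#' @export
extractTemplates <- function(x, rIdx, fs, window = c(200, 400)) {
  if (is(rIdx, "BeatSeries")) {
    fs <- rIdx@fs
    rIdx <- rIdx@rIndices
  }
  .assertScalar(fs, "fs")
  pre <- round(window[1] / 1000 * fs)
  post <- round(window[2] / 1000 * fs)
  n <- length(x)
  ok <- rIdx - pre >= 1L & rIdx + post <= n
  kept <- which(ok)
  if (!length(kept))
    stop("no beat has full window support within the record",
         call. = FALSE)
  tm <- t(vapply(rIdx[kept], function(i) x[(i - pre):(i + post)],
                 numeric(pre + post + 1L)))
  new("BeatTemplateSet", templates = tm, fs = fs,
      window = as.numeric(window), beatIndex = as.integer(kept),
      dropped = as.integer(which(!ok)))
}
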