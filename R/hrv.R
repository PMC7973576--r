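#' NN intervals from a labeled beat series
#'
#' Builds the normal-to-normal interval series: successive differences of
#' the beat times, in ms, keeping only intervals whose both endpoint
#' beats are labeled normal.  Intervals adjacent to an outlier beat are
#' therefore excluded, as are intervals outside the `rangeMs`
#' physiological band (ectopy/artifact guard).
#'
#' @param series A [BeatSeries-class].
#' @param rangeMs Length-2 numeric: admissible interval range in ms
#'   (default 300--2000, i.e. 30--200 BPM).
#' @return Numeric vector of NN intervals in ms, with attribute
#'   `"nExcluded"` giving the number of intervals dropped by either rule.
#' @export
nnFromBeats <- function(series, rangeMs = c(300, 2000)) {
  stopifnot(is(series, "BeatSeries"))
  normal <- beatLabels(series) == "normal"
  if (sum(normal) < 2L)
    stop("empty NN series: fewer than 2 normal beats", call. = FALSE)
  t <- rTimes(series) * 1000
  nn <- diff(t)
  ok <- normal[-length(normal)] & normal[-1]
  inRange <- nn >= rangeMs[1] & nn <= rangeMs[2]
  out <- nn[ok & inRange]
  attr(out, "nExcluded") <- sum(!(ok & inRange))
  out
}

#' Poincare plot descriptors and time-domain HRV
#'
#' From an NN series computes SDNN (SD of the intervals), SDSD (SD of
#' their successive differences), the Poincare minor/major axis
#' dispersions `SD1 = sqrt(SDSD^2 / 2)` and
#' `SD2 = sqrt(2 * SDNN^2 - SDSD^2 / 2)`, their ratio, and the fitted
#' ellipse area `S = pi * SD1 * SD2`.  Sample (n-1) standard deviations
#' are used throughout.  Should `2 * SDNN^2` fall below `SDSD^2 / 2`
#' numerically, SD2 clamps to 0 and the ratio is `NA`.
#'
#' @param nn Numeric NN intervals, ms (length >= 3).
#' @return A list with `sdnn`, `sdsd`, `sd1`, `sd2`, `sdRatio`, `areaS`
#'   (ms^2) and `n`.
#' @examples
#' poincare(c(800, 820, 800, 820, 800, 820))
#' @export
poincare <- function(nn) {
  if (length(nn) < 3L)
    stop("insufficient data: need >= 3 NN intervals", call. = FALSE)
  sdnn <- stats::sd(nn)
  sdsd <- stats::sd(diff(nn))
  sd1 <- sqrt(sdsd^2 / 2)
  sd2sq <- 2 * sdnn^2 - sdsd^2 / 2
  sd2 <- sqrt(max(sd2sq, 0))
  list(sdnn = sdnn, sdsd = sdsd, sd1 = sd1, sd2 = sd2,
       sdRatio = if (sd2 > 0) sd1 / sd2 else NA_real_,
       areaS = pi * sd1 * sd2, n = length(nn))
}

#' Detrended fluctuation analysis
#'
#' First-order DFA of an NN series: the mean-centered series is
#' integrated, split into non-overlapping windows of `n` beats, each
#' window is detrended by a least-squares line, and the fluctuation
#' `F(n)` is the root mean square of the residuals pooled over windows.
#' The scaling exponents are the slopes of `log F(n)` versus `log n`
#' fitted over the short-range (`alpha1`, default 4--16 beats) and
#' long-range (`alpha2`, default 16--64 beats) window sizes.  Pure
#' uncorrelated noise gives exponents near 0.5, an integrated random walk
#' near 1.5.
#'
#' @param nn Numeric NN intervals, ms.
#' @param shortRange,longRange Length-2 integer ranges of window sizes
#'   (beats) for the two exponents.
#' @return A list of class `"DFAResult"` with `windowSizes`,
#'   `fluctuation` (`F(n)`, ms), `alpha1`, `alpha2` and `alphaOverall`
#'   (slope over both ranges combined).
#' @export
dfa <- function(nn, shortRange = c(4, 16), longRange = c(16, 64)) {
  nmax <- max(longRange)
  if (length(nn) < 2 * nmax)
    stop("insufficient data: need >= ", 2 * nmax, " intervals",
         call. = FALSE)
  sizes <- unique(round(exp(seq(log(min(shortRange)), log(nmax),
                                length.out = 24))))
  y <- cumsum(nn - mean(nn))
  N <- length(y)
  fl <- vapply(sizes, function(wn) {
    m <- N %/% wn
    ym <- matrix(y[seq_len(m * wn)], nrow = wn)
    t <- seq_len(wn)
    tc <- t - mean(t)
    stt <- sum(tc^2)
    mu <- colMeans(ym)
    slope <- colSums(ym * tc) / stt
    res <- ym - rep(mu, each = wn) - outer(tc, slope)
    sqrt(mean(res^2))
  }, numeric(1))
  fit <- function(rng) {
    sel <- sizes >= rng[1] & sizes <= rng[2] & fl > 0
    if (sum(sel) < 2) return(NA_real_)
    unname(stats::coef(stats::lm(log(fl[sel]) ~ log(sizes[sel])))[2])
  }
  structure(list(windowSizes = sizes, fluctuation = fl,
                 alpha1 = fit(shortRange), alpha2 = fit(longRange),
                 alphaOverall = fit(range(shortRange, longRange))),
            class = "DFAResult")
}

#' All HRV metrics for one beat series
#'
#' Convenience wrapper: builds the NN series with [nnFromBeats()] and
#' returns the Poincare descriptors together with the DFA exponents
#' (exponents are `NA` when the series is too short for the requested
#' window sizes).
#'
#' @param series A [BeatSeries-class].
#' @param ... Passed to [dfa()].
#' @return A list with `sdnn`, `sdsd`, `sd1`, `sd2`, `sdRatio`, `areaS`,
#'   `alpha1`, `alpha2` and `nIntervals`.
#' @export
hrvMetrics <- function(series, ...) {
  nn <- nnFromBeats(series)
  p <- poincare(nn)
  d <- tryCatch(dfa(nn, ...),
                error = function(e) list(alpha1 = NA_real_,
                                         alpha2 = NA_real_))
  list(sdnn = p$sdnn, sdsd = p$sdsd, sd1 = p$sd1, sd2 = p$sd2,
       sdRatio = p$sdRatio, areaS = p$areaS,
       alpha1 = d$alpha1, alpha2 = d$alpha2, nIntervals = p$n)
}
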