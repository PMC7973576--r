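#' Synthetic dual-device configuration
#'
#' Bundles every knob of the paired-recording generator: recording length,
#' heart-rate statistics of the beat process, additive noise and baseline
#' wander, contact-loss (saturation) episodes on the experimental
#' channel(s), the inter-device sample offset and the optical
#' synchronization pulse train.  All randomness downstream derives from
#' `seed`.
#'
#' @param duration Recording length in seconds.
#' @param fs Sampling frequency in Hz.
#' @param hrMean Mean heart rate in BPM.  A resting rate is expected in
#'   the 60--100 BPM band; values outside it are accepted with a warning.
#' @param sdnnTarget Target SDNN of the NN-interval series, ms.
#' @param sdsdTarget Target SDSD of the NN-interval series, ms.
#' @param noiseRms RMS of band-limited measurement noise, mV (referred to
#'   the electrode, i.e. before the 11000x gain).
#' @param wanderAmp Baseline wander amplitude, mV.
#' @param wanderFreq Baseline wander frequency, Hz.
#' @param satRate Contact-loss episodes per minute on each experimental
#'   channel.
#' @param satDur Duration of each contact-loss episode, seconds.
#' @param syncOffset Inter-device offset in samples (device B minus
#'   device A; positive means B sees every event later in its own index).
#' @param nSyncPulses Number of LED synchronization pulses.
#' @param pulseWidth Width of each synchronization pulse, seconds.
#' @param nExpChannels Number of experimental ECG channels on device B.
#' @param ecgAmp R-wave amplitude of the synthetic beat template, mV.
#' @param adcBits,vcc,gain Acquisition front-end parameters used to
#'   quantize the ECG channels (see [adcToMillivolts()]).
#' @param seed Integer seed fixing all randomness.
#'
#' @return A validated list of class `"SynthConfig"`.
#' @seealso [generatePair()], [generateNNSeries()]
#' @export
synthConfig <- function(duration = 300, fs = 1000, hrMean = 75,
                        sdnnTarget = 50, sdsdTarget = 30,
                        noiseRms = 0.005, wanderAmp = 0.01,
                        wanderFreq = 0.3, satRate = 0, satDur = 1,
                        syncOffset = 0, nSyncPulses = NULL,
                        pulseWidth = 2, nExpChannels = 1,
                        ecgAmp = 0.1, adcBits = 10, vcc = 3.3,
                        gain = 11000, seed = 1) {
  .assertScalar(duration, "duration")
  .assertScalar(fs, "fs")
  .assertScalar(hrMean, "hrMean")
  if (hrMean < 60 || hrMean > 100)
    warning("hrMean ", hrMean, " BPM is outside the 60-100 BPM resting band")
  if (sdnnTarget < 0 || sdsdTarget < 0)
    stop("sdnnTarget and sdsdTarget must be non-negative", call. = FALSE)
  if (sdsdTarget > 2 * sdnnTarget)
    stop("infeasible RR targets: sdsdTarget must be <= 2 * sdnnTarget",
         call. = FALSE)
  if (is.null(nSyncPulses)) nSyncPulses <- max(3L, round(duration / 20))
  if (nSyncPulses < 1) stop("need at least one sync pulse", call. = FALSE)
  if (satRate > 0) {
    nEp <- round(satRate * duration / 60)
    if (nEp * (satDur + 1) > duration - 6)
      stop("infeasible saturation schedule: ", nEp, " episodes of ",
           satDur, " s do not fit in ", duration, " s", call. = FALSE)
  }
  cfg <- list(duration = duration, fs = fs, hrMean = hrMean,
              sdnnTarget = sdnnTarget, sdsdTarget = sdsdTarget,
              noiseRms = noiseRms, wanderAmp = wanderAmp,
              wanderFreq = wanderFreq, satRate = satRate, satDur = satDur,
              syncOffset = as.integer(syncOffset),
              nSyncPulses = as.integer(nSyncPulses),
              pulseWidth = pulseWidth,
              nExpChannels = as.integer(nExpChannels), ecgAmp = ecgAmp,
              adcBits = as.integer(adcBits), vcc = vcc, gain = gain,
              seed = as.integer(seed))
  class(cfg) <- "SynthConfig"
  cfg
}

#' Generate a stationary NN-interval series
#'
#' Draws a first-order autoregressive RR series whose stationary moments
#' match the requested SDNN and SDSD.  With mean interval
#' `m = 60000 / hrMean` ms the model is
#' `x_k - m = phi * (x_{k-1} - m) + e_k`; the two targets determine both
#' parameters in closed form: `phi = 1 - sdsd^2 / (2 * sdnn^2)` and
#' innovation SD `sdnn * sqrt(1 - phi^2)`.  The first interval is drawn
#' from the stationary distribution, so the series is stationary from the
#' start.
#'
#' @param hrMean Mean heart rate, BPM.
#' @param sdnnTarget Target SDNN, ms.  `0` yields a constant series (and
#'   requires `sdsdTarget = 0`).
#' @param sdsdTarget Target SDSD, ms.  Feasibility requires
#'   `0 < sdsdTarget < 2 * sdnnTarget` when `sdnnTarget > 0`.
#' @param nBeats Number of intervals to draw (>= 2).
#' @param seed Integer seed; the same inputs and seed give the identical
#'   series.
#'
#' @return Numeric vector of NN intervals in ms.
#' @examples
#' nn <- generateNNSeries(60, 50, 30, 1000, seed = 1)
#' c(mean(nn), sd(nn), sd(diff(nn)))
#' @export
generateNNSeries <- function(hrMean, sdnnTarget, sdsdTarget, nBeats,
                             seed = 1) {
  .assertScalar(hrMean, "hrMean")
  if (nBeats < 2) stop("nBeats must be >= 2", call. = FALSE)
  m <- 60000 / hrMean
  if (sdnnTarget == 0) {
    if (sdsdTarget != 0)
      stop("sdsdTarget must be 0 when sdnnTarget is 0", call. = FALSE)
    return(rep(m, nBeats))
  }
  phi <- 1 - sdsdTarget^2 / (2 * sdnnTarget^2)
  if (sdsdTarget <= 0 || phi <= -1 || phi >= 1)
    stop("infeasible targets: need 0 < sdsdTarget < 2 * sdnnTarget",
         call. = FALSE)
  sigmaE <- sdnnTarget * sqrt(1 - phi^2)
  withSeed(seed, {
    d1 <- rnorm(1, sd = sdnnTarget)
    e <- rnorm(nBeats - 1, sd = sigmaE)
    d <- c(d1, stats::filter(e, phi, method = "recursive", init = d1))
    m + as.numeric(d)
  })
}

# Fixed piecewise-Gaussian P-QRS-T beat template sampled at fs, spanning
# -250..+450 ms around the R apex; `amp` is the R-wave amplitude in mV.
ecgBeatWave <- function(fs, amp = 0.1) {
  t <- seq(-0.25, 0.45, by = 1 / fs)
  g <- function(center, sd, a) a * exp(-0.5 * ((t - center) / sd)^2)
  wave <- g(-0.170, 0.025, 0.12) + g(-0.022, 0.008, -0.15) +
    g(0, 0.010, 1.00) + g(0.022, 0.009, -0.20) + g(0.220, 0.045, 0.30)
  list(offsets = round(t * fs), wave = amp * wave)
}

# Band-limited Gaussian noise: white noise shaped to the analog front-end
# band [0.5, 40] Hz and rescaled to the requested RMS.
.bandNoise <- function(n, rms, fs) {
  if (rms <= 0 || n == 0L) return(numeric(n))
  w <- rnorm(n)
  bf <- signal::butter(2, c(0.5, 40) / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, w)
  x * rms / stats::sd(x)
}

#' Generate a paired two-device recording with ground truth
#'
#' Synthesizes the full dual-stream study setup: device A carries the
#' reference ECG plus the LED synchronization channel; device B carries
#' `nExpChannels` experimental ECG channels plus the luminosity channel,
#' delayed by `syncOffset` samples.  Both ECG streams place the same fixed
#' P-QRS-T template at the ground-truth R times, then add independent
#' band-limited noise, sinusoidal baseline wander and (on the experimental
#' channels only) contact-loss episodes clamped at an ADC rail, before
#' 10-bit quantization through the acquisition transfer function.
#' Rectangular pulses appear on the LED channel and, shifted by the
#' inter-device offset, on the luminosity channel.
#'
#' @param cfg A [synthConfig()] list.
#' @return A list with elements `deviceA`, `deviceB` (both
#'   [RawRecording-class]) and `truth`, a list with `r_times_ref` and
#'   `r_times_exp` (seconds, each in its own device timebase), `nn_ms`,
#'   `sat_windows` (per experimental channel, start/end seconds in device
#'   B's timebase), `true_offset` (samples) and `pulse_times` (seconds,
#'   device A timebase).
#' @examples
#' pair <- generatePair(synthConfig(duration = 30, seed = 7))
#' pair$deviceA
#' @export
generatePair <- function(cfg) {
  stopifnot(inherits(cfg, "SynthConfig"))
  fs <- cfg$fs
  N <- round(cfg$duration * fs)
  off <- cfg$syncOffset
  if (abs(off) >= N)
    stop("syncOffset exceeds the recording length", call. = FALSE)

  withSeed(cfg$seed, {
    ## ground-truth beat times (device-A timebase, seconds)
    nMax <- ceiling(cfg$duration / 60 * cfg$hrMean) + 10L
    nn <- generateNNSeries(cfg$hrMean, cfg$sdnnTarget, cfg$sdsdTarget,
                           nMax, seed = sample.int(.Machine$integer.max, 1))
    if (any(nn < 250)) {
      warning("NN intervals below 250 ms clipped during synthesis")
      nn <- pmax(nn, 250)
    }
    rt <- 0.5 + cumsum(c(0, nn[-1])) / 1000
    rt <- rt[rt <= cfg$duration - 0.5]
    if (length(rt) < 2) stop("configuration yields < 2 beats", call. = FALSE)

    ## clean waveform over the extended absolute sample grid
    kmin <- min(0L, -off)
    kmax <- max(N - 1L, N - 1L - off)
    M <- kmax - kmin + 1L
    clean <- numeric(M)
    tpl <- ecgBeatWave(fs, cfg$ecgAmp)
    for (tb in rt) {
      idx <- round(tb * fs) + tpl$offsets - kmin + 1L
      clean[idx] <- clean[idx] + tpl$wave
    }
    atK <- function(k) clean[k - kmin + 1L]   # k is 0-based absolute sample

    spec <- function(name, role) channelSpec(name, role, cfg$adcBits,
                                             cfg$vcc, cfg$gain)
    mkEcg <- function(k0) {
      mv <- atK(k0 + 0:(N - 1L)) +
        .bandNoise(N, cfg$noiseRms, fs) +
        cfg$wanderAmp * sin(2 * pi * cfg$wanderFreq * (0:(N - 1L)) / fs +
                            runif(1, 0, 2 * pi))
      millivoltsToAdc(mv, spec("x", "ecg_exp"))
    }

    ## synchronization pulse train (absolute onsets, seconds)
    margin <- 3 + cfg$pulseWidth
    pulseTimes <- seq(margin, cfg$duration - margin,
                      length.out = cfg$nSyncPulses)
    pulseAtK <- function(k) {
      lvl <- rep.int(100L, length(k))
      for (pt in pulseTimes) {
        on <- round(pt * fs)
        lvl[k >= on & k < on + round(cfg$pulseWidth * fs)] <- 923L
      }
      n <- pmin(pmax(lvl + round(rnorm(length(k), sd = 2)), 0L), 1023L)
      as.integer(n)
    }

    ## device A: reference ECG + LED
    recA <- rawRecording(
      cbind(mkEcg(0L), pulseAtK(0:(N - 1L))),
      list(spec("ECG_REF", "ecg_ref"),
           channelSpec("LED", "led", cfg$adcBits, cfg$vcc, 1)),
      fs = fs, deviceId = "A", meta = list(seed = cfg$seed))

    ## device B: experimental channels (+ saturation) + luminosity
    hi <- 2^cfg$adcBits - 1
    nEp <- if (cfg$satRate > 0) round(cfg$satRate * cfg$duration / 60) else 0L
    expCols <- vector("list", cfg$nExpChannels)
    satWindows <- vector("list", cfg$nExpChannels)
    for (ch in seq_len(cfg$nExpChannels)) {
      counts <- mkEcg(-off)
      wins <- matrix(numeric(), 0, 2,
                     dimnames = list(NULL, c("start", "end")))
      if (nEp > 0L) {
        slot <- (cfg$duration - 6) / nEp
        starts <- 3 + (seq_len(nEp) - 1) * slot +
          runif(nEp, 0, slot - cfg$satDur - 0.5)
        rails <- sample(c(0L, hi), nEp, replace = TRUE)
        L <- round(cfg$satDur * fs)
        for (e in seq_len(nEp)) {
          s0 <- round(starts[e] * fs)
          counts[(s0 + 1):(s0 + L)] <- rails[e]
          wins <- rbind(wins, c(s0 / fs, (s0 + L) / fs))
        }
      }
      expCols[[ch]] <- counts
      satWindows[[ch]] <- wins
    }
    recB <- rawRecording(
      do.call(cbind, c(expCols, list(pulseAtK((0:(N - 1L)) - off)))),
      c(lapply(seq_len(cfg$nExpChannels), function(ch)
          spec(paste0("A", ch), "ecg_exp")),
        list(channelSpec("LUX", "luminosity", cfg$adcBits, cfg$vcc, 1))),
      fs = fs, deviceId = "B", meta = list(seed = cfg$seed))
    names(satWindows) <- paste0("A", seq_len(cfg$nExpChannels))

    list(deviceA = recA, deviceB = recB,
         truth = list(
           r_times_ref = rt,
           r_times_exp = rt + off / fs,
           nn_ms = diff(rt) * 1000,
           sat_windows = satWindows,
           true_offset = off,
           pulse_times = pulseTimes))
  })
}
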