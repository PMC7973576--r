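# Shared fixture builders; everything is generated in code at test time.

# A two-channel recording with arbitrary small integer content.
tinyRecording <- function(n = 5, bits = 10L, fs = 1000, seed = 1) {
  set.seed(seed)
  m <- matrix(sample.int(2^bits, 2 * n, replace = TRUE) - 1L, ncol = 2)
  rawRecording(m,
               list(channelSpec("ECG_REF", "ecg_ref", adcBits = bits),
                    channelSpec("LED", "led", adcBits = bits, gain = 1)),
               fs = fs, deviceId = "T")
}

# Clean ECG-like signal: Gaussian R waves at the requested times (s).
beatTrain <- function(rTimesS, fs = 1000, durS = NULL, amp = 1,
                      widthS = 0.012) {
  if (is.null(durS)) durS <- max(rTimesS) + 0.5
  t <- seq(0, durS, by = 1 / fs)
  x <- numeric(length(t))
  for (rt in rTimesS) x <- x + amp * exp(-0.5 * ((t - rt) / widthS)^2)
  x
}

# Regular beat series with the given RR interval (ms).
regularBeats <- function(nBeats, rrMs, fs = 1000, labels = NULL) {
  beatSeries(1L + round((seq_len(nBeats) - 1) * rrMs / 1000 * fs), fs,
             labels)
}

# Independent brute-force DMEAN (explicit loops, no matrix shortcuts).
bruteDmean <- function(tm, tpThreshold = 70) {
  nb <- nrow(tm); ns <- ncol(tm)
  mu <- numeric(ns)
  for (j in seq_len(ns)) {
    s <- 0
    for (i in seq_len(nb)) s <- s + tm[i, j]
    mu[j] <- s / nb
  }
  dev <- matrix(0, nb, ns)
  for (i in seq_len(nb)) for (j in seq_len(ns))
    dev[i, j] <- abs(tm[i, j] - mu[j])
  pooled <- as.vector(dev)
  muD <- sum(pooled) / length(pooled)
  sigmaD <- sqrt(sum((pooled - muD)^2) / (length(pooled) - 1))
  bound <- muD + 0.5 * sigmaD
  tp <- numeric(nb)
  for (i in seq_len(nb)) {
    good <- 0
    for (j in seq_len(ns)) if (dev[i, j] <= bound) good <- good + 1
    tp[i] <- 100 * good / ns
  }
  list(tp = tp, kept = tp > tpThreshold)
}

# Detection performance of a detector output against ground-truth R
# sample indices at a +/- tolerance (samples).
detPerformance <- function(detected, truthIdx, tolSamples = 10) {
  sens <- if (length(truthIdx))
    mean(vapply(truthIdx, function(tt)
      any(abs(detected - tt) <= tolSamples), logical(1))) else NA
  ppv <- if (length(detected))
    mean(vapply(detected, function(dd)
      any(abs(truthIdx - dd) <= tolSamples), logical(1))) else NA
  list(sens = 100 * sens, ppv = 100 * ppv)
}
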