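test_that("the band-pass design meets its response contract", {
  taps <- designBandpass(300, c(3, 45), 1000)
  expect_length(taps, 301L)
  expect_equal(taps, rev(taps))                    # linear phase
  expect_lt(filterGain(taps, 0, 1000), 0.01)       # DC killed
  g10 <- filterGain(taps, 10, 1000)
  expect_gt(g10, 0.9); expect_lt(g10, 1.1)
  # passband within -3 dB, stopbands below -20 dB (single pass)
  pb <- filterGain(taps, seq(5, 40, by = 0.5), 1000)
  expect_gt(min(pb), 10^(-3 / 20))
  expect_lt(filterGain(taps, 0.5, 1000), 10^(-20 / 20))
  expect_lt(filterGain(taps, 100, 1000), 10^(-20 / 20))
})

test_that("bad filter specifications are rejected", {
  expect_error(designBandpass(301, c(3, 45), 1000), "even")
  expect_error(designBandpass(300, c(3, 600), 1000), "fs/2")
  expect_error(designBandpass(300, c(0, 45), 1000), "0 < low")
})

test_that("zero-phase filtering passes the band and rejects the edges", {
  taps <- designBandpass(300, c(3, 45), 1000)
  t <- (0:9999) / 1000
  mid <- 3000:7000

  y10 <- applyFilter(sin(2 * pi * 10 * t), taps)
  expect_gt(max(abs(y10[mid])), 0.9)
  expect_gt(cor(y10[mid], sin(2 * pi * 10 * t)[mid]), 0.999)  # no phase lag

  expect_lt(max(abs(applyFilter(rep(1, 5000), taps))), 0.01)

  y05 <- applyFilter(sin(2 * pi * 0.5 * t), taps)
  expect_lt(max(abs(y05[mid])), 0.1)

  expect_error(applyFilter(rnorm(100), taps), "exceed")
})

test_that("filtering is linear to machine tolerance", {
  taps <- designBandpass(300, c(3, 45), 1000)
  set.seed(3)
  x <- rnorm(2000); y <- rnorm(2000)
  lhs <- applyFilter(2.5 * x - 1.25 * y, taps)
  rhs <- 2.5 * applyFilter(x, taps) - 1.25 * applyFilter(y, taps)
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("the detector handles degenerate and single-beat inputs", {
  expect_identical(detectRPeaks(rep(0, 5000), 1000), integer())
  expect_identical(detectRPeaks(numeric(), 1000), integer())
  x <- beatTrain(1.0, fs = 1000, durS = 2.5)
  det <- detectRPeaks(x, 1000)
  expect_length(det, 1L)
  expect_lte(abs(det - 1001L), 10L)
})

test_that("detection recovers a clean regular beat train without duplicates", {
  rts <- seq(0.5, 29.5, by = 0.8)
  x <- beatTrain(rts, fs = 1000, durS = 30)
  det <- detectRPeaks(x, 1000)
  perf <- detPerformance(det, round(rts * 1000) + 1L)
  expect_equal(perf$sens, 100)
  expect_equal(perf$ppv, 100)
  expect_true(all(diff(det) > 200))    # refractory respected
})

test_that("template extraction drops edge beats and averages correctly", {
  fs <- 1000
  x <- beatTrain(c(0.05, 1, 2, 3), fs = fs, durS = 3.5)
  r <- c(51L, 1001L, 2001L, 3001L)
  ts <- extractTemplates(x, r, fs, window = c(200, 400))
  expect_equal(nBeats(ts), 3L)            # first beat lacks pre-window
  expect_equal(ts@dropped, 1L)
  expect_equal(beatIndex(ts), 2:4)
  expect_equal(ncol(templateMatrix(ts)), 601L)

  # identical beats give identical rows equal to their mean
  tm <- templateMatrix(ts)
  expect_equal(tm[1, ], tm[2, ], tolerance = 1e-12)
  expect_equal(meanTemplate(ts), tm[1, ], tolerance = 1e-12)

  # mean template equals a brute-force column loop
  set.seed(6)
  xr <- rnorm(5000)
  tsr <- extractTemplates(xr, c(500L, 1500L, 2500L, 3500L), fs)
  mt <- meanTemplate(tsr)
  tmr <- templateMatrix(tsr)
  loopMean <- vapply(seq_len(ncol(tmr)), function(j) {
    s <- 0
    for (i in seq_len(nrow(tmr))) s <- s + tmr[i, j]
    s / nrow(tmr)
  }, numeric(1))
  expect_equal(mt, loopMean)
  expect_error(extractTemplates(xr, 10L, fs), "window support")
})

test_that("filter plus detector recover every ground-truth beat cleanly", {
  taps <- designBandpass(300, c(3, 45), 1000)
  pair <- generatePair(synthConfig(duration = 60, noiseRms = 0.001,
                                   seed = 12))
  spec <- channelSpecOf(pair$deviceA, "ECG_REF")
  mv <- applyFilter(adcToMillivolts(channelData(pair$deviceA, "ECG_REF"),
                                    spec), taps)
  det <- detectRPeaks(mv, 1000)
  truth <- round(pair$truth$r_times_ref * 1000) + 1L
  perf <- detPerformance(det, truth)
  expect_equal(perf$sens, 100)
  expect_equal(perf$ppv, 100)
  expect_true(all(diff(det) > 200))
})
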