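test_that("matching a series against itself is the identity", {
  s <- regularBeats(100, 800)
  m <- matchRPeaks(s, s)
  expect_equal(m$deltaQrsPercent, 100)
  expect_equal(nrow(m$pairs), 100L)
  expect_length(m$unmatchedRef, 0L)
  expect_length(m$unmatchedExp, 0L)
})

test_that("missing and spurious beats move the QRS percentage as counted", {
  ref <- regularBeats(100, 800)
  drop <- c(10L, 40L, 70L)
  exp <- beatSeries(rIndices(ref)[-drop], 1000)
  m <- matchRPeaks(ref, exp)
  expect_equal(m$deltaQrsPercent, 97)
  expect_equal(m$unmatchedRef, drop)

  # 14 spurious extra detections per 100: percentages above 100 are legal
  spur <- rIndices(ref)[seq(3, 94, by = 7)] + 380L
  exp2 <- beatSeries(sort(c(rIndices(ref), spur)), 1000)
  m2 <- matchRPeaks(ref, exp2)
  expect_equal(m2$deltaQrsPercent, 114)
  expect_equal(nrow(m2$pairs), 100L)

  expect_error(matchRPeaks(beatSeries(integer(), 1000), ref), "no beats")
})

test_that("each beat is used at most once within the tolerance", {
  ref <- beatSeries(c(1000L, 2000L, 3000L), 1000)
  exp <- beatSeries(c(1010L, 1990L, 2050L, 3100L), 1000)
  m <- matchRPeaks(ref, exp, toleranceMs = 150)
  expect_equal(anyDuplicated(m$pairs[, "ref"]), 0L)
  expect_equal(anyDuplicated(m$pairs[, "exp"]), 0L)
  dt <- abs(rTimes(ref)[m$pairs[, "ref"]] - rTimes(exp)[m$pairs[, "exp"]])
  expect_true(all(dt <= 0.150))
})

test_that("instantaneous heart rate follows 60000/RR with band flags", {
  expect_equal(instantaneousHR(regularBeats(10, 1000))$hrBpm, rep(60, 9))
  expect_equal(instantaneousHR(regularBeats(10, 600))$hrBpm, rep(100, 9))
  hr <- instantaneousHR(regularBeats(10, 500))
  expect_equal(hr$hrBpm, rep(120, 9))
  expect_false(any(hr$inBand))         # tachycardic: flagged out of band
  expect_true(all(instantaneousHR(regularBeats(10, 800))$inBand))
  # outlier-labeled beats contribute no interval
  lab <- rep("normal", 10); lab[5] <- "outlier"
  hr2 <- instantaneousHR(regularBeats(10, 800, labels = lab))
  expect_equal(nrow(hr2), 7L)
  expect_equal(nrow(instantaneousHR(beatSeries(100L, 1000))), 0L)
})

test_that("the HR difference over matched beats behaves as stated", {
  ref <- regularBeats(50, 800)             # 75 BPM
  m <- matchRPeaks(ref, ref)
  d <- deltaHR(ref, ref, m)
  expect_equal(d$dhrMean, 0)
  expect_equal(d$dhrSd, 0)

  exp <- regularBeats(50, 1000)            # 60 BPM, same beat count
  m2 <- structure(list(pairs = cbind(ref = 1:50, exp = 1:50)),
                  class = "MatchedBeats")  # beat-by-beat pairing
  d2 <- deltaHR(ref, exp, m2)
  expect_equal(d2$dhrMean, -15)
  expect_equal(d2$dhrSd, 0)

  expect_error(deltaHR(ref, exp,
                       structure(list(pairs = m2$pairs[0, , drop = FALSE]),
                                 class = "MatchedBeats")),
               "fewer than 2")
})

test_that("signal detection error counts saturated runs only", {
  set.seed(2)
  clean <- as.integer(512 + round(rnorm(10000, sd = 20)))
  expect_equal(signalDetectionError(clean, 10, 1000), 0)

  # 40 of 100 samples clamped in one run (>= 50 ms at fs = 100)
  x <- as.integer(c(rep(500, 30), rep(1023, 40), rep(500, 30)))
  expect_equal(signalDetectionError(x, 10, fs = 100), 40)

  # sub-run-length rail touches do not count
  y <- clean; y[5000:5003] <- 1023L
  expect_equal(signalDetectionError(y, 10, 1000), 0)

  expect_error(signalDetectionError(integer(), 10, 1000), "empty")
})

test_that("SDE is invariant to ECG content without saturation", {
  pair <- generatePair(synthConfig(duration = 30, satRate = 4, satDur = 0.5,
                                   seed = 6))
  raw <- channelData(pair$deviceB, "A1")
  sde <- signalDetectionError(raw, 10, 1000)
  w <- pair$truth$sat_windows$A1
  expect_equal(sde, 100 * sum(w[, 2] - w[, 1]) / 30, tolerance = 0.01)
  # reference channel (beats, no saturation) scores 0
  expect_equal(signalDetectionError(channelData(pair$deviceA, "ECG_REF"),
                                    10, 1000), 0)
})

test_that("the Welch t-test wrapper matches its contract", {
  x <- c(1, 2, 3, 4)
  expect_equal(unpairedTTest(x, x), 1)
  set.seed(4)
  a <- rnorm(200); b <- rnorm(200, mean = 5)
  expect_lt(unpairedTTest(a, b), 1e-3)
  expect_error(unpairedTTest(c(1), c(1, 2)), ">= 2")
  expect_error(unpairedTTest(c(1, 1), c(2, 2)), "constant")
})
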