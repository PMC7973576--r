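test_that("a hand-written acquisition file parses to the expected object", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "# BEGIN HEADER",
    paste0('# {"fs":1000,"bits":10,"channels":[',
           '{"name":"ECG_REF","role":"ecg_ref"},',
           '{"name":"LED","role":"led"}],"device_id":"A"}'),
    "# END HEADER",
    "512\t100", "515\t100", "509\t900"), f)
  rec <- readRecording(f)
  expect_s4_class(rec, "RawRecording")
  expect_equal(samplingRate(rec), 1000)
  expect_equal(nrow(samples(rec)), 3L)
  expect_equal(length(channels(rec)), 2L)
  expect_equal(channelRoles(rec), c("ecg_ref", "led"))
  expect_equal(channelData(rec, "LED"), c(100L, 100L, 900L))
})

test_that("malformed headers and out-of-range values are rejected", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# {oops}", "1\t2"), f)
  expect_error(readRecording(f), "malformed header")

  writeLines(c("# BEGIN HEADER", "# not json at all", "# END HEADER",
               "1\t2"), f)
  expect_error(readRecording(f), "malformed JSON")

  writeLines(c(
    "# BEGIN HEADER",
    paste0('# {"fs":1000,"bits":10,"channels":[',
           '{"name":"E","role":"ecg_ref"}],"device_id":"A"}'),
    "# END HEADER",
    "512", "1024"), f)
  expect_error(readRecording(f), "1024.*row 2.*'E'")
})

test_that("write/read round-trips bit-exactly, deterministically, incl. empty", {
  # empty body: header-only file
  rec0 <- rawRecording(matrix(integer(), 0, 1),
                       list(channelSpec("E", "ecg_ref")), fs = 500)
  f <- withr::local_tempfile(fileext = ".txt")
  writeRecording(rec0, f)
  expect_equal(nrow(samples(readRecording(f))), 0L)

  # randomized round trips over resolutions and lengths
  set.seed(42)
  for (k in 1:30) {
    bits <- sample(c(6L, 10L), 1)
    n <- sample(0:2000, 1)
    fs <- sample(c(100, 500, 1000), 1)
    m <- matrix(sample.int(2^bits, 3 * n, replace = TRUE) - 1L, ncol = 3)
    rec <- rawRecording(
      m, list(channelSpec("E1", "ecg_ref", bits),
              channelSpec("E2", "ecg_exp", bits),
              channelSpec("L", "luminosity", bits, gain = 1)),
      fs = fs, deviceId = paste0("dev", k))
    writeRecording(rec, f)
    back <- readRecording(f)
    expect_identical(samples(back), samples(rec))
    expect_equal(samplingRate(back), fs)
    expect_equal(channelRoles(back), channelRoles(rec))
    expect_equal(deviceId(back), deviceId(rec))
  }

  # byte determinism
  rec <- tinyRecording(50)
  f2 <- withr::local_tempfile(fileext = ".txt")
  writeRecording(rec, f)
  writeRecording(rec, f2)
  expect_identical(readBin(f, "raw", 1e6), readBin(f2, "raw", 1e6))
})

test_that("ADC counts convert to millivolts per the symmetric convention", {
  spec <- channelSpec("E", "ecg_ref", adcBits = 10, vcc = 3.3,
                      gain = 11000)
  expect_equal(adcToMillivolts(512L, spec), 0)
  expect_equal(adcToMillivolts(0L, spec), (0 / 1024 - 0.5) * 3.3 / 11000 * 1000)
  expect_equal(adcToMillivolts(0L, spec), -0.15)
  # full-scale span matches the arithmetic oracle
  expect_equal(adcToMillivolts(1023L, spec) - adcToMillivolts(0L, spec),
               (1023 / 1024) * 3.3 / 11000 * 1000)
  # strictly monotone; midpoint within one LSB-equivalent of 0 mV
  mv <- adcToMillivolts(0:1023, spec)
  expect_true(all(diff(mv) > 0))
  lsb <- 3.3 / 11000 * 1000 / 1024
  expect_lt(abs(mv[513]), lsb)
  expect_error(adcToMillivolts(1024L, spec), "range")
})

test_that("stream rate is linear and rejects bad input", {
  expect_equal(streamRate(1, 1), 0.008)
  expect_equal(streamRate(1000, 14), 112)
  expect_error(streamRate(0, 7), "positive")
  set.seed(1)
  for (k in 1:10) {
    fs <- runif(1, 1, 5000); fb <- runif(1, 1, 32); a <- runif(1, 0.1, 4)
    expect_equal(streamRate(a * fs, fb), a * streamRate(fs, fb))
    expect_equal(streamRate(fs, a * fb), a * streamRate(fs, fb))
  }
})
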