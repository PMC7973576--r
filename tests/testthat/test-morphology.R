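mkTset <- function(tm, fs = 1000) {
  new("BeatTemplateSet", templates = tm, fs = fs, window = c(200, 400),
      beatIndex = seq_len(nrow(tm)), dropped = integer())
}

test_that("identical templates are all kept with TP 100", {
  tm <- matrix(rep(sin(seq(0, 2 * pi, length.out = 60)), each = 5), 5, 60)
  ts <- dmeanClassify(mkTset(tm))
  expect_equal(tpPercent(ts), rep(100, 5))
  expect_true(all(keptBeats(ts)))
  expect_error(dmeanClassify(mkTset(tm[1:2, ])), "insufficient")
})

test_that("a grossly deviant beat is rejected by the TP criterion", {
  set.seed(8)
  base <- sin(seq(0, 2 * pi, length.out = 100))
  tm <- matrix(rep(base, each = 20), 20, 100)
  tm <- tm + rnorm(length(tm), sd = 0.01)
  sigma <- sd(as.vector(tm))
  bad <- tm[20, ]
  bad[1:60] <- bad[1:60] + 10 * sigma      # 60% of samples far off
  tm[20, ] <- bad
  ts <- dmeanClassify(mkTset(tm))
  expect_lte(tpPercent(ts)[20], 40)
  expect_false(keptBeats(ts)[20])
  expect_true(all(keptBeats(ts)[1:19]))
  # matches the independent brute-force evaluation of the three steps
  ref <- bruteDmean(tm)
  expect_equal(tpPercent(ts), ref$tp)
  expect_identical(keptBeats(ts), ref$kept)
})

test_that("classification equals brute force on random template sets", {
  set.seed(15)
  for (k in 1:25) {
    nb <- sample(3:30, 1); ns <- sample(20:200, 1)
    tm <- matrix(rnorm(nb * ns), nb, ns)
    if (k %% 3 == 0) tm[1, ] <- tm[1, ] + 3       # occasional outlier
    ts <- dmeanClassify(mkTset(tm))
    ref <- bruteDmean(tm)
    expect_equal(tpPercent(ts), ref$tp)
    expect_identical(keptBeats(ts), ref$kept)
  }
})

test_that("the keep threshold is monotone and has a trivial floor", {
  set.seed(16)
  tm <- matrix(rnorm(15 * 80), 15, 80)
  ts0 <- dmeanClassify(mkTset(tm), tpThreshold = 0)
  expect_true(all(keptBeats(ts0)))
  prev <- rep(TRUE, 15)
  for (th in c(0, 25, 50, 75, 95)) {
    k <- keptBeats(dmeanClassify(mkTset(tm), tpThreshold = th))
    expect_true(all(k <= prev))   # raising the bar never re-admits a beat
    prev <- k
  }
})

test_that("Pearson correlation matches the explicit-sum formula", {
  x <- c(1, 2, 3, 4)
  expect_equal(pcc(x, x), 1)
  expect_equal(pcc(x, -x), -1)
  y <- c(2, 4, 6, 9)
  # explicit-loop evaluation of the normalized cross-product
  n <- length(x)
  xb <- sum(x) / n; yb <- sum(y) / n
  num <- den1 <- den2 <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - xb) * (y[i] - yb)
    den1 <- den1 + (x[i] - xb)^2
    den2 <- den2 + (y[i] - yb)^2
  }
  expect_equal(pcc(x, y), num / (sqrt(den1) * sqrt(den2)))
  expect_error(pcc(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pcc(x, c(1, 2)), "equal length")
})

test_that("correlation is invariant to positive affine maps, flips sign", {
  set.seed(17)
  for (k in 1:20) {
    x <- rnorm(50); y <- rnorm(50)
    r <- pcc(x, y)
    expect_equal(pcc(2.3 * x + 7, y), r, tolerance = 1e-12)
    expect_equal(pcc(x, 0.4 * y - 2), r, tolerance = 1e-12)
    expect_equal(pcc(-1.7 * x + 1, y), -r, tolerance = 1e-12)
  }
})

test_that("range-normalized RMSE matches its closed forms", {
  ref <- c(0, 1, 2, 1, 0)
  expect_equal(nrmse(ref, ref), 0)
  expect_equal(nrmse(ref, ref + 0.5), 100 * 0.5 / 2)  # shift / range
  set.seed(18)
  a <- rnorm(100); b <- rnorm(100)
  sq <- 0
  for (i in 1:100) sq <- sq + (a[i] - b[i])^2
  expect_equal(nrmse(a, b), 100 * sqrt(sq / 100) / (max(a) - min(a)))
  expect_error(nrmse(rep(1, 5), rnorm(5)), "flat reference")
})

test_that("recording-level scores hit the identity limit and degenerate case", {
  base <- sin(seq(0, 2 * pi, length.out = 80))
  tm <- matrix(rep(base, each = 10), 10, 80)
  tsR <- dmeanClassify(mkTset(tm))
  tsE <- dmeanClassify(mkTset(tm))
  m <- structure(list(pairs = cbind(ref = 1:10, exp = 1:10)),
                 class = "MatchedBeats")
  sc <- scoreRecording(tsR, tsE, m)
  expect_equal(sc$pccMean, 1)
  expect_equal(sc$nrmseMean, 0)
  expect_equal(sc$keptFraction, 100)
  expect_equal(sc$nScored, 10L)

  tsBad <- tsE
  tsBad@kept <- rep(FALSE, 10)
  expect_error(scoreRecording(tsR, tsBad, m), "empty score")
  tsUncls <- mkTset(tm)
  expect_error(scoreRecording(tsR, tsUncls, m), "classified")
})
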