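#' DMEAN outlier classification of beat templates
#'
#' Applies the mean-template distance rule: (1) compute the mean template
#' and each beat's sample-wise deviation from it; (2) pool the absolute
#' deviations and compute their mean and standard deviation; (3) flag any
#' sample whose absolute deviation exceeds `mean + 0.5 * SD`.  Each
#' beat's true-positive percentage is the share of its samples left
#' unflagged, and the beat is kept iff that percentage exceeds
#' `tpThreshold` (default 70%).
#'
#' @param tset A [BeatTemplateSet-class] with at least 3 beats.
#' @param tpThreshold Keep threshold in percent.
#' @return The input set with `tpPercent` and `kept` filled in.
#' @seealso [applyBeatLabels()] to push the decisions back onto a
#'   [BeatSeries-class].
#' @export
dmeanClassify <- function(tset, tpThreshold = 70) {
  stopifnot(is(tset, "BeatTemplateSet"))
  tm <- tset@templates
  if (nrow(tm) < 3L)
    stop("insufficient data: DMEAN needs >= 3 templates", call. = FALSE)
  mu <- colMeans(tm)
  D <- abs(sweep(tm, 2, mu))
  muD <- mean(D)
  sigmaD <- stats::sd(as.vector(D))
  flagged <- D > muD + 0.5 * sigmaD
  tp <- 100 * rowMeans(!flagged)
  tset@tpPercent <- tp
  tset@kept <- tp > tpThreshold
  tset
}

#' Write DMEAN decisions back to a beat series
#'
#' Beats whose template was rejected by [dmeanClassify()] (and beats
#' whose template was dropped at the record edges) are labeled
#' `"outlier"`; the rest keep their label.
#'
#' @param series The [BeatSeries-class] the templates came from.
#' @param tset A classified [BeatTemplateSet-class].
#' @return The relabeled [BeatSeries-class].
#' @export
applyBeatLabels <- function(series, tset) {
  stopifnot(is(series, "BeatSeries"), is(tset, "BeatTemplateSet"))
  if (!length(tset@kept))
    stop("template set has not been DMEAN-classified", call. = FALSE)
  lab <- beatLabels(series)
  lab[tset@dropped] <- "outlier"
  lab[tset@beatIndex[!tset@kept]] <- "outlier"
  beatLabels(series) <- lab
  series
}

#' Pearson correlation between two waveforms
#'
#' @param x,y Equal-length numeric waveforms (length >= 2), both
#'   non-constant.
#' @return The correlation coefficient in `[-1, 1]`.
#' @export
pcc <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("waveforms must have equal length >= 2", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant waveform", call. = FALSE)
  stats::cor(x, y)
}

#' Range-normalized root-mean-square error
#'
#' `100 * RMSE(ref, exp) / (max(ref) - min(ref))`, i.e. the RMS deviation
#' expressed as a percentage of the reference waveform's peak-to-peak
#' range.
#'
#' @param ref Reference waveform (non-constant).
#' @param exp Experimental waveform, same length.
#' @return NRMSE in percent (>= 0).
#' @export
nrmse <- function(ref, exp) {
  if (length(ref) != length(exp) || length(ref) < 2L)
    stop("waveforms must have equal length >= 2", call. = FALSE)
  rng <- max(ref) - min(ref)
  if (rng == 0)
    stop("undefined normalization: flat reference waveform", call. = FALSE)
  100 * sqrt(mean((ref - exp)^2)) / rng
}

#' Morphology scores over matched, kept beats
#'
#' For every matched beat pair whose templates exist on both devices and
#' survived DMEAN classification on both, computes the Pearson
#' correlation and range-normalized RMSE of the experimental template
#' against the reference template, and summarizes them as mean +/- SD.
#'
#' @param refT,expT DMEAN-classified [BeatTemplateSet-class] objects for
#'   the reference and experimental channels.
#' @param matches A `"MatchedBeats"` result from [matchRPeaks()] linking
#'   the two originating beat series.
#' @return A list of class `"MorphologyScores"`: `perBeat` (data.frame
#'   of `pcc`, `nrmse` per scored pair), `pccMean`, `pccSd`, `nrmseMean`,
#'   `nrmseSd`, `keptFraction` (% of experimental templates kept) and
#'   `nScored`.
#' @export
scoreRecording <- function(refT, expT, matches) {
  stopifnot(is(refT, "BeatTemplateSet"), is(expT, "BeatTemplateSet"),
            inherits(matches, "MatchedBeats"))
  if (!length(refT@kept) || !length(expT@kept))
    stop("both template sets must be DMEAN-classified first",
         call. = FALSE)
  rowR <- match(matches$pairs[, "ref"], refT@beatIndex)
  rowE <- match(matches$pairs[, "exp"], expT@beatIndex)
  ok <- !is.na(rowR) & !is.na(rowE)
  ok[ok] <- refT@kept[rowR[ok]] & expT@kept[rowE[ok]]
  if (!any(ok))
    stop("empty score: no matched pair with both templates kept",
         call. = FALSE)
  rowR <- rowR[ok]; rowE <- rowE[ok]
  scores <- vapply(seq_along(rowR), function(k) {
    r <- refT@templates[rowR[k], ]
    e <- expT@templates[rowE[k], ]
    c(pcc(r, e), nrmse(r, e))
  }, numeric(2))
  perBeat <- data.frame(pcc = scores[1, ], nrmse = scores[2, ])
  structure(list(
    perBeat = perBeat,
    pccMean = mean(perBeat$pcc), pccSd = stats::sd(perBeat$pcc),
    nrmseMean = mean(perBeat$nrmse), nrmseSd = stats::sd(perBeat$nrmse),
    keptFraction = 100 * mean(expT@kept),
    nScored = nrow(perBeat)), class = "MorphologyScores")
}
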