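# Run code with a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Centered moving average with edge shrinkage (partial windows at the ends
# average over the available samples only).
movingAverage <- function(x, width) {
  width <- max(1L, as.integer(width))
  n <- length(x)
  if (n == 0L) return(numeric())
  cs <- cumsum(c(0, x))
  half <- width %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (width - half - 1L), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Causal (trailing) moving average, window w samples.
movingAverageCausal <- function(x, width) {
  width <- max(1L, as.integer(width))
  n <- length(x)
  if (n == 0L) return(numeric())
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - width + 1L, 1L)
  (cs[seq_len(n) + 1L] - cs[lo]) / (seq_len(n) - lo + 1L)
}

.assertScalar <- function(x, name, positive = TRUE) {
  if (length(x) != 1L || !is.finite(x) || (positive && x <= 0))
    stop("'", name, "' must be a single ",
         if (positive) "positive " else "finite ", "number", call. = FALSE)
  invisible(x)
}
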