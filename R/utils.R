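# Shared numeric helpers used across the feature battery and analyses.

#' Count sign changes of a series about its mean
#'
#' The zero-cross statistic used throughout the feature battery: the number
#' of sign changes of `x - mean(x)`. Samples exactly at the mean carry the
#' sign of the preceding sample so a touch without a crossing is not counted.
#'
#' @param x Numeric vector.
#' @param center Value to cross; defaults to `mean(x)`.
#' @return Integer count of crossings.
#' @export
zero_cross <- function(x, center = mean(x)) {
  s <- sign(x - center)
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(diff(s) != 0L)
}

#' Mode of a continuous sample
#'
#' Most frequent value after rounding to `digits` decimals (the sample mode
#' is ill-defined for continuous data otherwise). Ties resolve to the
#' smallest value.
#'
#' @param x Numeric vector.
#' @param digits Decimals to round to before tabulating.
#' @return Numeric scalar.
#' @export
mode_stat <- function(x, digits = 2L) {
  r <- rle(sort.int(round(x, digits)))
  r$values[which.max(r$lengths)]
}

# Type-7 quantile from an already-sorted vector (avoids quantile()'s
# overhead in the per-window hot path).
sorted_quantile <- function(xs, p) {
  n <- length(xs)
  if (n == 1L) return(rep(xs, length(p)))
  h <- (n - 1) * p + 1
  lo <- floor(h)
  xs[lo] + (h - lo) * (xs[pmin(n, lo + 1L)] - xs[lo])
}

# Excess-free sample skewness and kurtosis (population-moment form).
skewness_stat <- function(x) {
  n <- length(x)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) return(0)
  mean((x - m)^3) / s2^1.5
}

kurtosis_stat <- function(x) {
  n <- length(x)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) return(0)
  mean((x - m)^4) / s2^2 - 3
}

rms_stat <- function(x) sqrt(mean(x^2))

# Basic statistical block shared by the temperature and RR batteries.
stat_block <- function(x, include_max = FALSE) {
  xs <- sort.int(x, method = "quick")
  n <- length(xs)
  q <- sorted_quantile(xs, c(0.25, 0.5, 0.75))
  rl <- rle(round(xs, 2))
  out <- c(
    mean = mean(x),
    median = q[2],
    mode = rl$values[which.max(rl$lengths)],
    min = xs[1],
    range = xs[n] - xs[1],
    rms = rms_stat(x),
    zero_cross = as.numeric(zero_cross(x)),
    kurtosis = kurtosis_stat(x),
    skew = skewness_stat(x),
    q25 = q[1],
    q75 = q[3]
  )
  if (include_max) out <- c(out, max = xs[n])
  out
}

# Missing-feature marker: a named NA vector with the given names.
na_features <- function(nms) setNames(rep(NA_real_, length(nms)), nms)

#' Empirical distribution table on the composite-score support
#'
#' @param x Numeric sample.
#' @param support Evaluation grid (defaults to the 13-91 composite support).
#' @return Tibble with `score` and `cdf` columns.
#' @export
ecdf_table <- function(x, support = seq(13, 91, by = 0.5)) {
  f <- ecdf(x)
  tibble::tibble(score = support, cdf = f(support))
}

# Count modes of a Gaussian kernel density (Silverman bandwidth by
# default); descriptor for bimodality of the nonresponse affect
# distribution. A local maximum only counts as a mode when its
# topographic prominence (height above the highest saddle separating it
# from a higher peak) reaches `rel_prominence` of the global maximum —
# a raw local-maximum count is dominated by sampling ripples.
density_mode_count <- function(x, bw = "nrd0", n = 512, rel_prominence = 0.1) {
  d <- density(x, bw = bw, n = n)
  y <- d$y
  peaks <- which(diff(sign(diff(y))) == -2L) + 1L
  if (length(peaks) <= 1L) return(length(peaks))
  ord <- peaks[order(y[peaks], decreasing = TRUE)]
  count <- 1L  # the global maximum is always a mode
  for (p in ord[-1]) {
    higher <- ord[y[ord] > y[p]]
    # highest saddle on the valley between p and the nearest higher peak
    saddle <- max(vapply(higher, function(q) {
      min(y[seq(min(p, q), max(p, q))])
    }, numeric(1)))
    if (y[p] - saddle >= rel_prominence * max(y)) count <- count + 1L
  }
  count
}

# Seed helper: derive a distinct 32-bit sub-seed from a base seed.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + 104729 * as.double(k)) %% 2147483647)
}
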