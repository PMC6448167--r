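# Paired two-sided Wilcoxon signed-rank test with an exact null for small
# samples, and the spider-graph polygon area summarizing mean index values.

#' Paired two-sided Wilcoxon signed-rank test
#'
#' Zero differences are dropped; ties among the absolute differences are
#' mid-ranked. For n <= `exact_max` nonzero pairs the p-value is computed
#' from the exact permutation null of the positive-rank sum (all 2^n sign
#' assignments, evaluated by generating-function convolution over the
#' doubled ranks so mid-ranks stay integral); above that a normal
#' approximation with continuity correction and tie-corrected variance is
#' used.
#'
#' @param a,b equal-length paired samples.
#' @param exact_max largest n for which the exact null is enumerated
#'   (default 25).
#' @return List with `p_value`, `statistic` (positive-rank sum W+), `n`
#'   (nonzero pairs) and `method`.
#' @export
wilcoxon_paired <- function(a, b, exact_max = 25) {
  if (length(a) != length(b))
    stop("parameter error: samples must have equal length", call. = FALSE)
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n < 5)
    stop("insufficient-data error: fewer than 5 nonzero pairs", call. = FALSE)
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  if (n <= exact_max) {
    # distribution of W+ over all sign assignments, on doubled ranks
    r2 <- as.integer(round(2 * r))
    tot <- sum(r2)
    cnt <- rep(0, tot + 1)  # cnt[s+1] = number of subsets with doubled sum s
    cnt[1] <- 1
    for (ri in r2) {
      shifted <- c(rep(0, ri), cnt[seq_len(tot + 1 - ri)])
      cnt <- cnt + shifted
    }
    probs <- cnt / 2^n
    w2 <- round(2 * w_pos)
    p_lo <- sum(probs[seq_len(w2 + 1)])
    p_hi <- sum(probs[(w2 + 1):(tot + 1)])
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (w_pos - mu - sign(w_pos - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(p_value = p, statistic = w_pos, n = n, method = method)
}

#' Spider-graph polygon area
#'
#' Places the k mean index values at distance `values[i]` along k equally
#' spaced axes and returns the shoelace area of the resulting polygon.
#' Smaller area indicates a more accurate registration. The conventional
#' axis order for the four distance indices is HD, DD, R, RM (values in mm,
#' no per-axis rescaling).
#'
#' @param values numeric vector of k >= 3 non-negative axis values.
#' @return Polygon area (squared axis units).
#' @export
spider_area <- function(values) {
  values <- as.numeric(values)
  k <- length(values)
  if (k < 3)
    stop("parameter error: need at least 3 axes", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0))
    stop("parameter error: axis values must be finite and >= 0", call. = FALSE)
  ang <- 2 * pi * (seq_len(k) - 1) / k
  x <- values * cos(ang); y <- values * sin(ang)
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}
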