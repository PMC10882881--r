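#' Coefficient of determination
#'
#' Fraction of the variance of the observed values explained by the
#' predictions: `1 - SSE/SStot`. Unlike a squared correlation it is sensitive
#' to the scale and offset of the predictions; it equals 1 for a perfect
#' predictor, 0 for the trivial predictor that always outputs the observed
#' mean, and can be arbitrarily negative for predictors worse than that.
#'
#' @param pairs a [continuous_pairs()] object.
#' @return a single numeric value in (-Inf, 1].
#' @examples
#' r_squared(continuous_pairs(c(3, 2, 1), c(1, 2, 3)))  # -3
#' @export
r_squared <- function(pairs) {
  .check_pairs(pairs, 2L)
  y <- pairs$observed
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    stop("observed values have zero variance; R^2 undefined", call. = FALSE)
  }
  1 - sum((pairs$predicted - y)^2) / ss_tot
}

#' Root mean square error
#'
#' @inheritParams r_squared
#' @return RMSE in the units of the observed values.
#' @export
rmse <- function(pairs) {
  .check_pairs(pairs, 1L)
  sqrt(mean((pairs$predicted - pairs$observed)^2))
}

#' Pearson correlation between predicted and observed values
#'
#' Scale-free measure of linear association; invariant to positive affine
#' transforms of either side.
#'
#' @inheritParams r_squared
#' @return correlation in [-1, 1].
#' @export
pearson <- function(pairs) {
  .check_pairs(pairs, 3L)
  if (stats::var(pairs$predicted) == 0 || stats::var(pairs$observed) == 0) {
    stop("zero variance on one side; Pearson correlation undefined",
         call. = FALSE)
  }
  stats::cor(pairs$predicted, pairs$observed, method = "pearson")
}

#' Spearman rank correlation
#'
#' Pearson correlation applied to mid-ranks (ties receive average ranks).
#'
#' @inheritParams r_squared
#' @return correlation in [-1, 1].
#' @export
spearman <- function(pairs) {
  .check_pairs(pairs, 3L)
  if (length(unique(pairs$predicted)) < 2L || length(unique(pairs$observed)) < 2L) {
    stop("all values tied on one side; Spearman correlation undefined",
         call. = FALSE)
  }
  stats::cor(pairs$predicted, pairs$observed, method = "spearman")
}

#' Kendall rank correlation with tie correction (tau-b)
#'
#' Sign-concordance statistic with the denominator corrected for tie groups
#' on both variables, so that it reaches +/-1 when one ordering determines
#' the other up to ties. Reduces to plain Kendall tau when there are no
#' ties. Computed in O(n log n) by merge-sort inversion counting with tie
#' bookkeeping, which keeps saturation-mutagenesis-sized inputs (tens of
#' thousands of variants) fast.
#'
#' @inheritParams r_squared
#' @return tau-b in [-1, 1].
#' @examples
#' kendall_tau_b(continuous_pairs(1:5, c(2, 4, 6, 8, 10)))  # 1
#' @export
kendall_tau_b <- function(pairs) {
  .check_pairs(pairs, 2L)
  .tau_b(pairs$predicted, pairs$observed)
}

.tau_b <- function(x, y) {
  n <- length(x)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    stop("all values tied on one side; tau-b undefined", call. = FALSE)
  }
  o <- order(x, y)
  x <- x[o]
  y <- y[o]
  half <- function(k) k * (k - 1) / 2
  n0 <- half(n)
  tx <- rle(x)$lengths
  n1 <- sum(half(as.numeric(tx)))
  ty <- rle(sort(y))$lengths
  n2 <- sum(half(as.numeric(ty)))
  joint_change <- c(TRUE, x[-1L] != x[-n] | y[-1L] != y[-n])
  txy <- diff(c(which(joint_change), n + 1L))
  n3 <- sum(half(as.numeric(txy)))
  s <- .count_inversions(y) # discordant pairs: x-groups are y-sorted internally
  (n0 - n1 - n2 + n3 - 2 * s) / sqrt((n0 - n1) * (n0 - n2))
}

# Number of strict inversions (v[i] > v[j], i < j) via bottom-up merge sort.
# Cross-run inversions are counted vectorized with findInterval, so the
# R-level loop is O(n) iterations total.
.count_inversions <- function(v) {
  n <- length(v)
  inv <- 0
  width <- 1L
  while (width < n) {
    starts <- seq.int(1L, n, by = 2L * width)
    for (st in starts) {
      mid <- st + width - 1L
      if (mid >= n) next
      en <- min(st + 2L * width - 1L, n)
      a <- v[st:mid]
      b <- v[(mid + 1L):en]
      inv <- inv + sum(length(a) - as.numeric(findInterval(b, a)))
      v[st:en] <- sort(c(a, b), method = "radix")
    }
    width <- 2L * width
  }
  inv
}

#' Full continuous-target metric suite
#'
#' @inheritParams r_squared
#' @return named list with elements `r2`, `rmse`, `pearson`, `spearman`,
#'   `kendall_tau_b`.
#' @export
continuous_metrics <- function(pairs) {
  list(
    r2 = r_squared(pairs),
    rmse = rmse(pairs),
    pearson = pearson(pairs),
    spearman = spearman(pairs),
    kendall_tau_b = kendall_tau_b(pairs)
  )
}
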