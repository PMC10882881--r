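#' Bootstrap confidence interval for a metric
#'
#' Case resampling with replacement (n out of n), percentile interval.
#' Resampling and the interval follow the plain (non-stratified) bootstrap
#' by default; `stratified = TRUE` resamples within label classes, which is
#' useful for severely imbalanced binary data. Binary resamples that lose a
#' class are redrawn (up to `max_redraws` per iteration) and counted; if the
#' degenerate draws outnumber half of all draws the run aborts with advice
#' to use stratified mode. Results are deterministic given `seed` (the RNG
#' is pinned to Mersenne-Twister with inversion normals and the caller's RNG
#' state is restored).
#'
#' @param data a [labeled_scores()] or [continuous_pairs()] object.
#' @param metric a function mapping `data` to a single numeric value, e.g.
#'   [auc()] or [kendall_tau_b()].
#' @param iterations bootstrap iteration count (the package default
#'   configuration uses 1000).
#' @param level confidence level.
#' @param seed integer seed.
#' @param stratified resample within label classes (binary data only).
#' @param type `"percentile"` (default) or `"bca"` (bias-corrected and
#'   accelerated, with jackknife acceleration; costs n extra metric
#'   evaluations).
#' @param max_redraws redraw cap per iteration for degenerate resamples.
#' @return list of class `bootstrap_result`: `point`, `ci_low`, `ci_high`,
#'   `level`, `iterations`, `seed`, `n_degenerate_redrawn`, `replicates`.
#' @examples
#' d <- generate_binary(binormal_spec(n = 300, seed = 3))
#' bootstrap_metric(d, auc, iterations = 200, seed = 1)
#' @export
bootstrap_metric <- function(data, metric, iterations = 1000, level = 0.95,
                             seed = 1L, stratified = FALSE,
                             type = c("percentile", "bca"),
                             max_redraws = 100L) {
  type <- match.arg(type)
  stopifnot(iterations >= 1, level > 0, level < 1)
  if (!inherits(data, "labeled_scores") && !inherits(data, "continuous_pairs")) {
    stop("`data` must be labeled_scores or continuous_pairs", call. = FALSE)
  }
  point <- metric(data)
  n <- nrow(data)
  binary <- inherits(data, "labeled_scores")
  idx_pos <- if (binary) which(data$label == 1) else integer()
  idx_neg <- if (binary) which(data$label == 0) else integer()
  vals <- numeric(iterations)
  degen <- 0L
  with_seed(seed, {
    for (b in seq_len(iterations)) {
      idx <- NULL
      for (try in seq_len(max_redraws)) {
        cand <- if (stratified && binary) {
          c(sample(idx_pos, replace = TRUE), sample(idx_neg, replace = TRUE))
        } else {
          sample.int(n, replace = TRUE)
        }
        if (!binary || (any(data$label[cand] == 1) && any(data$label[cand] == 0))) {
          idx <- cand
          break
        }
        degen <- degen + 1L
      }
      if (is.null(idx)) {
        stop("resampling kept losing a label class; use stratified = TRUE",
             call. = FALSE)
      }
      vals[b] <- metric(data[idx, , drop = FALSE])
    }
  })
  if (degen > 0.5 * (iterations + degen)) {
    stop("more than half of bootstrap draws lacked a label class; ",
         "use stratified = TRUE", call. = FALSE)
  }
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  if (type == "bca") {
    probs <- .bca_probs(data, metric, point, vals, probs, binary)
  }
  qs <- stats::quantile(vals, probs, names = FALSE)
  structure(
    list(point = point, ci_low = qs[1L], ci_high = qs[2L], level = level,
         type = type, iterations = iterations, seed = as.integer(seed),
         n_degenerate_redrawn = degen, replicates = vals),
    class = "bootstrap_result"
  )
}

# BCa adjustment: bias correction from the replicate distribution, jackknife
# acceleration. Falls back to the raw percentiles for degenerate cases
# (constant replicates or undefined jackknife values).
.bca_probs <- function(data, metric, point, vals, probs, binary) {
  frac <- (sum(vals < point) + 0.5 * sum(vals == point)) / length(vals)
  if (frac <= 0 || frac >= 1) return(probs)
  z0 <- stats::qnorm(frac)
  n <- nrow(data)
  jack <- vapply(seq_len(n), function(i) {
    d <- data[-i, , drop = FALSE]
    if (binary && (!any(d$label == 1) || !any(d$label == 0))) return(NA_real_)
    metric(d)
  }, 0)
  jack <- jack[!is.na(jack)]
  dev <- mean(jack) - jack
  denom <- 6 * sum(dev^2)^1.5
  a <- if (denom > 0) sum(dev^3) / denom else 0
  z <- stats::qnorm(probs)
  adj <- stats::pnorm(z0 + (z0 + z) / (1 - a * (z0 + z)))
  if (any(!is.finite(adj))) probs else adj
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> point = %.6g, %g%% CI [%.6g, %.6g] (%d iterations)\n",
              x$point, 100 * x$level, x$ci_low, x$ci_high, x$iterations))
  if (x$n_degenerate_redrawn > 0) {
    cat(sprintf("  %d degenerate resamples redrawn\n", x$n_degenerate_redrawn))
  }
  invisible(x)
}

#' Permutation p-value against a random-score null
#'
#' Breaks the score-label (binary) or predicted-observed (continuous)
#' pairing by permutation, which realizes the "random model" nulls AUC =
#' 0.5, r = 0, tau = 0. One-sided:
#' `p = (1 + #\{null >= observed\}) / (iterations + 1)`.
#'
#' @inheritParams bootstrap_metric
#' @param null currently only `"random_scores"` (label / observed-value
#'   permutation).
#' @return list of class `permutation_test`: `p_value`, `observed`,
#'   `iterations`, `seed`, `null_values`.
#' @export
null_pvalue <- function(data, metric, null = "random_scores",
                        iterations = 1000, seed = 1L) {
  null <- match.arg(null)
  stopifnot(iterations >= 1)
  if (!inherits(data, "labeled_scores") && !inherits(data, "continuous_pairs")) {
    stop("`data` must be labeled_scores or continuous_pairs", call. = FALSE)
  }
  observed <- metric(data)
  n <- nrow(data)
  binary <- inherits(data, "labeled_scores")
  vals <- with_seed(seed, vapply(seq_len(iterations), function(b) {
    d <- data
    if (binary) {
      d$label <- d$label[sample.int(n)]
    } else {
      d$observed <- d$observed[sample.int(n)]
    }
    metric(d)
  }, 0))
  structure(
    list(p_value = (1 + sum(vals >= observed)) / (iterations + 1),
         observed = observed, iterations = iterations,
         seed = as.integer(seed), null_values = vals),
    class = "permutation_test"
  )
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("<permutation_test> observed = %.6g, p = %.4g (%d permutations)\n",
              x$observed, x$p_value, x$iterations))
  invisible(x)
}
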