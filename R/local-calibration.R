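#' Local posterior and local positive likelihood ratio by score windowing
#'
#' Estimates, at each evaluation score s, the posterior probability of
#' pathogenicity under the test-set prior as the fraction of positive items
#' inside the score window `[s - eps, s + eps]`, where
#' `eps = window_fraction * (P95 - P5)` of the score distribution (a robust
#' range that limits the influence of outliers). When a window holds fewer
#' than `min(ceiling(window_min_fraction * n), window_max_count)` items it is
#' grown outward by nearest neighbors in absolute score distance — one whole
#' tie group at a time, with distance ties resolved toward the lower score,
#' so the window is always a closed score interval — until the count rule is
#' met; the effective window width thus adapts to the local score density. The local
#' positive likelihood ratio lr+(s) — the ratio of the class-conditional
#' score densities, equivalently the slope of the ROC curve at s — is then
#' recovered from the windowed posterior by dividing posterior odds by the
#' test-set prior odds. lr+ does not depend on the class prior, which is what
#' makes it transferable to other populations (see [posterior_at_score()]).
#'
#' @param scores a [labeled_scores()] object with both classes, n >= 10.
#' @param grid evaluation scores; defaults to the sorted distinct observed
#'   scores (so that evidence thresholds land on observed scores). Pass
#'   `grid = "uniform"` for an equally spaced grid of `grid_length` points
#'   spanning the observed range.
#' @param config an [analysis_config()]; supplies the window constants and
#'   the optional test-prior override.
#' @param grid_length length of the uniform grid when `grid = "uniform"`.
#' @return data frame of class `local_calibration_curve` with columns
#'   `score`, `posterior_test`, `lr_plus`, `window_halfwidth`,
#'   `window_count`, and attributes `alpha_test`, `epsilon`, `flipped`.
#' @examples
#' d <- generate_binary(binormal_spec(n = 2000, seed = 7))
#' head(local_posterior(d))
#' @export
local_posterior <- function(scores, grid = NULL, config = analysis_config(),
                            grid_length = 200L) {
  .check_both_classes(scores)
  n <- nrow(scores)
  if (n < 10L) stop("need at least 10 items", call. = FALSE)
  o <- order(scores$score)
  ss <- scores$score[o]
  ys <- scores$label[o]
  q <- stats::quantile(ss, c(0.05, 0.95), names = FALSE)
  eps <- config$window_fraction * (q[2L] - q[1L])
  k <- min(ceiling(config$window_min_fraction * n), config$window_max_count)
  if (k > n) {
    stop("window count rule requires ", k, " items but only ", n,
         " are available", call. = FALSE)
  }
  if (is.null(grid)) {
    grid <- unique(ss)
  } else if (identical(grid, "uniform")) {
    grid <- seq(ss[1L], ss[n], length.out = grid_length)
  } else {
    grid <- sort(as.numeric(grid))
  }
  lo <- findInterval(grid - eps, ss, left.open = TRUE) + 1L # first idx >= s-eps
  hi <- findInterval(grid + eps, ss)                        # last idx <= s+eps
  need <- which(hi - lo + 1L < k)
  for (g in need) {
    l <- lo[g]
    h <- hi[g]
    sg <- grid[g]
    while (h - l + 1L < k) {
      dl <- if (l > 1L) sg - ss[l - 1L] else Inf
      dr <- if (h < n) ss[h + 1L] - sg else Inf
      # add the nearest whole tie group so the window stays a score
      # interval; distance ties resolve toward the lower score
      if (dl <= dr) {
        v <- ss[l - 1L]
        while (l > 1L && ss[l - 1L] == v) l <- l - 1L
      } else {
        v <- ss[h + 1L]
        while (h < n && ss[h + 1L] == v) h <- h + 1L
      }
    }
    lo[g] <- l
    hi[g] <- h
  }
  cnt <- hi - lo + 1L
  cy <- c(0, cumsum(ys))
  p <- (cy[hi + 1L] - cy[lo]) / cnt
  halfw <- pmax(eps, grid - ss[lo], ss[hi] - grid)
  alpha_test <- config$test_prior %||% mean(scores$label)
  structure(
    data.frame(score = grid, posterior_test = p,
               lr_plus = .lr_from_posterior(p, alpha_test),
               window_halfwidth = halfw, window_count = cnt),
    class = c("local_calibration_curve", "data.frame"),
    alpha_test = alpha_test, epsilon = eps,
    flipped = isTRUE(attr(scores, "flipped"))
  )
}

# Posterior odds divided by prior odds; posterior 1 maps to +Inf.
.lr_from_posterior <- function(p, alpha) {
  ifelse(p >= 1, Inf, (p / (1 - p)) * ((1 - alpha) / alpha))
}

#' Local positive likelihood ratio from a windowed posterior
#'
#' Converts windowed test-set posteriors to lr+ values by dividing posterior
#' odds by the test-set prior odds. A posterior of exactly 1 maps to +Inf;
#' the `"infinite"` attribute flags those grid points.
#'
#' @param curve a [local_posterior()] curve, or a numeric vector of
#'   posteriors.
#' @param test_prior the test-set class prior in (0,1); defaults to the
#'   curve's `alpha_test` attribute.
#' @return numeric vector of lr+ values aligned with the curve grid.
#' @examples
#' local_lr_plus(0.5, test_prior = 0.2)  # 4
#' @export
local_lr_plus <- function(curve, test_prior = NULL) {
  p <- if (inherits(curve, "local_calibration_curve")) {
    curve$posterior_test
  } else {
    as.numeric(curve)
  }
  test_prior <- test_prior %||% attr(curve, "alpha_test")
  if (is.null(test_prior) || test_prior <= 0 || test_prior >= 1) {
    stop("`test_prior` must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (any(p < 0 | p > 1)) stop("posteriors must lie in [0, 1]", call. = FALSE)
  out <- .lr_from_posterior(p, test_prior)
  if (any(!is.finite(out))) attr(out, "infinite") <- which(!is.finite(out))
  out
}

#' Bootstrap lower confidence bound on the local lr+ curve
#'
#' A more stringent basis for evidence thresholds: items are case-resampled,
#' the windowed posterior is recomputed on a fixed grid each time, and the
#' pointwise lower quantile of the lr+ replicates replaces the point
#' estimate. Passing the result to [evidence_thresholds()] requires the
#' lower confidence bound — not just the estimate — to sustain each level's
#' requirement. Off by default throughout the package; opt in explicitly.
#'
#' @inheritParams local_posterior
#' @param iterations bootstrap iteration count.
#' @param seed integer seed.
#' @param probs lower-tail probability for the bound (default 0.05).
#' @return a `local_calibration_curve` on the fixed grid whose
#'   `posterior_test` and `lr_plus` are the pointwise lower bounds; the
#'   point-estimate curve is kept in the `"raw"` attribute.
#' @export
curve_lower_bound <- function(scores, grid = NULL, config = analysis_config(),
                              iterations = 200, seed = 1L, probs = 0.05) {
  .check_both_classes(scores)
  stopifnot(probs > 0, probs < 1, iterations >= 1)
  point <- local_posterior(scores, grid = grid, config = config)
  fixed_grid <- point$score
  n <- nrow(scores)
  reps <- with_seed(seed, vapply(seq_len(iterations), function(b) {
    repeat {
      idx <- sample.int(n, replace = TRUE)
      if (any(scores$label[idx] == 1) && any(scores$label[idx] == 0)) break
    }
    d <- labeled_scores(scores$score[idx], scores$label[idx])
    local_posterior(d, grid = fixed_grid, config = config)$posterior_test
  }, numeric(length(fixed_grid))))
  p_low <- apply(matrix(reps, nrow = length(fixed_grid)), 1, stats::quantile,
                 probs = probs, names = FALSE)
  out <- point
  out$posterior_test <- p_low
  out$lr_plus <- .lr_from_posterior(p_low, attr(point, "alpha_test"))
  attr(out, "raw") <- point
  attr(out, "bound") <- probs
  out
}

#' Smooth a local calibration curve for display
#'
#' `"isotonic"` enforces a monotone non-decreasing posterior (hence lr+) in
#' score via pool-adjacent-violators ([stats::isoreg()]); appropriate when
#' the predictor is believed to rank correctly and the wiggle is estimation
#' noise. `"moving_average"` applies a centered running mean to the
#' posterior. In both cases lr+ is recomputed from the smoothed posterior so
#' the pointwise posterior/lr+ relation is preserved, and the unsmoothed
#' curve is kept in the `"raw"` attribute.
#'
#' @param curve a [local_posterior()] curve.
#' @param method `"none"`, `"isotonic"`, or `"moving_average"`.
#' @param window odd window length for the moving average.
#' @return a `local_calibration_curve` with smoothed `posterior_test` and
#'   `lr_plus`.
#' @export
smooth_curve <- function(curve, method = c("none", "isotonic", "moving_average"),
                         window = 5L) {
  stopifnot(inherits(curve, "local_calibration_curve"), nrow(curve) > 0L)
  method <- match.arg(method)
  if (method == "none") return(curve)
  p <- curve$posterior_test
  if (method == "isotonic") {
    p_sm <- stats::isoreg(curve$score, p)$yf
  } else {
    stopifnot(window >= 1L)
    m <- length(p)
    half <- (as.integer(window) - 1L) %/% 2L
    p_sm <- vapply(seq_len(m), function(i) {
      mean(p[max(1L, i - half):min(m, i + half)])
    }, 0)
  }
  out <- curve
  out$posterior_test <- p_sm
  out$lr_plus <- .lr_from_posterior(p_sm, attr(curve, "alpha_test"))
  attr(out, "raw") <- curve
  attr(out, "smoothing") <- method
  out
}

#' @export
print.local_calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<local_calibration_curve> %d grid points, alpha_test=%.4f, epsilon=%.4g\n",
    nrow(x), attr(x, "alpha_test"), attr(x, "epsilon")))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("  ...\n")
  invisible(x)
}

#' Write a local calibration curve to a TSV file
#'
#' Columns `score`, `posterior_test`, `lr_plus`, `window_count`.
#'
#' @param curve a [local_posterior()] curve.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "local_calibration_curve"))
  cols <- c("score", "posterior_test", "lr_plus", "window_count")
  utils::write.table(as.data.frame(curve)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
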