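#' Binormal score-set specification
#'
#' Class-conditional Gaussian score model: benign (label 0) scores are
#' N(mu0, sigma0^2), pathogenic (label 1) scores are N(mu1, sigma1^2),
#' labels are Bernoulli(alpha). Closed forms:
#' `AUC = pnorm((mu1 - mu0) / sqrt(sigma0^2 + sigma1^2))` and
#' `lr+(s) = dnorm(s, mu1, sigma1) / dnorm(s, mu0, sigma0)` (log-linear in s
#' when the sigmas are equal). The defaults (unit separation, equal unit
#' sigmas, balanced classes) give AUC of about 0.76, typical of a moderately
#' informative predictor on a balanced benchmark set.
#'
#' @param mu0,sigma0 negative-class score mean and standard deviation.
#' @param mu1,sigma1 positive-class score mean and standard deviation.
#' @param alpha class prior in (0,1).
#' @param n sample size.
#' @param seed integer seed.
#' @return list of class `binormal_spec`.
#' @export
binormal_spec <- function(mu0 = 0, sigma0 = 1, mu1 = 1, sigma1 = 1,
                          alpha = 0.5, n = 1000L, seed = 1L) {
  stopifnot(sigma0 > 0, sigma1 > 0, alpha > 0, alpha < 1, n >= 1)
  structure(
    list(mu0 = mu0, sigma0 = sigma0, mu1 = mu1, sigma1 = sigma1,
         alpha = alpha, n = as.integer(n), seed = as.integer(seed)),
    class = "binormal_spec"
  )
}

#' Generate a labeled score set from a binormal specification
#'
#' @param spec a [binormal_spec()].
#' @return [labeled_scores()] with a `"truth"` attribute: the spec
#'   parameters plus `auc` (closed form), `lr_fun(s)`, and
#'   `posterior_fun(s, alpha)`.
#' @examples
#' d <- generate_binary(binormal_spec(n = 500, seed = 42))
#' attr(d, "truth")$auc
#' @export
generate_binary <- function(spec) {
  stopifnot(inherits(spec, "binormal_spec"))
  dat <- with_seed(spec$seed, {
    y <- stats::rbinom(spec$n, 1L, spec$alpha)
    s <- ifelse(y == 1L,
                stats::rnorm(spec$n, spec$mu1, spec$sigma1),
                stats::rnorm(spec$n, spec$mu0, spec$sigma0))
    list(s = s, y = y)
  })
  out <- labeled_scores(dat$s, dat$y)
  lr_fun <- function(s) {
    stats::dnorm(s, spec$mu1, spec$sigma1) / stats::dnorm(s, spec$mu0, spec$sigma0)
  }
  attr(out, "truth") <- list(
    spec = spec,
    auc = stats::pnorm((spec$mu1 - spec$mu0) /
                         sqrt(spec$sigma0^2 + spec$sigma1^2)),
    lr_fun = lr_fun,
    posterior_fun = function(s, alpha = spec$alpha) {
      posterior_from_lr(lr_fun(s), alpha)
    }
  )
  out
}

#' Generate a bounded-score set from a beta-mixture model
#'
#' For predictors with outputs confined to [0, 1] (probability-like scores):
#' benign scores are Beta(shape0[1], shape0[2]), pathogenic scores
#' Beta(shape1[1], shape1[2]). The truth record carries the closed-form
#' density-ratio `lr_fun`.
#'
#' @param n sample size.
#' @param alpha class prior in (0,1).
#' @param shape0,shape1 length-2 beta shape parameters for the negative and
#'   positive class.
#' @param seed integer seed.
#' @return [labeled_scores()] with a `"truth"` attribute.
#' @export
generate_binary_beta <- function(n = 1000L, alpha = 0.5,
                                 shape0 = c(2, 5), shape1 = c(5, 2),
                                 seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, all(shape0 > 0), all(shape1 > 0))
  dat <- with_seed(seed, {
    y <- stats::rbinom(n, 1L, alpha)
    s <- ifelse(y == 1L,
                stats::rbeta(n, shape1[1L], shape1[2L]),
                stats::rbeta(n, shape0[1L], shape0[2L]))
    list(s = s, y = y)
  })
  out <- labeled_scores(dat$s, dat$y)
  lr_fun <- function(s) {
    stats::dbeta(s, shape1[1L], shape1[2L]) / stats::dbeta(s, shape0[1L], shape0[2L])
  }
  attr(out, "truth") <- list(
    alpha = alpha, shape0 = shape0, shape1 = shape1,
    lr_fun = lr_fun,
    posterior_fun = function(s, a = alpha) posterior_from_lr(lr_fun(s), a)
  )
  out
}

#' Bivariate-normal specification for continuous pairs
#'
#' Predicted and observed values are standard bivariate normal with Pearson
#' correlation `rho`; closed forms: Pearson correlation -> rho, Kendall tau
#' -> `(2/pi) * asin(rho)`. An optional strictly increasing transform can be
#' applied to the predicted margin to exercise rank-invariance (it leaves
#' Spearman and tau unchanged while breaking the linear relation).
#'
#' @param rho Pearson correlation in (-1, 1).
#' @param n sample size.
#' @param transform `"identity"`, `"exp"`, or `"cube"` applied to the
#'   predicted margin.
#' @param seed integer seed.
#' @return list of class `bivariate_spec`.
#' @export
bivariate_spec <- function(rho = 0.5, n = 1000L,
                           transform = c("identity", "exp", "cube"),
                           seed = 1L) {
  stopifnot(rho > -1, rho < 1, n >= 2)
  structure(
    list(rho = rho, n = as.integer(n), transform = match.arg(transform),
         seed = as.integer(seed)),
    class = "bivariate_spec"
  )
}

#' Generate predicted/observed pairs from a bivariate specification
#'
#' @param spec a [bivariate_spec()].
#' @return [continuous_pairs()] with a `"truth"` attribute holding the spec
#'   plus the closed-form `pearson` (of the untransformed margins) and
#'   `kendall_tau`.
#' @export
generate_continuous <- function(spec) {
  stopifnot(inherits(spec, "bivariate_spec"))
  dat <- with_seed(spec$seed, {
    z1 <- stats::rnorm(spec$n)
    z2 <- stats::rnorm(spec$n)
    x <- z1
    y <- spec$rho * z1 + sqrt(1 - spec$rho^2) * z2
    list(x = x, y = y)
  })
  x <- switch(spec$transform,
              identity = dat$x,
              exp = exp(dat$x),
              cube = dat$x^3)
  out <- continuous_pairs(predicted = x, observed = dat$y)
  attr(out, "truth") <- list(
    spec = spec,
    pearson = spec$rho,
    kendall_tau = (2 / pi) * asin(spec$rho)
  )
  out
}

#' Quantize scores into tied bins
#'
#' Replaces values by the midpoints of `bins` equal-width bins spanning the
#' observed range, deliberately creating ties to exercise the tie
#' corrections in AUC and tau-b. Labels (or the other margin) are unchanged.
#'
#' @param base a [labeled_scores()] or [continuous_pairs()] object.
#' @param bins number of bins, >= 2.
#' @param which for `continuous_pairs`: which column(s) to quantize
#'   (`"predicted"`, `"observed"`, or `"both"`).
#' @return object of the same class with quantized values.
#' @export
generate_tied <- function(base, bins, which = c("predicted", "observed", "both")) {
  if (bins < 2) stop("`bins` must be at least 2", call. = FALSE)
  quantize <- function(v) {
    rng <- range(v)
    if (rng[1L] == rng[2L]) return(v)
    width <- diff(rng) / bins
    b <- pmin(floor((v - rng[1L]) / width), bins - 1)
    rng[1L] + (b + 0.5) * width
  }
  if (inherits(base, "labeled_scores")) {
    out <- base
    out$score <- quantize(base$score)
    return(out)
  }
  if (inherits(base, "continuous_pairs")) {
    which <- match.arg(which)
    out <- base
    if (which %in% c("predicted", "both")) out$predicted <- quantize(base$predicted)
    if (which %in% c("observed", "both")) out$observed <- quantize(base$observed)
    return(out)
  }
  stop("`base` must be labeled_scores or continuous_pairs", call. = FALSE)
}

#' Write a generated set with its analytic truth sidecar
#'
#' Writes the scores as the TSV dialect [read_scores()] reads, plus a JSON
#' sidecar (`<path>.truth.json`) with the generator parameters and
#' closed-form values.
#'
#' @param scores output of [generate_binary()] or [generate_binary_beta()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_synthetic <- function(scores, path) {
  write_scores(scores, path)
  truth <- attr(scores, "truth")
  keep <- Filter(function(x) !is.function(x), truth)
  if (!is.null(keep$spec)) keep$spec <- unclass(keep$spec)
  jsonlite::write_json(keep, paste0(path, ".truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
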