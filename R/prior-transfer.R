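#' Prior specification for transfer to a target population
#'
#' Class-conditional quantities (TPR, FPR, lr+) estimated on a test set
#' carry over unchanged to any population with the same class-conditional
#' score distributions; prior-dependent quantities (PPV, posterior, relative
#' risk, PPP) must be recomputed at the target prior. This object pairs the
#' two priors involved.
#'
#' @param alpha_target class prior of the target (reference) population.
#' @param alpha_test class prior of the test set; defaults to the observed
#'   positive fraction when a `labeled_scores` object is supplied.
#' @return list of class `prior_spec`.
#' @export
prior_spec <- function(alpha_target, alpha_test = NULL) {
  if (inherits(alpha_test, "labeled_scores")) {
    alpha_test <- mean(alpha_test$label)
  }
  stopifnot(alpha_target > 0, alpha_target < 1,
            is.null(alpha_test) || (alpha_test > 0 && alpha_test < 1))
  structure(list(alpha_target = alpha_target, alpha_test = alpha_test),
            class = "prior_spec")
}

.alpha_of <- function(prior) {
  if (inherits(prior, "prior_spec")) prior$alpha_target else as.numeric(prior)
}

#' Positive predictive value at a threshold, under a target prior
#'
#' `PPV(tau) = alpha * TPR / (alpha * TPR + (1 - alpha) * FPR)`.
#'
#' @param tpr,fpr empirical true/false positive rates at the threshold.
#' @param prior a [prior_spec()] or a plain target prior alpha in (0,1).
#' @return PPV in [0, 1].
#' @examples
#' ppv_at_threshold(0.6, 0.1, 0.1)  # 0.4
#' @export
ppv_at_threshold <- function(tpr, fpr, prior) {
  alpha <- .alpha_of(prior)
  stopifnot(alpha > 0, alpha < 1,
            all(tpr >= 0 & tpr <= 1), all(fpr >= 0 & fpr <= 1))
  den <- alpha * tpr + (1 - alpha) * fpr
  if (any(den == 0)) {
    stop("TPR and FPR both zero; PPV undefined", call. = FALSE)
  }
  alpha * tpr / den
}

#' Posterior probability of pathogenicity at a score, under a target prior
#'
#' `rho(s) = alpha * lr+(s) / (alpha * (lr+(s) - 1) + 1)`; the local
#' positive predictive value at the target prior.
#'
#' @param lr_plus local positive likelihood ratio(s), >= 0.
#' @inheritParams ppv_at_threshold
#' @return posterior in [0, 1], vectorized over `lr_plus`.
#' @export
posterior_at_score <- function(lr_plus, prior) {
  posterior_from_lr(lr_plus, .alpha_of(prior))
}

#' Relative risk at a score, under a target prior
#'
#' Posterior probability of pathogenicity relative to the population
#' average: `RR(s) = lr+(s) / (alpha * (lr+(s) - 1) + 1)`, equal to
#' `posterior_at_score(...) / alpha` exactly.
#'
#' @inheritParams posterior_at_score
#' @return relative risk >= 0, vectorized over `lr_plus`.
#' @examples
#' relative_risk(6, 0.013)  # about 5.63
#' @export
relative_risk <- function(lr_plus, prior) {
  alpha <- .alpha_of(prior)
  stopifnot(alpha > 0, alpha < 1)
  if (any(lr_plus < 0, na.rm = TRUE)) stop("`lr_plus` must be >= 0", call. = FALSE)
  ifelse(is.infinite(lr_plus), 1 / alpha,
         lr_plus / (alpha * (lr_plus - 1) + 1))
}

#' Per-score table of prior-corrected clinical quantities
#'
#' Applies the prior-shift corrections pointwise over the calibration grid:
#' posterior rho and relative risk from the grid lr+, and PPP / PPV from the
#' empirical TPR and FPR with each grid score taken as the threshold.
#'
#' @param curve a [local_posterior()] curve.
#' @param scores the [labeled_scores()] the curve was computed from.
#' @param prior a [prior_spec()] or target prior alpha.
#' @return data frame of class `prior_transfer` with columns `score`,
#'   `lr_plus`, `posterior`, `relative_risk`, `ppp`, `ppv`, and attribute
#'   `alpha_target`.
#' @export
transfer_report <- function(curve, scores, prior) {
  stopifnot(inherits(curve, "local_calibration_curve"))
  .check_both_classes(scores)
  alpha <- .alpha_of(prior)
  r <- .rates_at(scores, curve$score)
  den <- alpha * r$tpr + (1 - alpha) * r$fpr
  structure(
    data.frame(
      score = curve$score,
      lr_plus = curve$lr_plus,
      posterior = posterior_at_score(curve$lr_plus, alpha),
      relative_risk = relative_risk(curve$lr_plus, alpha),
      ppp = den,
      ppv = ifelse(den > 0, alpha * r$tpr / den, NaN)
    ),
    class = c("prior_transfer", "data.frame"),
    alpha_target = alpha
  )
}
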