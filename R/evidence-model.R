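#' Likelihood-ratio requirements per ACMG/AMP evidence level
#'
#' Under the exponential evidence-combination model, one line of Very Strong
#' evidence carries positive likelihood ratio c, and Strong, Moderate, and
#' Supporting lines carry the square, fourth, and eighth roots of c, so that
#' one Very Strong line equals two Strong, four Moderate, or eight
#' Supporting lines.
#'
#' @param c likelihood ratio of one Very Strong line; must exceed 1.
#' @return named numeric vector `supporting`, `moderate`, `strong`,
#'   `very_strong`, strictly increasing.
#' @examples
#' round(level_requirements(350), 2)  # 2.08, 4.32, 18.71, 350
#' @export
level_requirements <- function(c) {
  if (!is.numeric(c) || length(c) != 1L || c <= 1) {
    stop("`c` must be a single number greater than 1", call. = FALSE)
  }
  c(supporting = c^(1 / 8), moderate = c^(1 / 4),
    strong = c^(1 / 2), very_strong = c)
}

#' Evidence model: constant c, class prior, and per-level requirements
#'
#' The defaults c = 351 at a prior of 0.10 reflect the diagnostic setting of
#' one or a few candidate genes; for the screening setting use
#' `evidence_model(c = 8511, prior = 0.01)`.
#'
#' @inheritParams level_requirements
#' @param prior class prior of pathogenicity, in (0,1).
#' @return list of class `evidence_model` with fields `c`, `prior`,
#'   `requirements`.
#' @export
evidence_model <- function(c = 351, prior = 0.10) {
  stopifnot(prior > 0, prior < 1)
  structure(
    list(c = c, prior = prior, requirements = level_requirements(c)),
    class = "evidence_model"
  )
}

#' @export
print.evidence_model <- function(x, ...) {
  cat(sprintf("<evidence_model> c = %g, prior = %g\n", x$c, x$prior))
  print(round(x$requirements, 3))
  invisible(x)
}

#' Evidence line counts
#'
#' @param n_su,n_mo,n_st,n_vs non-negative integer counts of Supporting,
#'   Moderate, Strong, and Very Strong lines.
#' @return list of class `evidence_counts`.
#' @export
evidence_counts <- function(n_su = 0L, n_mo = 0L, n_st = 0L, n_vs = 0L) {
  counts <- c(n_su = n_su, n_mo = n_mo, n_st = n_st, n_vs = n_vs)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  structure(list(n_su = as.integer(n_su), n_mo = as.integer(n_mo),
                 n_st = as.integer(n_st), n_vs = as.integer(n_vs)),
            class = "evidence_counts")
}

#' Combine evidence lines into a total likelihood ratio
#'
#' Multiplies the per-line likelihood ratios, i.e. raises c to
#' `n_su/8 + n_mo/4 + n_st/2 + n_vs`.
#'
#' @param counts an [evidence_counts()] object (or a list with fields
#'   `n_su`, `n_mo`, `n_st`, `n_vs`).
#' @inheritParams level_requirements
#' @return combined LR+ (single numeric).
#' @examples
#' combine_evidence(evidence_counts(n_su = 8), c = 350)  # 350
#' @export
combine_evidence <- function(counts, c) {
  if (c <= 1) stop("`c` must be greater than 1", call. = FALSE)
  ex <- counts$n_su / 8 + counts$n_mo / 4 + counts$n_st / 2 + counts$n_vs
  c^ex
}

#' Posterior probability of pathogenicity from a likelihood ratio
#'
#' Odds-form Bayes rule: posterior odds = LR+ x prior odds, returned on the
#' probability scale as `lr * prior / ((lr - 1) * prior + 1)`. Strictly
#' increasing in `lr`; `lr = 1` returns the prior and `lr = Inf` returns 1.
#'
#' @param lr positive likelihood ratio(s), >= 0.
#' @param prior class prior in (0,1).
#' @return posterior probability in [0, 1], vectorized over `lr`.
#' @examples
#' round(posterior_from_lr(6, 0.21), 1)   # 0.6
#' round(posterior_from_lr(15, 0.25), 1)  # 0.8
#' @export
posterior_from_lr <- function(lr, prior) {
  stopifnot(prior > 0, prior < 1)
  if (any(lr < 0, na.rm = TRUE)) stop("`lr` must be >= 0", call. = FALSE)
  ifelse(is.infinite(lr), 1, lr * prior / ((lr - 1) * prior + 1))
}

#' Likelihood ratio implied by a posterior (inverse Bayes)
#'
#' @param posterior posterior probability in [0, 1).
#' @param prior class prior in (0,1).
#' @return the LR+ whose [posterior_from_lr()] equals `posterior`.
#' @export
lr_from_posterior <- function(posterior, prior) {
  stopifnot(prior > 0, prior < 1)
  if (any(posterior < 0 | posterior > 1)) {
    stop("`posterior` must lie in [0, 1]", call. = FALSE)
  }
  .lr_from_posterior(posterior, prior)
}

#' Score thresholds per evidence level
#'
#' For each level, the smallest grid score tau such that every grid score at
#' or above tau has estimated lr+ meeting the level's requirement (a
#' for-all condition over the upper tail, not a first crossing: an interior
#' dip below the requirement pushes the threshold above the dip). Levels
#' whose requirement is never sustained are reported as NA. Thresholds are
#' in the normalized (higher-is-positive) score units; when the input was
#' declared lower-is-positive the `"original"` attribute carries the
#' sign-flipped thresholds, to be read as "original score <= threshold".
#'
#' @param curve a [local_posterior()] curve on the observed-score grid.
#' @param model an [evidence_model()].
#' @param direction `"pathogenic"` (default) finds, per level, the smallest
#'   score above which lr+ always meets the level's requirement;
#'   `"benign"` mirrors the construction for evidence of benignity, using
#'   the reciprocal requirements (c^(-1/8), ...) and returning the largest
#'   score below which lr+ always stays at or under them.
#' @return named numeric vector (`supporting`, `moderate`, `strong`,
#'   `very_strong`), NA where a level is not reached; attributes `flipped`,
#'   `original` and `direction`.
#' @export
evidence_thresholds <- function(curve, model,
                                direction = c("pathogenic", "benign")) {
  stopifnot(inherits(curve, "local_calibration_curve"),
            inherits(model, "evidence_model"))
  direction <- match.arg(direction)
  lr <- curve$lr_plus
  s <- curve$score
  thr <- if (direction == "pathogenic") {
    suffix_min <- rev(cummin(rev(lr)))
    vapply(model$requirements, function(req) {
      ok <- which(suffix_min >= req)
      if (length(ok)) s[ok[1L]] else NA_real_
    }, 0)
  } else {
    prefix_max <- cummax(lr)
    vapply(1 / model$requirements, function(req) {
      ok <- which(prefix_max <= req)
      if (length(ok)) s[ok[length(ok)]] else NA_real_
    }, 0)
  }
  flipped <- isTRUE(attr(curve, "flipped"))
  structure(thr, flipped = flipped,
            original = if (flipped) -thr else thr,
            direction = direction)
}

#' Fraction of the target population reaching each evidence level
#'
#' Probability of a pathogenic (positive) prediction at each level's score
#' threshold, corrected to the target class prior:
#' `PPP(tau) = alpha * TPR(tau) + (1 - alpha) * FPR(tau)`. Levels with no
#' threshold contribute 0.
#'
#' @inheritParams roc_curve
#' @param thresholds output of [evidence_thresholds()] (or a named numeric
#'   vector of score thresholds, NA allowed).
#' @param target_prior class prior alpha of the target population, in (0,1).
#' @return named numeric vector of PPP values per level.
#' @export
fraction_reaching <- function(scores, thresholds, target_prior) {
  .check_both_classes(scores)
  stopifnot(target_prior > 0, target_prior < 1)
  out <- vapply(as.numeric(thresholds), function(tau) {
    if (is.na(tau)) return(0)
    r <- .rates_at(scores, tau)
    target_prior * r$tpr + (1 - target_prior) * r$fpr
  }, 0)
  names(out) <- names(thresholds)
  out
}

#' Solve for the evidence constant c from combining rules
#'
#' Given a set of evidence-combination rules, each asserting that a
#' particular combination of lines suffices for a class ("pathogenic" or
#' "likely_pathogenic"), finds the smallest c such that every rule's
#' combined likelihood ratio yields a posterior meeting its class target
#' (0.99 for pathogenic, 0.90 for likely pathogenic, by default) at the
#' given prior. The search is a bisection to 1e-6 on c; the result is also
#' reported as the smallest integer c satisfying all rules.
#'
#' @param prior class prior in (0,1).
#' @param rules list of rules; each rule is a list with fields `counts` (an
#'   [evidence_counts()]) and `class` (`"pathogenic"` or
#'   `"likely_pathogenic"`).
#' @param targets named posterior targets per class.
#' @param c_max upper bound for the search.
#' @return list with `c_exact` (bisection solution) and `c` (smallest
#'   integer satisfying all rules).
#' @examples
#' solve_c(0.5, list(list(counts = evidence_counts(n_su = 8),
#'                        class = "pathogenic")))$c  # 99
#' @export
solve_c <- function(prior, rules,
                    targets = c(pathogenic = 0.99, likely_pathogenic = 0.90),
                    c_max = 1e12) {
  stopifnot(prior > 0, prior < 1)
  if (!length(rules)) stop("`rules` must be non-empty", call. = FALSE)
  for (r in rules) {
    if (is.null(r$counts) || is.null(r$class) || !r$class %in% names(targets)) {
      stop("each rule needs `counts` and a `class` named in `targets`",
           call. = FALSE)
    }
  }
  ok <- function(c) {
    all(vapply(rules, function(r) {
      posterior_from_lr(combine_evidence(r$counts, c), prior) >=
        targets[[r$class]]
    }, TRUE))
  }
  if (!ok(c_max)) {
    stop("no c below ", c_max, " satisfies all rules", call. = FALSE)
  }
  lo <- 1 + 1e-9
  hi <- c_max
  if (ok(lo)) {
    c_exact <- lo
  } else {
    while (hi - lo > 1e-6) {
      mid <- (lo + hi) / 2
      if (ok(mid)) hi <- mid else lo <- mid
    }
    c_exact <- hi
  }
  c_int <- max(2, floor(c_exact))
  while (!ok(c_int)) c_int <- c_int + 1
  list(c_exact = c_exact, c = c_int)
}
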