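#' Full assessment report for a score set
#'
#' Orchestrates the package over one input. For binary (labeled) scores:
#' tie-aware AUC and truncated AUC with bootstrap confidence intervals, the
#' ROC point list, the local calibration curve, evidence-level score
#' thresholds under the configured evidence model, the fraction of the
#' target population reaching each level, and threshold metrics (MCC,
#' likelihood ratios, DOR) at each attained evidence threshold. For
#' continuous pairs: R^2, RMSE, Pearson, Spearman and Kendall tau-b, each
#' with bootstrap confidence intervals.
#'
#' @param scores a [labeled_scores()] or [continuous_pairs()] object.
#' @param config an [analysis_config()].
#' @return list of class `predcal_report`.
#' @export
run_report <- function(scores, config = analysis_config()) {
  if (inherits(scores, "labeled_scores")) {
    .run_report_binary(scores, config)
  } else if (inherits(scores, "continuous_pairs")) {
    .run_report_continuous(scores, config)
  } else {
    stop("`scores` must be labeled_scores or continuous_pairs", call. = FALSE)
  }
}

.boot_row <- function(data, name, metric, config, seed_offset) {
  b <- bootstrap_metric(data, metric,
                        iterations = config$bootstrap_iterations,
                        level = config$level,
                        seed = config$seed + seed_offset)
  data.frame(metric = name, estimate = b$point,
             ci_low = b$ci_low, ci_high = b$ci_high,
             stringsAsFactors = FALSE)
}

.run_report_binary <- function(scores, config) {
  .check_both_classes(scores)
  metrics <- rbind(
    .boot_row(scores, "auc", auc, config, 1L),
    .boot_row(scores, "truncated_auc",
              function(d) truncated_auc(d, config$truncation_fpr), config, 2L)
  )
  roc <- roc_curve(scores)
  curve <- local_posterior(scores, config = config)
  model <- evidence_model(c = config$evidence_constant,
                          prior = config$target_prior)
  thr <- evidence_thresholds(curve, model)
  ppp <- fraction_reaching(scores, thr, config$target_prior)
  evidence <- data.frame(
    level = names(model$requirements),
    lr_requirement = unname(model$requirements),
    threshold = unname(as.numeric(thr)),
    ppp = unname(ppp),
    stringsAsFactors = FALSE
  )
  at_thresholds <- lapply(as.numeric(thr)[!is.na(thr)], function(tau) {
    threshold_metrics(scores, tau)
  })
  names(at_thresholds) <- names(thr)[!is.na(thr)]
  transfer <- transfer_report(curve, scores, config$target_prior)
  structure(
    list(type = "binary", n = nrow(scores),
         alpha_test = attr(curve, "alpha_test"),
         config = config, metrics = metrics, roc = roc,
         calibration = curve, evidence = evidence,
         threshold_metrics = at_thresholds, transfer = transfer),
    class = "predcal_report"
  )
}

.run_report_continuous <- function(pairs, config) {
  .check_pairs(pairs, 3L)
  metrics <- rbind(
    .boot_row(pairs, "r2", r_squared, config, 1L),
    .boot_row(pairs, "rmse", rmse, config, 2L),
    .boot_row(pairs, "pearson", pearson, config, 3L),
    .boot_row(pairs, "spearman", spearman, config, 4L),
    .boot_row(pairs, "kendall_tau_b", kendall_tau_b, config, 5L)
  )
  structure(
    list(type = "continuous", n = nrow(pairs), config = config,
         metrics = metrics),
    class = "predcal_report"
  )
}

#' @export
print.predcal_report <- function(x, digits = 4, ...) {
  cat(sprintf("<predcal_report> %s input, n = %d\n", x$type, x$n))
  cat("\nMetrics (with ", 100 * x$config$level, "% bootstrap CIs, ",
      x$config$bootstrap_iterations, " iterations):\n", sep = "")
  m <- x$metrics
  m[, -1L] <- round(m[, -1L], digits)
  print.data.frame(m, row.names = FALSE)
  if (x$type == "binary") {
    cat(sprintf("\nTest-set prior alpha_D = %.4f; target prior alpha = %g; c = %g\n",
                x$alpha_test, x$config$target_prior,
                x$config$evidence_constant))
    cat("\nEvidence levels (NA threshold = level not reached):\n")
    ev <- x$evidence
    ev$lr_requirement <- signif(ev$lr_requirement, 4)
    ev$threshold <- round(ev$threshold, digits)
    ev$ppp <- round(ev$ppp, digits)
    print.data.frame(ev, row.names = FALSE)
  }
  invisible(x)
}

# jsonlite stringifies non-finite values; map them to null / +-1e308-free
# explicit markers instead so downstream parsers are not surprised.
.json_sanitize <- function(x) {
  if (is.list(x)) return(lapply(x, .json_sanitize))
  if (is.data.frame(x)) {
    x[] <- lapply(x, function(col) {
      if (is.numeric(col)) ifelse(is.finite(col) | is.na(col), col, NA) else col
    })
    return(x)
  }
  if (is.numeric(x)) return(ifelse(is.finite(x) | is.na(x), x, NA))
  x
}

#' Write a machine-readable (JSON) report
#'
#' Serializes a [run_report()] result. Non-finite numbers (infinite
#' likelihood ratios at perfectly separated scores) are written as null.
#'
#' @param report a `predcal_report`.
#' @param path output path for the JSON document.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "predcal_report"))
  out <- unclass(report)
  out$config <- unclass(out$config)
  for (f in c("roc", "calibration", "transfer")) {
    if (!is.null(out[[f]])) out[[f]] <- as.data.frame(out[[f]])
  }
  if (!is.null(out$threshold_metrics)) {
    out$threshold_metrics <- lapply(out$threshold_metrics, unclass)
  }
  out <- .json_sanitize(out)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE, dataframe = "rows")
  invisible(path)
}
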