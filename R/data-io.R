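#' Labeled predictor scores
#'
#' Container for per-item predictor scores with binary pathogenicity labels.
#' Scores are normalized at construction so that higher scores always point
#' towards the positive (pathogenic) class: inputs declared
#' `lower_is_positive` are sign-flipped once, and the flip is recorded in the
#' `"flipped"` attribute so thresholds can be reported back in original units.
#'
#' @param score numeric vector of predictor outputs.
#' @param label binary labels; 0/1, logical, or a character dialect understood
#'   by [parse_labels()].
#' @param item_id optional unique item identifiers; generated if omitted.
#' @param orientation `"higher_is_positive"` (default) or
#'   `"lower_is_positive"`.
#' @param label_map optional named vector mapping label strings to 0/1,
#'   passed to [parse_labels()].
#'
#' @return A data frame of class `labeled_scores` with columns `item_id`,
#'   `score`, `label`, carrying attributes `orientation`
#'   (always `"higher_is_positive"` after normalization) and `flipped`.
#' @examples
#' labeled_scores(c(0.9, 0.2, 0.7), c("pathogenic", "benign", "pathogenic"))
#' @export
labeled_scores <- function(score, label, item_id = NULL,
                           orientation = c("higher_is_positive", "lower_is_positive"),
                           label_map = NULL) {
  orientation <- match.arg(orientation)
  score <- as.numeric(score)
  label <- parse_labels(label, label_map)
  if (length(score) != length(label)) {
    stop("`score` and `label` must have the same length", call. = FALSE)
  }
  if (anyNA(score)) stop("`score` contains missing values", call. = FALSE)
  if (is.null(item_id)) {
    item_id <- sprintf("item_%d", seq_along(score))
  } else {
    item_id <- as.character(item_id)
  }
  if (anyDuplicated(item_id)) {
    stop("duplicate item_id: ", item_id[duplicated(item_id)][1L], call. = FALSE)
  }
  flipped <- orientation == "lower_is_positive"
  if (flipped) score <- -score
  structure(
    data.frame(item_id = item_id, score = score, label = label,
               stringsAsFactors = FALSE),
    class = c("labeled_scores", "data.frame"),
    orientation = "higher_is_positive",
    flipped = flipped
  )
}

#' Parse binary pathogenicity labels
#'
#' Accepts 0/1 (numeric or character), logical, and the case-insensitive
#' dialects benign/pathogenic and negative/positive. A custom mapping can be
#' supplied for other dialects.
#'
#' @param x vector of raw labels.
#' @param label_map optional named numeric vector, e.g.
#'   `c(damaging = 1, tolerated = 0)`; names are matched case-insensitively.
#' @return integer vector of 0/1.
#' @export
parse_labels <- function(x, label_map = NULL) {
  if (is.logical(x)) return(as.integer(x))
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1))) {
      bad <- which(!(x %in% c(0, 1)))[1L]
      stop("unparseable label at row ", bad, ": ", x[bad], call. = FALSE)
    }
    return(as.integer(x))
  }
  dict <- c("0" = 0L, "1" = 1L,
            "benign" = 0L, "pathogenic" = 1L,
            "negative" = 0L, "positive" = 1L)
  if (!is.null(label_map)) {
    user <- as.integer(label_map)
    names(user) <- tolower(names(label_map))
    dict <- c(user, dict[setdiff(names(dict), names(user))])
  }
  key <- tolower(trimws(as.character(x)))
  out <- unname(dict[key])
  if (anyNA(out) && !anyNA(x)) {
    bad <- which(is.na(out))[1L]
    stop("unparseable label at row ", bad, ": \"", x[bad], "\"", call. = FALSE)
  }
  out
}

#' Predicted/observed continuous value pairs
#'
#' @param predicted numeric predictions, in assay units.
#' @param observed numeric experimental values, in the same units. Observed
#'   values are taken as-is (they may already be averages over replicates).
#' @param item_id optional unique identifiers.
#' @return data frame of class `continuous_pairs` with columns `item_id`,
#'   `predicted`, `observed`.
#' @examples
#' continuous_pairs(c(0.1, 0.5, 0.8), c(0.2, 0.4, 0.9))
#' @export
continuous_pairs <- function(predicted, observed, item_id = NULL) {
  predicted <- as.numeric(predicted)
  observed <- as.numeric(observed)
  if (length(predicted) != length(observed)) {
    stop("`predicted` and `observed` must have the same length", call. = FALSE)
  }
  if (anyNA(predicted) || anyNA(observed)) {
    stop("missing values in predicted/observed", call. = FALSE)
  }
  if (is.null(item_id)) {
    item_id <- sprintf("item_%d", seq_along(predicted))
  } else {
    item_id <- as.character(item_id)
  }
  if (anyDuplicated(item_id)) {
    stop("duplicate item_id: ", item_id[duplicated(item_id)][1L], call. = FALSE)
  }
  structure(
    data.frame(item_id = item_id, predicted = predicted, observed = observed,
               stringsAsFactors = FALSE),
    class = c("continuous_pairs", "data.frame")
  )
}

#' Analysis configuration
#'
#' Collects the tunable constants of a calibration analysis in one place.
#' Defaults follow the clinical operating point for a diagnostic-setting
#' class prior of 10%: evidence constant c = 351 (for the 1% screening prior
#' use c = 8511), local windows of half-width 5% of the robust score range
#' with at least 10% of items (capped at 50) per window, and 1000 bootstrap
#' iterations.
#'
#' @param target_prior class prior of the target (reference) population,
#'   in (0,1).
#' @param test_prior optional override for the test-set prior; defaults to
#'   the observed fraction of positives when NULL.
#' @param evidence_constant positive likelihood ratio of one Very Strong line
#'   of evidence (c > 1).
#' @param truncation_fpr FPR cap for the truncated AUC.
#' @param window_fraction local-window half-width as a fraction of the
#'   5th-95th percentile score range.
#' @param window_min_fraction minimum fraction of items per window.
#' @param window_max_count cap on the minimum item count per window.
#' @param bootstrap_iterations bootstrap iteration count.
#' @param level confidence level for intervals.
#' @param seed integer seed controlling all randomness downstream.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(target_prior = 0.10,
                            test_prior = NULL,
                            evidence_constant = 351,
                            truncation_fpr = 0.2,
                            window_fraction = 0.05,
                            window_min_fraction = 0.10,
                            window_max_count = 50,
                            bootstrap_iterations = 1000,
                            level = 0.95,
                            seed = 1L) {
  stopifnot(
    target_prior > 0, target_prior < 1,
    is.null(test_prior) || (test_prior > 0 && test_prior < 1),
    evidence_constant > 1,
    truncation_fpr > 0, truncation_fpr <= 1,
    window_fraction > 0, window_fraction <= 1,
    window_min_fraction > 0, window_min_fraction <= 1,
    window_max_count >= 1,
    bootstrap_iterations >= 1,
    level > 0, level < 1
  )
  structure(
    list(target_prior = target_prior, test_prior = test_prior,
         evidence_constant = evidence_constant,
         truncation_fpr = truncation_fpr,
         window_fraction = window_fraction,
         window_min_fraction = window_min_fraction,
         window_max_count = window_max_count,
         bootstrap_iterations = bootstrap_iterations,
         level = level, seed = as.integer(seed)),
    class = "analysis_config"
  )
}

#' Read an analysis configuration from YAML
#'
#' The YAML keys mirror the arguments of [analysis_config()].
#'
#' @param path path to a YAML file.
#' @return list of class `analysis_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  extra <- setdiff(names(vals), known)
  if (length(extra)) {
    stop("unknown configuration field(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  do.call(analysis_config, vals)
}

.read_table <- function(path, format) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  }
  sep <- if (format == "csv") "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, comment.char = "",
                    check.names = FALSE)
}

.numeric_column <- function(x, col) {
  if (is.numeric(x)) return(x)
  raw <- trimws(as.character(x))
  out <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(out) & !is.na(raw) & raw != "" &
                 !toupper(raw) %in% c("NA", "NAN"))
  if (length(bad)) {
    stop("non-numeric value in column '", col, "' at row ", bad[1L], ": \"",
         raw[bad[1L]], "\"", call. = FALSE)
  }
  out
}

#' Read labeled scores from a delimited table
#'
#' Rows with a missing score or missing label are dropped and counted in the
#' `"load_report"` attribute; unparseable (non-missing) labels are an error.
#'
#' @param path path to a TSV/CSV file with a header row.
#' @param format `"auto"` (by extension), `"tsv"`, or `"csv"`.
#' @param score_column,label_column,id_column column names; `id_column` NULL
#'   generates identifiers.
#' @inheritParams labeled_scores
#' @return [labeled_scores()] object with attribute `load_report`
#'   (`n_read`, `n_dropped`).
#' @export
read_scores <- function(path, format = c("auto", "tsv", "csv"),
                        score_column = "score", label_column = "label",
                        id_column = NULL,
                        orientation = c("higher_is_positive", "lower_is_positive"),
                        label_map = NULL) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  tab <- .read_table(path, format)
  for (col in c(score_column, label_column, id_column)) {
    if (!col %in% names(tab)) {
      stop("column '", col, "' not found in ", path, call. = FALSE)
    }
  }
  score <- .numeric_column(tab[[score_column]], score_column)
  raw_label <- tab[[label_column]]
  if (is.character(raw_label)) {
    raw_label[trimws(raw_label) == ""] <- NA
  }
  keep <- !is.na(score) & !is.na(raw_label)
  n_dropped <- sum(!keep)
  if (!any(keep)) stop("no usable rows in ", path, call. = FALSE)
  out <- labeled_scores(
    score = score[keep],
    label = parse_labels(raw_label[keep], label_map),
    item_id = if (is.null(id_column)) NULL else tab[[id_column]][keep],
    orientation = orientation
  )
  attr(out, "load_report") <- list(n_read = nrow(tab), n_dropped = n_dropped)
  out
}

#' Read predicted/observed pairs from a delimited table
#'
#' Non-numeric cells are an error naming the offending row; rows where either
#' value is missing are dropped and counted in the `"load_report"` attribute.
#'
#' @inheritParams read_scores
#' @param predicted_column,observed_column column names.
#' @return [continuous_pairs()] object with attribute `load_report`.
#' @export
read_continuous <- function(path, format = c("auto", "tsv", "csv"),
                            predicted_column = "predicted",
                            observed_column = "observed",
                            id_column = NULL) {
  format <- match.arg(format)
  tab <- .read_table(path, format)
  for (col in c(predicted_column, observed_column, id_column)) {
    if (!col %in% names(tab)) {
      stop("column '", col, "' not found in ", path, call. = FALSE)
    }
  }
  predicted <- .numeric_column(tab[[predicted_column]], predicted_column)
  observed <- .numeric_column(tab[[observed_column]], observed_column)
  keep <- !is.na(predicted) & !is.na(observed)
  if (!any(keep)) stop("no usable rows in ", path, call. = FALSE)
  out <- continuous_pairs(
    predicted[keep], observed[keep],
    item_id = if (is.null(id_column)) NULL else tab[[id_column]][keep]
  )
  attr(out, "load_report") <- list(n_read = nrow(tab), n_dropped = sum(!keep))
  out
}

#' Write labeled scores to a delimited table
#'
#' Scores are written with 17 significant digits so that a write/read
#' round trip reproduces them bit-exactly.
#'
#' @param scores a [labeled_scores()] object.
#' @param path output path.
#' @param format `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(scores, "labeled_scores"))
  sep <- if (format == "csv") "," else "\t"
  out <- data.frame(
    item_id = scores$item_id,
    score = vapply(scores$score, function(v) format(v, digits = 17), ""),
    label = scores$label,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.labeled_scores <- function(x, ...) {
  n1 <- sum(x$label == 1)
  cat(sprintf("<labeled_scores> %d items (%d positive, %d negative)\n",
              nrow(x), n1, nrow(x) - n1))
  if (isTRUE(attr(x, "flipped"))) {
    cat("  scores sign-flipped from a lower_is_positive input\n")
  }
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("  ...\n")
  invisible(x)
}

#' @export
print.continuous_pairs <- function(x, ...) {
  cat(sprintf("<continuous_pairs> %d items\n", nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("  ...\n")
  invisible(x)
}

.check_labeled <- function(scores) {
  if (!inherits(scores, "labeled_scores")) {
    stop("expected a `labeled_scores` object", call. = FALSE)
  }
  invisible(scores)
}

.check_both_classes <- function(scores) {
  .check_labeled(scores)
  if (!any(scores$label == 1) || !any(scores$label == 0)) {
    stop("both label classes must be present", call. = FALSE)
  }
  invisible(scores)
}

.check_pairs <- function(pairs, n_min = 1L) {
  if (!inherits(pairs, "continuous_pairs")) {
    stop("expected a `continuous_pairs` object", call. = FALSE)
  }
  if (nrow(pairs) < n_min) {
    stop("need at least ", n_min, " pairs", call. = FALSE)
  }
  invisible(pairs)
}
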