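#' Confusion matrix for one binary problem
#'
#' @param predictions predicted labels, each one of the problem's two
#'   diagnosis names (or 0/1 relative to `positive_class`).
#' @param truths true labels, same coding and length.
#' @param positive_class the diagnosis counted as positive.
#' @param negative_class the other diagnosis; required when labels are
#'   diagnosis names, optional for 0/1 coding.
#' @return object of class `confusion_matrix`: tp, fp, tn, fn counts.
#' @export
confusion <- function(predictions, truths, positive_class,
                      negative_class = NULL) {
  if (length(predictions) != length(truths))
    stop_labeled("length_mismatch", "predictions (%d) and truths (%d) differ",
                 length(predictions), length(truths))
  coerce <- function(v, what) {
    if (is.numeric(v)) {
      if (!all(v %in% c(0, 1)))
        stop_labeled("bad_label", "%s has numeric labels outside {0, 1}", what)
      return(as.integer(v))
    }
    allowed <- c(negative_class, positive_class)
    if (!all(v %in% allowed))
      stop_labeled("bad_label", "%s has labels outside the problem pair (%s)",
                   what, paste(allowed, collapse = ", "))
    as.integer(v == positive_class)
  }
  p <- coerce(predictions, "predictions")
  t <- coerce(truths, "truths")
  structure(list(tp = sum(p == 1 & t == 1), fp = sum(p == 1 & t == 0),
                 tn = sum(p == 0 & t == 0), fn = sum(p == 0 & t == 1),
                 positive_class = positive_class),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> positive=%s  tp=%d fp=%d tn=%d fn=%d\n",
              x$positive_class %||% "1", x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Accuracy, sensitivity, specificity (as percentages) from a confusion matrix
#'
#' Sensitivity is the true-positive rate among actual positives, specificity
#' the true-negative rate among actual negatives. A degenerate denominator
#' (no positives, or no negatives, in the evaluated set) yields `NA` with an
#' `undefined` flag rather than a fabricated 0 or 100.
#'
#' @param cm a [confusion()] result.
#' @param problem optional ordered pair of diagnosis names (negative,
#'   positive) recorded in the result.
#' @param holdout_mode optional "subject" or "slice" tag.
#' @return one-row data.frame of class `metrics_record`: problem, mode,
#'   accuracy, sensitivity, specificity (percent), undefined flags.
#' @export
metrics <- function(cm, problem = NULL, holdout_mode = NA_character_) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tp + cm$fp + cm$tn + cm$fn
  if (total == 0) stop_labeled("empty_confusion", "no evaluated slices")
  pos <- cm$tp + cm$fn
  neg <- cm$tn + cm$fp
  rec <- data.frame(
    problem = if (is.null(problem)) NA_character_ else paste(problem, collapse = " vs. "),
    holdout_mode = holdout_mode,
    accuracy = 100 * (cm$tp + cm$tn) / total,
    sensitivity = if (pos > 0) 100 * cm$tp / pos else NA_real_,
    specificity = if (neg > 0) 100 * cm$tn / neg else NA_real_,
    undefined_sensitivity = pos == 0,
    undefined_specificity = neg == 0,
    stringsAsFactors = FALSE)
  class(rec) <- c("metrics_record", class(rec))
  rec
}

#' Median of each metric across binary problems
#'
#' The per-mode summary statistic: the median accuracy, sensitivity and
#' specificity over a set of binary-problem records, midpoint convention for
#' even counts (`stats::median`). All records must share one hold-out mode.
#'
#' @param records data.frame of metric rows (e.g. rbind of [metrics()]
#'   results), with columns accuracy, sensitivity, specificity and
#'   holdout_mode.
#' @param na.rm drop undefined (NA) entries before taking medians.
#' @return named list: accuracy, sensitivity, specificity medians.
#' @export
median_metrics <- function(records, na.rm = FALSE) {
  if (nrow(records) < 1) stop_labeled("no_records", "need at least one record")
  modes <- unique(records$holdout_mode)
  modes <- modes[!is.na(modes)]
  if (length(modes) > 1)
    stop_labeled("mixed_modes", "records mix hold-out modes (%s)",
                 paste(modes, collapse = ", "))
  list(accuracy = stats::median(records$accuracy, na.rm = na.rm),
       sensitivity = stats::median(records$sensitivity, na.rm = na.rm),
       specificity = stats::median(records$specificity, na.rm = na.rm))
}

#' Per-problem performance gap between the two hold-out modes
#'
#' For every binary problem evaluated under both modes, computes
#' (slice-mode minus subject-mode) differences in accuracy, sensitivity and
#' specificity — the leakage gap — together with the leakage audits of both
#' plans (when supplied) and per-mode median summaries.
#'
#' @param subject_records,slice_records metric tables for the same problem
#'   list under subject-level and slice-level hold-out.
#' @param subject_audit,slice_audit optional [audit_leakage()] results.
#' @return object of class `leakage_report`.
#' @export
leakage_gap <- function(subject_records, slice_records,
                        subject_audit = NULL, slice_audit = NULL) {
  if (!setequal(subject_records$problem, slice_records$problem) ||
      nrow(subject_records) != nrow(slice_records))
    stop_labeled("problem_mismatch", "the two record sets cover different problems")
  sl <- slice_records[match(subject_records$problem, slice_records$problem), ]
  gaps <- data.frame(problem = subject_records$problem,
                     accuracy_gap = sl$accuracy - subject_records$accuracy,
                     sensitivity_gap = sl$sensitivity - subject_records$sensitivity,
                     specificity_gap = sl$specificity - subject_records$specificity,
                     stringsAsFactors = FALSE)
  structure(list(
    gaps = gaps,
    median_subject = median_metrics(subject_records, na.rm = TRUE),
    median_slice = median_metrics(slice_records, na.rm = TRUE),
    subject_audit = subject_audit,
    slice_audit = slice_audit),
    class = "leakage_report")
}

#' @export
print.leakage_report <- function(x, ...) {
  cat("<leakage_report>\n")
  cat(sprintf("  median accuracy: slice %.2f%% vs subject %.2f%% (gap %+0.2f points)\n",
              x$median_slice$accuracy, x$median_subject$accuracy,
              x$median_slice$accuracy - x$median_subject$accuracy))
  if (!is.null(x$subject_audit))
    cat(sprintf("  subject plan leaky: %s; slice plan leaky: %s\n",
                x$subject_audit$leaky, x$slice_audit$leaky))
  invisible(x)
}

#' Write a leakage report as JSON
#' @param report a `leakage_report`.
#' @param path output path.
#' @export
write_leakage_report <- function(report, path) {
  jsonlite::write_json(list(
    gaps = report$gaps,
    median_subject = report$median_subject,
    median_slice = report$median_slice,
    subject_audit = if (is.null(report$subject_audit)) NULL else
      unclass(report$subject_audit),
    slice_audit = if (is.null(report$slice_audit)) NULL else
      unclass(report$slice_audit)
  ), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Bundled reference metrics from a published two-hold-out fMRI replication
#'
#' The seven-problem benchmark table (accuracy/sensitivity/specificity under
#' subject-level and slice-level hold-out) that motivated this harness, as
#' printed; used to exercise median aggregation and the gap computation on
#' real reported numbers.
#'
#' @return data.frame with columns problem, holdout_mode, accuracy,
#'   sensitivity, specificity (percentages).
#' @export
reference_metrics <- function() {
  path <- system.file("extdata", "reference_metrics.csv", package = "sliceleak",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
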