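#' @title Binary-classifier evaluation of mapping sets
#' @name evaluation
#' @description Predicted id sets are scored against gold-standard id sets
#'   within an explicit universe: TP are predictions present in the gold
#'   set, FP predictions absent from it, FN gold members missed, TN the
#'   rest of the universe. Sensitivity and positive predictive value are
#'   derived; undefined ratios are reported as `NA`, never coerced to 0.
NULL

#' Construct a confusion matrix from counts
#'
#' @param tp,fp,tn,fn non-negative counts.
#' @return An object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) abort("confusion_matrix: counts must be >= 0")
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 universe_size = tp + fp + tn + fn),
            class = "confusion_matrix")
}

#' Confusion matrix of a predicted set against a gold set
#'
#' @param predicted character vector of predicted ids (must lie in
#'   `universe`).
#' @param gold character vector of gold-standard ids (must lie in
#'   `universe`).
#' @param universe character vector of all ids under evaluation.
#' @return A `confusion_matrix`.
#' @export
confusion <- function(predicted, gold, universe) {
  predicted <- unique(predicted)
  gold <- unique(gold)
  universe <- unique(universe)
  if (!all(predicted %in% universe)) {
    abort("confusion: predicted ids not contained in the universe")
  }
  if (!all(gold %in% universe)) {
    abort("confusion: gold ids not contained in the universe")
  }
  tp <- length(intersect(predicted, gold))
  fp <- length(setdiff(predicted, gold))
  fn <- length(setdiff(gold, predicted))
  tn <- length(universe) - tp - fp - fn
  confusion_matrix(tp = tp, fp = fp, tn = tn, fn = fn)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion matrix> TP=%d FP=%d TN=%d FN=%d (universe %d)\n",
              x$tp, x$fp, x$tn, x$fn, x$universe_size))
  invisible(x)
}

#' Sensitivity and positive predictive value
#'
#' `sensitivity = TP / (TP + FN)`, `ppv = TP / (TP + FP)`. A ratio with a
#' zero denominator is undefined and returned as `NA`.
#'
#' @param cm a `confusion_matrix`.
#' @return A one-row tibble with columns `sensitivity`, `ppv`.
#' @export
confusion_stats <- function(cm) {
  tibble(
    sensitivity = if (cm$tp + cm$fn > 0) cm$tp / (cm$tp + cm$fn) else NA_real_,
    ppv = if (cm$tp + cm$fp > 0) cm$tp / (cm$tp + cm$fp) else NA_real_)
}

#' @rdname confusion_stats
#' @param x a `confusion_matrix`.
#' @param ... unused.
#' @export
tidy.confusion_matrix <- function(x, ...) {
  tibble(outcome = c("tp", "fp", "tn", "fn"),
         count = c(x$tp, x$fp, x$tn, x$fn))
}

#' @rdname confusion_stats
#' @export
glance.confusion_matrix <- function(x, ...) {
  dplyr::bind_cols(
    tibble(tp = x$tp, fp = x$fp, tn = x$tn, fn = x$fn,
           universe_size = x$universe_size),
    confusion_stats(x))
}

#' Check a confusion matrix against externally stated totals
#'
#' `TRUE` iff `tp + fp` equals the number of predictions, `tp + fn` the
#' gold-set size, and the four cells sum to the universe size.
#'
#' @param cm a `confusion_matrix`.
#' @param n_predicted,n_gold,n_universe stated totals.
#' @return Logical scalar.
#' @export
validate_confusion <- function(cm, n_predicted, n_gold, n_universe) {
  (cm$tp + cm$fp == n_predicted) &&
    (cm$tp + cm$fn == n_gold) &&
    (cm$universe_size == n_universe)
}

#' Componentwise differences between two evaluations
#'
#' @param cm_a,cm_b confusion matrices over the same universe.
#' @param mapped_a,mapped_b the mapped-set sizes being compared.
#' @return A one-row tibble `d_tp`, `d_fp`, `d_mapped` (A minus B).
#' @export
compare_confusion <- function(cm_a, cm_b, mapped_a, mapped_b) {
  if (cm_a$universe_size != cm_b$universe_size) {
    abort("compare_confusion: universes differ")
  }
  tibble(d_tp = cm_a$tp - cm_b$tp,
         d_fp = cm_a$fp - cm_b$fp,
         d_mapped = mapped_a - mapped_b)
}
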