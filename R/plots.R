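#' @title Plots for mapping and confirmation results
#' @name plots
#' @description `autoplot()` methods give quick ggplot2 views of each
#'   result type: the 2x2 outcome counts of a confusion matrix, the tier
#'   distribution of a confirmation report, and the attrition of pairs
#'   across successively refined mapping sets.
NULL

#' @rdname plots
#' @param object a `confusion_matrix`.
#' @param ... unused.
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  d <- tidy(object)
  d$truth <- ifelse(d$outcome %in% c("tp", "fn"), "in gold set",
                    "not in gold set")
  d$called <- ifelse(d$outcome %in% c("tp", "fp"), "predicted",
                     "not predicted")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$called, y = .data$truth,
                                  fill = .data$count)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(
      label = paste0(toupper(.data$outcome), "\n", .data$count))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 guide = "none") +
    ggplot2::labs(x = NULL, y = NULL, title = "Confusion matrix") +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @export
autoplot.link_confirmation <- function(object, ...) {
  s <- object$summary
  d <- tibble(
    tier = factor(c("strong_3x", "strong_2x", "weak", "unsupported",
                    "no_data"),
                  levels = c("strong_3x", "strong_2x", "weak",
                             "unsupported", "no_data")),
    n = c(s$strong_3x, s$strong_2x, s$weak, s$unsupported, s$no_data))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$tier, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "confirmation tier", y = "predicted links",
                  title = sprintf("Link confirmation (%d analyzed, %d verified)",
                                  s$n_analyzed, s$n_verified)) +
    ggplot2::theme_minimal()
}

#' Attrition of mapped pairs across refinement levels
#'
#' Shows pair and distinct-target counts for a list of mapping sets, in
#' the order given (e.g. similarity-only, family-refined,
#' subfamily-refined).
#'
#' @param sets a list of `reglink_mapping` objects.
#' @return A ggplot object.
#' @export
plot_mapping_attrition <- function(sets) {
  d <- bind_rows(lapply(sets, glance))
  d$label <- factor(d$label, levels = d$label)
  long <- tidyr::pivot_longer(d, c("n_pairs", "n_distinct_targets"),
                              names_to = "measure", values_to = "n")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$n,
                                     fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "mapping set", y = "count",
                  title = "Mapping-set attrition under refinement") +
    ggplot2::theme_minimal()
}
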