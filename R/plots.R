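#' Plot a ROC curve
#'
#' @param object A `"roc_result"` from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  thr <- c(Inf, sort(unique(object$scores), decreasing = TRUE))
  is_pos <- object$labels == object$positive
  pts <- purrr::map_dfr(thr, function(t) {
    tibble(fpr = mean(object$scores[!is_pos] >= t),
           tpr = mean(object$scores[is_pos] >= t))
  })
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("AUC = %.3f (%d%% CI %.3f-%.3f)", object$auc,
                      round(100 * object$conf_level), object$ci_low,
                      object$ci_high)
    ) +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential screen
#'
#' @param stats Screen tibble from [wilcoxon_screen()] (optionally with a
#'   `method` column, which is faceted).
#' @param p_threshold Significance line, default 0.05.
#' @return A ggplot.
#' @export
plot_screen_volcano <- function(stats, p_threshold = 0.05) {
  d <- filter(as_tibble(stats), is.finite(.data$fold_change),
              .data$fold_change > 0)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = log2(.data$fold_change),
                                       y = -log10(.data$p_value),
                                       colour = .data$p_value < p_threshold)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(p_threshold),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "log2 fold change (uncontrolled / controlled)",
                  y = "-log10 Wilcoxon p") +
    ggplot2::theme_minimal()
  if ("method" %in% names(d)) p <- p + ggplot2::facet_wrap(~method)
  p
}

#' Plot per-patient eGFR trajectories
#'
#' @param visits_egfr Visit table carrying an `egfr_<method>` column.
#' @param method Which equation's eGFR to plot.
#' @param labels Optional tibble (`patient_id`, `label`) to colour by.
#' @return A ggplot.
#' @export
plot_egfr_trajectories <- function(visits_egfr, method = "EKFC_CYS",
                                   labels = NULL) {
  col <- paste0("egfr_", method)
  d <- as_tibble(visits_egfr)
  if (!col %in% names(d)) abort(sprintf("no `%s` column", col))
  if (!is.null(labels)) {
    d <- left_join(d, as_tibble(labels)[, c("patient_id", "label")],
                   by = "patient_id")
  } else {
    d$label <- "all"
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_years, y = .data[[col]],
                                  group = .data$patient_id,
                                  colour = .data$label)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_hline(yintercept = 60, linetype = "dotted") +
    ggplot2::labs(x = "Years from baseline",
                  y = sprintf("eGFR (%s), mL/min/1.73m²", method),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of label agreement patterns
#'
#' @param object A `"label_concordance"` from [label_overlap()].
#' @param max_patterns Show at most this many most frequent patterns.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot label_concordance
#' @export
autoplot.label_concordance <- function(object, max_patterns = 12, ...) {
  pc <- head(object$pattern_counts, max_patterns)
  pc$pattern <- apply(pc[, object$methods, drop = FALSE], 1, paste,
                      collapse = " / ")
  ggplot2::ggplot(pc, ggplot2::aes(x = stats::reorder(.data$pattern, .data$n),
                                   y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = paste(object$methods, collapse = " / "),
                  y = "Patients") +
    ggplot2::theme_minimal()
}
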