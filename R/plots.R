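#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_abline geom_col
#'   geom_histogram geom_vline scale_x_log10 scale_y_log10 labs autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' ROC curve plot
#'
#' @param object An `endo_roc` from [metric_roc()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.endo_roc <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    geom_line() +
    geom_vline(xintercept = object$fp_max, linetype = "dotted") +
    labs(x = "False positive rate", y = "True positive rate",
         title = sprintf("AUC %.3f; partial AUC %.4f at FP <= %.0f%%",
                         object$auc, object$pauc, 100 * object$fp_max))
}

#' Elution profile plot
#'
#' @param profiles Long tibble `accession`, `fraction`, `intensity`
#'   (optionally `replicate`).
#' @param accessions Optional subset of proteins to show.
#' @return A ggplot of intensity against fraction, one line per protein.
#' @export
plot_elution_profiles <- function(profiles, accessions = NULL) {
  df <- as_tibble(profiles)
  if (!is.null(accessions)) df <- df[df$accession %in% accessions, ]
  p <- ggplot(df, aes(x = .data$fraction, y = .data$intensity,
                      colour = .data$accession)) +
    geom_line() +
    labs(x = "Fraction (1 = highest apparent mass)", y = "Intensity")
  if ("replicate" %in% names(df)) {
    p <- p + ggplot2::facet_wrap(~replicate)
  }
  p
}

#' Degree-distribution plot with power-law fit
#'
#' @param object A `network_stats` from [network_stats()].
#' @param ... Unused.
#' @return A ggplot on log-log axes.
#' @export
autoplot.network_stats <- function(object, ...) {
  ggplot(object$degree_histogram, aes(x = .data$degree, y = .data$count)) +
    geom_point() +
    scale_x_log10() + scale_y_log10() +
    labs(x = "Degree", y = "Frequency",
         title = sprintf("Power-law R² = %.3f", object$powerlaw_r2))
}

#' Cross-link distance histogram
#'
#' @param object An `xl_evaluation` from [evaluate_crosslinks()].
#' @param ... Unused.
#' @return A ggplot of Calpha-Calpha distances coloured by status, with the
#'   threshold marked.
#' @export
autoplot.xl_evaluation <- function(object, ...) {
  df <- object[!is.na(object$distance), ]
  ggplot(df, aes(x = .data$distance, fill = .data$status)) +
    geom_histogram(binwidth = 2.5, boundary = 0) +
    geom_vline(xintercept = df$threshold_used[1], linetype = "dashed") +
    labs(x = "Cα–Cα distance (Å)", y = "Cross-links")
}
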