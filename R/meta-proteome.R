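#' ROC evaluation of a localization metric
#'
#' Fits a binomial logistic regression of the reference label on the metric
#' and evaluates the resulting predictor by ROC, reporting the partial area
#' under the curve over the 0-10% false-positive range (and its normalized
#' form, partial AUC divided by the maximal attainable area). Because the
#' logistic transform of a single metric is monotone, the curve equals the
#' ROC of the raw metric.
#'
#' @param data Data frame of per-protein evidence.
#' @param metric Column holding the metric values (tidy-eval).
#' @param label Column holding the reference logical label (tidy-eval).
#' @param fp_max Upper end of the false-positive range (default 0.10).
#' @return An `endo_roc` object. `tidy()` gives the curve points
#'   (`fpr`, `tpr`); `glance()` gives `auc`, `pauc`, `pauc_normalized`.
#' @export
#' @examples
#' d <- gen_presence_matrix(200, 8, seed = 2)
#' metric_roc(d, dataset_presence, label == "endosome")
metric_roc <- function(data, metric, label, fp_max = 0.10) {
  m <- dplyr::pull(dplyr::mutate(data, .m = {{ metric }}), .data$.m)
  y <- dplyr::pull(dplyr::mutate(data, .y = {{ label }}), .data$.y)
  if (length(unique(y)) < 2) abort("both label classes must be present")
  if (length(unique(m)) < 2) {
    warn("metric is constant; reporting a degenerate (chance) ROC")
    curve <- tibble(fpr = c(0, 1), tpr = c(0, 1), threshold = NA_real_)
    out <- list(curve = curve, auc = 0.5, pauc = fp_max^2 / 2,
                pauc_normalized = fp_max / 2, fp_max = fp_max,
                degenerate = TRUE, roc = NULL)
    class(out) <- "endo_roc"
    return(out)
  }
  # perfect separation only saturates the fitted probabilities; the ROC of a
  # monotone transform is unchanged, so glm convergence warnings are moot here
  fit <- withCallingHandlers(
    glm(y ~ m, family = binomial()),
    warning = function(w) {
      if (grepl("glm\\.fit", conditionMessage(w)) ||
          grepl("fitted probabilities|did not converge", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  pred <- stats::predict(fit, type = "response")
  r <- pROC::roc(response = y, predictor = pred, quiet = TRUE,
                 direction = "<", levels = c(FALSE, TRUE))
  pauc <- as.numeric(pROC::auc(r, partial.auc = c(1, 1 - fp_max),
                               partial.auc.focus = "specificity"))
  curve <- tibble(
    fpr = 1 - r$specificities,
    tpr = r$sensitivities,
    threshold = r$thresholds
  )
  curve <- dplyr::arrange(curve, .data$fpr, .data$tpr)
  out <- list(curve = curve, auc = as.numeric(pROC::auc(r)), pauc = pauc,
              pauc_normalized = pauc / fp_max, fp_max = fp_max,
              degenerate = FALSE, roc = r)
  class(out) <- "endo_roc"
  out
}

#' @export
print.endo_roc <- function(x, ...) {
  cat(sprintf("<endo_roc: AUC %.3f, pAUC(FP<=%.0f%%) %.4f (normalized %.3f)%s>\n",
              x$auc, 100 * x$fp_max, x$pauc, x$pauc_normalized,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.endo_roc <- function(x, ...) x$curve

#' @exportS3Method generics::glance
glance.endo_roc <- function(x, ...) {
  tibble(auc = x$auc, pauc = x$pauc, pauc_normalized = x$pauc_normalized,
         fp_max = x$fp_max, degenerate = x$degenerate)
}

#' Combine localization metrics into a single score
#'
#' Sums the three per-protein metrics -- dataset presence, organelle-IP
#' abundance and reference-interaction count. By default each metric is
#' rank-normalized to `[0, 1]` first so their scales are commensurable
#' (`standardize = FALSE` sums raw values). Missing IP abundance is imputed
#' as the observed minimum (absence treated as not detected) and the number
#' of imputed values is reported via a message.
#'
#' @param data Data frame with columns `dataset_presence`, `ip_abundance`,
#'   `ref_interaction_count`.
#' @param standardize Rank-normalize each metric before summation.
#' @return `data` with added `metric_presence`, `metric_abundance`,
#'   `metric_interactions` (as used) and `combined_score`. The score is
#'   monotone non-decreasing in each metric.
#' @export
combine_scores <- function(data, standardize = TRUE) {
  stopifnot(all(c("dataset_presence", "ip_abundance", "ref_interaction_count")
                %in% names(data)))
  out <- as_tibble(data)
  n_missing <- sum(is.na(out$ip_abundance))
  if (n_missing > 0) {
    inform(sprintf("imputing %d missing ip_abundance value(s) as the observed minimum",
                   n_missing))
    out$ip_abundance[is.na(out$ip_abundance)] <-
      min(out$ip_abundance, na.rm = TRUE)
  }
  rank01 <- function(x) {
    if (length(x) < 2 || length(unique(x)) < 2) return(rep(0, length(x)))
    (rank(x, ties.method = "average") - 1) / (length(x) - 1)
  }
  f <- if (standardize) rank01 else identity
  out$metric_presence <- f(out$dataset_presence)
  out$metric_abundance <- f(out$ip_abundance)
  out$metric_interactions <- f(out$ref_interaction_count)
  out$combined_score <- out$metric_presence + out$metric_abundance +
    out$metric_interactions
  out
}

#' Call the organelle proteome at a target false-positive rate
#'
#' Chooses the smallest score threshold (over the distinct observed scores)
#' such that the fraction of reference-negative proteins at or above it does
#' not exceed `fp_target` -- i.e. calls as many proteins as the FP budget
#' allows. Negatives are proteins not on the curated reference list (the
#' reference has no curated negative set; this is an approximation).
#' Proteins on the exclusion list (e.g. a mitochondrial catalogue) are never
#' called. Ties at the threshold are included (`>=`); if that violates the
#' FP bound the next distinct score is used.
#'
#' @param data Data frame with a combined score column and a reference
#'   label column.
#' @param score Score column (tidy-eval), default `combined_score`.
#' @param label Reference logical column (tidy-eval), default `is_reference`.
#' @param fp_target Allowed false-positive fraction among negatives (0.10).
#' @param exclude Logical column flagging excluded proteins (tidy-eval),
#'   or `NULL`.
#' @return An `endo_call`: the input tibble with `predicted_endosomal`,
#'   `called_or_reference`, `threshold_used`, `fp_target`. `glance()` gives
#'   the realized FP rate, recall on the reference, threshold and counts.
#' @export
call_endosomal <- function(data, score = combined_score, label = is_reference,
                           fp_target = 0.10, exclude = NULL) {
  if (fp_target <= 0 || fp_target >= 1) abort("`fp_target` must be in (0, 1)")
  out <- as_tibble(data)
  s <- dplyr::pull(dplyr::mutate(out, .s = {{ score }}), .data$.s)
  y <- dplyr::pull(dplyr::mutate(out, .y = {{ label }}), .data$.y)
  excl <- if (rlang::quo_is_null(rlang::enquo(exclude))) {
    rep(FALSE, nrow(out))
  } else {
    dplyr::pull(dplyr::mutate(out, .e = {{ exclude }}), .data$.e)
  }
  neg <- s[!y]
  if (length(neg) == 0) abort("no reference-negative proteins: threshold undefined")

  candidates <- sort(unique(s))
  ok <- vapply(candidates, function(t) mean(neg >= t) <= fp_target, logical(1))
  threshold <- if (any(ok)) candidates[which(ok)[1]] else Inf

  out$predicted_endosomal <- s >= threshold & !excl
  out$called_or_reference <- out$predicted_endosomal | y
  out$threshold_used <- threshold
  out$fp_target <- fp_target
  class(out) <- c("endo_call", class(out))
  out
}

#' @exportS3Method generics::glance
glance.endo_call <- function(x, ...) {
  y <- if ("is_reference" %in% names(x)) x$is_reference else NULL
  realized_fp <- if (!is.null(y)) mean(x$predicted_endosomal[!y]) else NA_real_
  recall <- if (!is.null(y) && any(y)) mean(x$predicted_endosomal[y]) else NA_real_
  tibble(
    n = nrow(x),
    n_predicted = sum(x$predicted_endosomal),
    threshold = x$threshold_used[1],
    fp_target = x$fp_target[1],
    realized_fp_rate = realized_fp,
    reference_recall = recall
  )
}
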