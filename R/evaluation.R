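#' Confusion counts for a two-class prediction
#'
#' Counts with class 1 (cancerous) as the positive class: TP and FN over
#' the cancerous samples, TN and FP over the normal ones.
#'
#' @param truth,predicted Equal-length label vectors with values in
#'   `{1, 2}`.
#' @return A one-row tibble with columns `tp`, `fn`, `tn`, `fp`.
#' @export
#' @examples
#' confusion(c(1, 1, 2, 2), c(1, 2, 2, 2))
confusion <- function(truth, predicted) {
  if (length(truth) == 0) abort_input("empty label vectors")
  if (length(truth) != length(predicted)) {
    abort_input("`truth` and `predicted` differ in length")
  }
  if (!all(c(truth, predicted) %in% c(1L, 2L))) {
    abort_input("labels must be drawn from {1, 2}")
  }
  tibble::tibble(
    tp = sum(truth == 1 & predicted == 1),
    fn = sum(truth == 1 & predicted == 2),
    tn = sum(truth == 2 & predicted == 2),
    fp = sum(truth == 2 & predicted == 1)
  )
}

#' Sensitivity, specificity and misclassified count
#'
#' `sensitivity = 100 * TP / (TP + FN)` over the cancerous samples,
#' `specificity = 100 * TN / (TN + FP)` over the normal ones, and
#' `misclassified = FN + FP`. Values are kept at full precision; the print
#' method rounds to one decimal place.
#'
#' @param counts A confusion-count row from [confusion()].
#' @return A one-row tibble with `sensitivity`, `specificity` (percent) and
#'   `misclassified`.
#' @export
#' @examples
#' diagnostic_metrics(tibble::tibble(tp = 22, fn = 4, tn = 36, fp = 0))
diagnostic_metrics <- function(counts) {
  if (counts$tp + counts$fn == 0 || counts$tn + counts$fp == 0) {
    abort_input("both classes must be present to compute sensitivity and specificity")
  }
  tibble::tibble(
    sensitivity = 100 * counts$tp / (counts$tp + counts$fn),
    specificity = 100 * counts$tn / (counts$tn + counts$fp),
    misclassified = counts$fn + counts$fp
  )
}

#' Evaluate a classifier on named subsets
#'
#' Predicts each subset with the fitted model and reports per-subset
#' confusion counts, sensitivity, specificity and misclassified count, plus
#' a model-size annotation (number of selected variables for SPA-LDA,
#' number of latent variables for PLS-DA).
#'
#' @param model A fitted `spa_lda` or `pls_da` model.
#' @param subsets Named list of spectra tibbles (e.g. the output of
#'   [split_subsets()]).
#' @return An `evaluation_report` tibble: one row per subset with columns
#'   `classifier`, `subset`, `tp`, `fn`, `tn`, `fp`, `sensitivity`,
#'   `specificity`, `misclassified`, `model_size`.
#' @export
evaluate_classifier <- function(model, subsets) {
  classifier <- class(model)[1]
  size <- switch(classifier,
    spa_lda = sprintf("%d variables", length(model$selected)),
    pls_da = sprintf("%d LVs x %d channels", model$n_lv,
                     length(model$wavenumbers)),
    sprintf("%s model", classifier))
  out <- purrr::imap_dfr(subsets, function(sp, nm) {
    sp <- as_spectra(sp)
    pred <- suppressMessages(predict(model, sp))
    cm <- confusion(spectra_labels(sp), pred)
    dplyr::bind_cols(
      tibble::tibble(classifier = classifier, subset = nm),
      cm, diagnostic_metrics(cm),
      tibble::tibble(model_size = size))
  })
  class(out) <- unique(c("evaluation_report", class(out)))
  out
}

#' @export
print.evaluation_report <- function(x, ...) {
  shown <- dplyr::mutate(tibble::as_tibble(x),
                         sensitivity = round(.data$sensitivity, 1),
                         specificity = round(.data$specificity, 1))
  print(shown)
  invisible(x)
}

#' Compare two evaluation reports subset by subset
#'
#' Joins two reports on subset name and tabulates their sensitivities and
#' specificities side by side with deltas (first minus second) and each
#' model's size, the summary used to weigh a parsimonious variable-selection
#' model against a full-spectrum baseline.
#'
#' @param report_a,report_b `evaluation_report` tibbles over identical
#'   subsets.
#' @return A tibble, one row per subset.
#' @export
compare_reports <- function(report_a, report_b) {
  if (!setequal(report_a$subset, report_b$subset)) {
    abort_input("reports do not cover identical subsets")
  }
  a <- tibble::as_tibble(report_a)
  b <- tibble::as_tibble(report_b)
  dplyr::inner_join(a, b, by = "subset", suffix = c("_a", "_b")) |>
    dplyr::transmute(
      subset = .data$subset,
      classifier_a = .data$classifier_a,
      classifier_b = .data$classifier_b,
      sensitivity_a = .data$sensitivity_a,
      sensitivity_b = .data$sensitivity_b,
      delta_sensitivity = .data$sensitivity_a - .data$sensitivity_b,
      specificity_a = .data$specificity_a,
      specificity_b = .data$specificity_b,
      delta_specificity = .data$specificity_a - .data$specificity_b,
      model_size_a = .data$model_size_a,
      model_size_b = .data$model_size_b
    )
}
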