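#' Confusion counts for binary predictions
#'
#' @param labels,predictions Equal-length 0/1 vectors.
#' @return A `tepr_confusion` list with fields `tp`, `fp`, `tn`, `fn`, `n`.
#' @export
confusion <- function(labels, predictions) {
  if (length(labels) != length(predictions)) {
    abort("`labels` and `predictions` must have equal length")
  }
  if (any(!labels %in% c(0, 1)) || any(!predictions %in% c(0, 1))) {
    abort("`labels` and `predictions` must be binary (0/1)")
  }
  structure(list(
    tp = sum(labels == 1 & predictions == 1),
    fp = sum(labels == 0 & predictions == 1),
    tn = sum(labels == 0 & predictions == 0),
    fn = sum(labels == 1 & predictions == 0),
    n = length(labels)
  ), class = "tepr_confusion")
}

#' Matthews correlation coefficient
#'
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, the primary metric
#' of the pipeline: a correlation-like score on the confusion table that is
#' robust to class imbalance and equals the Pearson (phi) correlation of the
#' two binary vectors. Any zero factor in the denominator yields 0 by
#' convention.
#'
#' @param c A `tepr_confusion` from [confusion()].
#' @return A value in `[-1, 1]`.
#' @export
mcc_value <- function(c) {
  # doubles avoid integer overflow on large counts
  den <- as.numeric(c$tp + c$fp) * as.numeric(c$tp + c$fn) *
    as.numeric(c$tn + c$fp) * as.numeric(c$tn + c$fn)
  if (den == 0) return(0)
  (as.numeric(c$tp) * c$tn - as.numeric(c$fp) * c$fn) / sqrt(den)
}

#' Metric report: accuracy, F1, MCC, specificity, sensitivity
#'
#' Computes the full metric suite from labels and predictions (or a
#' prediction tibble from [predict.tepr_model()]). Empty denominators yield
#' 0.
#'
#' @param labels 0/1 vector, or a prediction tibble with `label` and `pred`
#'   columns (then `predictions` is ignored).
#' @param predictions 0/1 vector.
#' @param model_name Optional model name stored in the report.
#' @return A one-row tibble: `model`, `acc`, `f1`, `mcc`, `specificity`,
#'   `sensitivity`, `n`.
#' @export
metric_report <- function(labels, predictions = NULL, model_name = NA_character_) {
  if (is.data.frame(labels)) {
    predictions <- labels$pred
    labels <- labels$label
  }
  c <- confusion(labels, predictions)
  div <- function(num, den) if (den == 0) 0 else num / den
  tibble(
    model = model_name,
    acc = div(c$tp + c$tn, c$n),
    f1 = div(2 * c$tp, 2 * c$tp + c$fp + c$fn),
    mcc = mcc_value(c),
    specificity = div(c$tn, c$tn + c$fp),
    sensitivity = div(c$tp, c$tp + c$fn),
    n = c$n
  )
}

#' Pearson correlation between two models' predictions
#'
#' On binary prediction vectors this is the phi coefficient; self-comparison
#' gives exactly 1. A zero-variance vector makes the correlation undefined
#' and returns `NA` with a message.
#'
#' @param preds_a,preds_b Equal-length prediction vectors (binary by
#'   default; probabilities are accepted).
#' @return A correlation in `[-1, 1]`, or `NA`.
#' @export
pearson_between <- function(preds_a, preds_b) {
  if (length(preds_a) != length(preds_b)) abort("prediction vectors must have equal length")
  if (identical(preds_a, preds_b)) return(1)
  if (sd(preds_a) == 0 || sd(preds_b) == 0) {
    inform("pearson_between: zero-variance prediction vector; correlation undefined")
    return(NA_real_)
  }
  cor(preds_a, preds_b)
}

#' McNemar test between two models on the same samples
#'
#' Builds the 2x2 discordance table of per-sample correctness of the two
#' models and tests the symmetry of the discordant cells. With fewer than 25
#' discordant pairs an exact two-sided binomial test is used
#' ([stats::binom.test()]); otherwise the continuity-corrected chi-square
#' form ([stats::mcnemar.test()]). Identical predictions give p = 1.
#'
#' @param preds_a,preds_b Binary prediction vectors of the two models.
#' @param labels True 0/1 labels.
#' @return The p-value, with attribute `"method"`.
#' @export
mcnemar_between <- function(preds_a, preds_b, labels) {
  if (length(preds_a) != length(preds_b) || length(preds_a) != length(labels)) {
    abort("`preds_a`, `preds_b` and `labels` must have equal length")
  }
  ok_a <- preds_a == labels
  ok_b <- preds_b == labels
  b <- sum(ok_a & !ok_b)  # A right, B wrong
  c <- sum(!ok_a & ok_b)
  if (b + c == 0) return(structure(1, method = "degenerate"))
  if (b + c < 25) {
    p <- stats::binom.test(b, b + c, 0.5)$p.value
    structure(unname(p), method = "exact_binomial")
  } else {
    tab <- matrix(c(sum(ok_a & ok_b), b, c, sum(!ok_a & !ok_b)), 2, 2, byrow = TRUE)
    structure(unname(stats::mcnemar.test(tab, correct = TRUE)$p.value),
              method = "chisq_corrected")
  }
}

#' Compare models against a reference model
#'
#' For a set of prediction tibbles evaluated on the same samples, computes
#' per-model metrics plus the Pearson correlation and McNemar p-value of each
#' model's predictions against a reference (typically the generalized
#' all-task model; self-comparison gives 1 for both).
#'
#' @param predictions Named list of prediction tibbles
#'   ([predict.tepr_model()] output) over the same windows.
#' @param reference Name of the reference model in `predictions`.
#' @return A tibble with one row per model.
#' @export
compare_models <- function(predictions, reference = "All-task") {
  if (!reference %in% names(predictions)) {
    abort(sprintf("reference model '%s' not found", reference))
  }
  ref <- predictions[[reference]]
  purrr::imap(predictions, function(p, nm) {
    common <- dplyr::inner_join(p, ref, by = "window_id", suffix = c("", ".ref"))
    rep <- metric_report(p$label, p$pred, model_name = nm)
    rep$pearson <- pearson_between(common$pred, common$pred.ref)
    rep$mcnemar_p <- as.numeric(mcnemar_between(common$pred, common$pred.ref, common$label))
    rep
  }) |> purrr::list_rbind()
}
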