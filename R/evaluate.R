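#' Confusion counts at a probability threshold
#'
#' Tumor is the positive class throughout: a patch with
#' `p >= threshold` is predicted tumor (ties predicted positive — the
#' threshold is inclusive).
#'
#' @param probabilities Predicted tumor probabilities.
#' @param labels True labels; `"tumor"`/`"non_tumor"` strings, logicals, or
#'   0/1 numerics (1 = tumor).
#' @param threshold Decision threshold (default 0.5).
#' @return A `confusion_counts` list with fields `TP`, `FP`, `TN`, `FN`
#'   summing to `length(probabilities)`.
#' @export
confusion_counts <- function(probabilities, labels, threshold = 0.5) {
  if (!length(probabilities)) abort("Cannot tally an empty prediction vector.")
  truth <- as_tumor_logical(labels)
  if (length(truth) != length(probabilities)) {
    abort("`probabilities` and `labels` must have equal length.")
  }
  pred <- probabilities >= threshold
  structure(list(TP = sum(pred & truth), FP = sum(pred & !truth),
                 TN = sum(!pred & !truth), FN = sum(!pred & truth)),
            class = "confusion_counts")
}

as_tumor_logical <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) abort("Numeric labels must be 0/1 (1 = tumor).")
    return(labels == 1)
  }
  if (!all(labels %in% c("tumor", "non_tumor"))) {
    abort("Labels must be 'tumor' or 'non_tumor'.")
  }
  labels == "tumor"
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' Sensitivity = TP/(TP+FN) (tumor detection rate), specificity =
#' TN/(TN+FP), accuracy = (TN+TP)/total. A zero denominator yields `NA`
#' (a tumor-only test set has no defined specificity), never an error.
#'
#' @param counts A [confusion_counts()] object.
#' @return One-row tibble with `sensitivity`, `specificity`, `accuracy`
#'   as proportions in \[0, 1\] (or `NA`).
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  with(counts, tibble(
    sensitivity = safe_div(TP, TP + FN),
    specificity = safe_div(TN, TN + FP),
    accuracy = safe_div(TN + TP, TN + TP + FP + FN)))
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney probability that a randomly chosen tumor
#' patch outscores a randomly chosen non-tumor patch, ties counted one
#' half (midrank formulation) — threshold-free and invariant under any
#' strictly monotone transform of the scores.
#'
#' @inheritParams confusion_counts
#' @return AUC in \[0, 1\], or `NA` when only one class is present.
#' @export
roc_auc <- function(probabilities, labels) {
  truth <- as_tumor_logical(labels)
  n_pos <- sum(truth); n_neg <- sum(!truth)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(probabilities)  # midranks handle ties
  (sum(r[truth]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Per-patient classification report
#'
#' Aggregates patch-level predictions into the per-patient rows of a
#' clinical results table: AUC, accuracy, sensitivity and specificity (as
#' percentages) and the patch count. Patients whose evaluated patches are
#' single-class get `NA` where the quantity is undefined (e.g. specificity
#' and AUC for tumor-only patients).
#'
#' Quality-control exclusions are applied here, and only here: when a
#' manifest is supplied, patches from cubes flagged `excluded` are dropped
#' from the evaluation — the classifier is not retrained.
#'
#' @param predictions Tibble from [predict_patches()] (needs columns
#'   `patient_id`, `roi_id`, `label`, `p_tumor`).
#' @param manifest Optional `hsi_manifest` carrying exclusion flags.
#' @param threshold Decision threshold for the confusion counts.
#' @return A `metrics_report` tibble: one row per patient with `auc`,
#'   `accuracy`, `sensitivity`, `specificity` (percent, unrounded) and
#'   `n_patches`.
#' @export
evaluate_patients <- function(predictions, manifest = NULL, threshold = 0.5) {
  df <- as_tibble(predictions)
  if (!is.null(manifest)) {
    excl <- manifest[manifest$excluded, c("patient_id", "roi_id")]
    df <- dplyr::anti_join(df, excl, by = c("patient_id", "roi_id"))
  }
  if (!nrow(df)) abort("No patches left to evaluate.")
  out <- df |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_modify(function(d, key) {
      cc <- confusion_counts(d$p_tumor, d$label, threshold)
      m <- classification_metrics(cc)
      tibble(auc = roc_auc(d$p_tumor, d$label),
             accuracy = 100 * m$accuracy,
             sensitivity = 100 * m$sensitivity,
             specificity = 100 * m$specificity,
             n_patches = nrow(d))
    }) |>
    dplyr::ungroup()
  class(out) <- c("metrics_report", class(tibble()))
  out
}

#' Column-wise aggregate of a per-patient report
#'
#' Mean and sample standard deviation over the non-`NA` per-patient values
#' of each metric — the unweighted per-patient average used in the
#' summary rows of clinical results tables. Values are aggregated
#' unrounded; display rounding (percentages to integers, AUC to two
#' decimals, halves away from zero) happens last, in the `display`
#' columns.
#'
#' @param report A `metrics_report` from [evaluate_patients()], or any
#'   tibble with numeric metric columns.
#' @param columns Metric columns to aggregate.
#' @return Tibble with one row per metric: `metric`, `mean`, `sd`, `n`
#'   (contributing patients), `display_mean`, `display_sd`.
#' @export
aggregate_metrics <- function(report,
                              columns = intersect(c("auc", "accuracy", "sensitivity", "specificity"),
                                                  names(report))) {
  rows <- lapply(columns, function(col) {
    v <- report[[col]]
    v <- v[!is.na(v)]
    if (!length(v)) {
      return(tibble(metric = col, mean = NA_real_, sd = NA_real_, n = 0L,
                    display_mean = NA_real_, display_sd = NA_real_))
    }
    digits <- if (col == "auc") 2L else 0L
    tibble(metric = col, mean = mean(v),
           sd = if (length(v) > 1L) sd(v) else 0,
           n = length(v),
           display_mean = round_half_up(mean(v), digits),
           display_sd = round_half_up(if (length(v) > 1L) sd(v) else 0, digits))
  })
  dplyr::bind_rows(rows)
}

#' @method tidy metrics_report
#' @export
tidy.metrics_report <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), cols = c("auc", "accuracy", "sensitivity", "specificity"),
                      names_to = "metric", values_to = "value")
}

#' @method glance metrics_report
#' @export
glance.metrics_report <- function(x, ...) {
  agg <- aggregate_metrics(x)
  out <- tidyr::pivot_wider(agg[, c("metric", "mean")], names_from = "metric",
                            values_from = "mean")
  dplyr::mutate(out, n_patients = nrow(x))
}

#' Per-patient metrics plot
#' @param object A `metrics_report`.
#' @param ... Unused.
#' @return A ggplot faceted by metric.
#' @method autoplot metrics_report
#' @export
autoplot.metrics_report <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$patient_id, y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
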