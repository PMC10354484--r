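#' Threshold a pregnancy probability into a classification
#'
#' A record is classified pregnant when its probability is greater than
#' *or equal to* the threshold (the inclusive rule that reproduces the
#' published classifications).
#'
#' @param prob Probabilities in `[0, 1]` (vectorized; `NA` passes
#'   through).
#' @param threshold Classification threshold.
#' @return Logical vector, `TRUE` = classified pregnant.
#' @export
classify_pregnant <- function(prob, threshold = 0.75) {
  if (any(prob < 0 | prob > 1, na.rm = TRUE)) {
    stop("probabilities must lie in [0, 1]")
  }
  prob >= threshold
}

#' Confusion counts and performance rates against known status
#'
#' Evaluates classifications against known reproductive status: presumed
#' pregnant females (PF) are the positives and presumed non-pregnant
#' females (LF and JF) the negatives; MF records (unknown truth) must be
#' excluded by the caller or are dropped here when a `group` vector is
#' given. Reported rates are accuracy, misclassification, true/false
#' positive and negative rates, as unrounded percentages plus
#' whole-percent values rounded half away from zero.
#'
#' @param classified Logical vector from [classify_pregnant()].
#' @param truth Logical vector of true pregnancy status, or a `group`
#'   vector (`"PF"`/`"LF"`/`"JF"`/`"MF"`) from which truth is derived
#'   (PF = positive, LF and JF = negative, MF dropped).
#' @return A list with `counts` (tibble: tp, tn, fp, fn, total) and
#'   `metrics` (tibble: metric, value_pct, rounded_pct).
#' @examples
#' confusion_metrics(c(TRUE, TRUE, FALSE, TRUE), c("PF", "PF", "JF", "LF"))
#' @export
confusion_metrics <- function(classified, truth) {
  if (is.character(truth) || is.factor(truth)) {
    truth <- as.character(truth)
    keep <- truth %in% c("PF", "LF", "JF")
    classified <- classified[keep]
    truth <- truth[keep] == "PF"
  }
  keep <- !is.na(classified) & !is.na(truth)
  classified <- classified[keep]
  truth <- truth[keep]
  if (length(truth) == 0) stop("no records of known status to evaluate")

  tp <- sum(classified & truth)
  tn <- sum(!classified & !truth)
  fp <- sum(classified & !truth)
  fn <- sum(!classified & truth)
  total <- tp + tn + fp + fn

  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  metrics <- tibble::tibble(
    metric = c("accuracy", "misclassification", "tpr", "fnr", "tnr", "fpr"),
    value_pct = c(pct(tp + tn, total), pct(fn + fp, total),
                  pct(tp, tp + fn), pct(fn, tp + fn),
                  pct(tn, tn + fp), pct(fp, tn + fp))
  )
  metrics$rounded_pct <- round_half_away(metrics$value_pct)

  list(counts = tibble::tibble(tp = tp, tn = tn, fp = fp, fn = fn,
                               total = total),
       metrics = metrics)
}

# round half away from zero (74.5 -> 75), matching reported whole percents
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Model performance table across bootstrap runs
#'
#' Applies the classification threshold to each model's per-record point
#' probabilities and tabulates the six confusion-matrix rates against
#' known reproductive status, one column per model.
#'
#' @param boots A named list of [boot_pregnancy()] objects (or a single
#'   one).
#' @param threshold Classification threshold.
#' @return A tibble with one row per metric and one column per model,
#'   plus a `counts` attribute holding the per-model confusion counts.
#' @export
performance_table <- function(boots, threshold = 0.75) {
  if (inherits(boots, "preg_boot")) boots <- list(boots)
  if (is.null(names(boots)) || any(!nzchar(names(boots)))) {
    names(boots) <- vapply(boots, function(b) b$model, character(1))
  }
  per_model <- lapply(boots, function(b) {
    s <- b$summary
    confusion_metrics(classify_pregnant(s$point, threshold), s$group)
  })
  out <- per_model[[1]]$metrics[, "metric"]
  for (nm in names(per_model)) {
    out[[nm]] <- per_model[[nm]]$metrics$rounded_pct
  }
  attr(out, "counts") <- purrr::map_dfr(per_model, ~.x$counts,
                                        .id = "model")
  out
}
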