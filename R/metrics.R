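#' Tally a binary confusion matrix
#'
#' @param truth,predicted Equal-length label vectors over at most two
#'   classes.
#' @param positive_class The label counted as positive.
#' @return A `confusion_matrix`: list with integer counts `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
confusion <- function(truth, predicted, positive_class = "positive") {
  if (length(truth) != length(predicted)) abort("truth and predicted differ in length")
  if (length(truth) < 1) abort("at least one prediction required")
  classes <- unique(c(truth, predicted))
  if (length(classes) > 2) abort("confusion() handles binary labels only")
  tp <- sum(truth == positive_class & predicted == positive_class)
  fn <- sum(truth == positive_class & predicted != positive_class)
  fp <- sum(truth != positive_class & predicted == positive_class)
  tn <- sum(truth != positive_class & predicted != positive_class)
  confusion_matrix(tp, fp, tn, fn)
}

#' @rdname confusion
#' @param tp,fp,tn,fn Nonnegative counts.
#' @export
confusion_matrix <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || sum(counts) < 1) {
    abort("counts must be nonnegative with a positive total")
  }
  structure(as.list(setNames(as.integer(counts), names(counts))),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion> TP=%d FP=%d TN=%d FN=%d\n", x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Scores derived from a confusion matrix
#'
#' `accuracy = (TP + TN) / total`, `sensitivity = TP / (TP + FN)`,
#' `specificity = TN / (TN + FP)` and `f_score` the harmonic mean of
#' precision `TP / (TP + FP)` and sensitivity (the F1 statistic). A score
#' whose denominator is zero is undefined and returned as `NA` rather
#' than silently zero; `f_score` is 0 when `TP = 0` but errors were made,
#' and `NA` only when there are neither true positives nor any
#' positive-labelled rows on either side.
#'
#' @param cm A `confusion_matrix`.
#' @return A single numeric score, or `NA` when undefined.
#' @export
accuracy <- function(cm) (cm$tp + cm$tn) / (cm$tp + cm$fp + cm$tn + cm$fn)

#' @rdname accuracy
#' @export
sensitivity <- function(cm) {
  if (cm$tp + cm$fn == 0) return(NA_real_)
  cm$tp / (cm$tp + cm$fn)
}

#' @rdname accuracy
#' @export
specificity <- function(cm) {
  if (cm$tn + cm$fp == 0) return(NA_real_)
  cm$tn / (cm$tn + cm$fp)
}

#' @rdname accuracy
#' @export
f_score <- function(cm) {
  if (cm$tp == 0) {
    if (cm$fp + cm$fn == 0) return(NA_real_)
    return(0)
  }
  precision <- cm$tp / (cm$tp + cm$fp)
  recall <- cm$tp / (cm$tp + cm$fn)
  2 * precision * recall / (precision + recall)
}

#' Aggregate confusion matrices over repetitions
#'
#' Computes per-repetition scores and their arithmetic means and maxima.
#' Undefined (`NA`) scores are excluded from the means, with the number
#' of exclusions recorded per score.
#'
#' @param matrices List of `confusion_matrix` objects (one per
#'   repetition).
#' @param spec,k,metric Optional provenance recorded on the result.
#' @return An `eeg_eval` object: the per-repetition score table plus the
#'   aggregate statistics; see [tidy()] and [glance()].
#' @export
summarize_evaluations <- function(matrices, spec = NULL, k = NULL,
                                  metric = NULL) {
  if (length(matrices) == 0) abort("no confusion matrices to summarise")
  per_rep <- dplyr::bind_rows(lapply(seq_along(matrices), function(i) {
    cm <- matrices[[i]]
    tibble::tibble(
      repetition = i, tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn,
      accuracy = accuracy(cm), sensitivity = sensitivity(cm),
      specificity = specificity(cm), f_score = f_score(cm)
    )
  }))
  mean_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  max_na <- function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
  structure(
    list(
      scores = per_rep,
      mean_accuracy = mean_na(per_rep$accuracy),
      max_accuracy = max_na(per_rep$accuracy),
      mean_f_score = mean_na(per_rep$f_score),
      max_f_score = max_na(per_rep$f_score),
      mean_sensitivity = mean_na(per_rep$sensitivity),
      mean_specificity = mean_na(per_rep$specificity),
      n_undefined = vapply(
        per_rep[c("accuracy", "sensitivity", "specificity", "f_score")],
        function(x) sum(is.na(x)), integer(1)
      ),
      spec = spec, k = k, metric = metric
    ),
    class = "eeg_eval"
  )
}

#' @export
print.eeg_eval <- function(x, ...) {
  cat(sprintf(
    "<eeg_eval> %d repetitions  mean acc %.3f (max %.3f)  mean F %.3f (max %.3f)\n",
    nrow(x$scores), x$mean_accuracy, x$max_accuracy,
    x$mean_f_score, x$max_f_score
  ))
  invisible(x)
}

#' Tidy per-repetition scores of an evaluation
#'
#' @param x An `eeg_eval`.
#' @param ... Unused.
#' @return Tibble with one row per repetition: counts and scores.
#' @export
tidy.eeg_eval <- function(x, ...) x$scores

#' One-row summary of an evaluation
#'
#' @param x An `eeg_eval`.
#' @param ... Unused.
#' @return One-row tibble of the aggregate statistics.
#' @export
glance.eeg_eval <- function(x, ...) {
  tibble::tibble(
    n_reps = nrow(x$scores),
    mean_accuracy = x$mean_accuracy, max_accuracy = x$max_accuracy,
    mean_f_score = x$mean_f_score, max_f_score = x$max_f_score,
    mean_sensitivity = x$mean_sensitivity,
    mean_specificity = x$mean_specificity
  )
}
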