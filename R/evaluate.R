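# ---------------------------------------------------------------------------
# Symmetric direct/reverse evaluation with bias categorization
# ---------------------------------------------------------------------------

#' Partition a dataset by mutation direction
#'
#' @param df Mutation dataset; every record needs a direction flag.
#' @return List with `direct` and `reverse` data.frames (disjoint,
#'   exhaustive).
#' @export
split_direct_reverse <- function(df) {
  if (any(is.na(df$direction)) ||
      !all(df$direction %in% c("direct", "reverse")))
    stop("record(s) without a valid direction flag")
  list(direct = df[df$direction == "direct", , drop = FALSE],
       reverse = df[df$direction == "reverse", , drop = FALSE])
}

#' Direction-bias category marks
#'
#' Categorizes the gap between direct- and reverse-mutation accuracy by
#' the standard thresholds: no mark for a difference up to 0.05, one dot
#' for 0.05 < d <= 0.1, two dots for 0.1 < d <= 0.2, three dots above
#' 0.2. The mark uses the absolute difference (bias is flagged in either
#' direction); the signed difference reverse minus direct is also
#' returned.
#'
#' @param accuracy_direct,accuracy_reverse Accuracies in [0, 1].
#' @return List: `mark` ("none", one, two or three bullet characters),
#'   `difference` (absolute), `signed_difference` (reverse - direct).
#' @export
bias_category <- function(accuracy_direct, accuracy_reverse) {
  stopifnot(accuracy_direct >= 0, accuracy_direct <= 1,
            accuracy_reverse >= 0, accuracy_reverse <= 1)
  d <- abs(accuracy_direct - accuracy_reverse)
  dr <- round(d, 9)  # keep 0.9 - 0.7 on the <= 0.2 side of its threshold
  mark <- if (dr <= 0.05) "none"
  else if (dr <= 0.1) "●"
  else if (dr <= 0.2) "●●"
  else "●●●"
  list(mark = mark, difference = d,
       signed_difference = accuracy_reverse - accuracy_direct)
}

#' Classification metrics at threshold 0.5
#'
#' Accuracy, precision and recall for the 0.5-thresholded calls and AUC
#' by the rank (Mann-Whitney) statistic with midrank tie handling.
#' Single-class inputs yield an undefined (NA) AUC rather than a
#' placeholder 0.5.
#'
#' @param labels 0/1 vector.
#' @param probabilities Predicted probabilities in [0, 1].
#' @return List of class `stabgvp_eval`: accuracy, precision, recall,
#'   auc, n.
#' @export
compute_metrics <- function(labels, probabilities) {
  stopifnot(length(labels) == length(probabilities),
            length(labels) > 0,
            all(probabilities >= 0 & probabilities <= 1))
  labels <- as.integer(labels)
  pred <- as.integer(probabilities > 0.5)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  auc <- if (n1 == 0 || n0 == 0) NA_real_ else {
    r <- rank(probabilities)  # midranks on ties
    (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  out <- list(accuracy = mean(pred == labels),
              precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
              recall = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
              auc = auc, n = length(labels))
  class(out) <- "stabgvp_eval"
  out
}

#' @export
print.stabgvp_eval <- function(x, ...) {
  cat(sprintf("n=%d accuracy=%.3f precision=%s recall=%s auc=%s\n",
              x$n, x$accuracy,
              ifelse(is.na(x$precision), "NA", sprintf("%.3f", x$precision)),
              ifelse(is.na(x$recall), "NA", sprintf("%.3f", x$recall)),
              ifelse(is.na(x$auc), "undefined", sprintf("%.3f", x$auc))))
  invisible(x)
}

#' Symmetric direct/reverse evaluation report
#'
#' Evaluates predictions separately on direct and reverse mutations,
#' averages the two accuracies, and attaches the bias mark. Input is a
#' prediction table: one row per record with its true label, predicted
#' probability and direction.
#'
#' @param predictions Data.frame with columns `record_id`, `label`,
#'   `probability`, `direction`.
#' @return List of class `stabgvp_report`: accuracy_direct,
#'   accuracy_reverse, accuracy_avg, overall precision/recall/auc,
#'   bias difference and mark, per-direction sample sizes.
#' @export
eval_report <- function(predictions) {
  need <- c("record_id", "label", "probability", "direction")
  miss <- setdiff(need, names(predictions))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  parts <- split_direct_reverse(predictions)
  md <- compute_metrics(parts$direct$label, parts$direct$probability)
  mr <- if (nrow(parts$reverse) > 0)
    compute_metrics(parts$reverse$label, parts$reverse$probability)
  else list(accuracy = NA_real_, n = 0L)
  overall <- compute_metrics(predictions$label, predictions$probability)
  bias <- if (is.na(mr$accuracy)) list(mark = "none", difference = NA_real_,
                                       signed_difference = NA_real_)
  else bias_category(md$accuracy, mr$accuracy)
  out <- list(accuracy_direct = md$accuracy,
              accuracy_reverse = mr$accuracy,
              accuracy_avg = mean(c(md$accuracy, mr$accuracy)),
              precision = overall$precision, recall = overall$recall,
              auc = overall$auc,
              bias_difference = bias$signed_difference,
              bias_abs_difference = bias$difference,
              bias_marks = bias$mark,
              n_direct = md$n, n_reverse = mr$n)
  class(out) <- "stabgvp_report"
  out
}

#' @export
print.stabgvp_report <- function(x, ...) {
  cat("Symmetric evaluation\n")
  cat(sprintf("  direct:  accuracy %.3f (n=%d)\n", x$accuracy_direct,
              x$n_direct))
  if (!is.na(x$accuracy_reverse))
    cat(sprintf("  reverse: accuracy %.3f (n=%d)\n", x$accuracy_reverse,
                x$n_reverse))
  cat(sprintf("  average accuracy %.3f  bias %s (|d|=%s)\n",
              x$accuracy_avg, x$bias_marks,
              ifelse(is.na(x$bias_abs_difference), "NA",
                     sprintf("%.3f", x$bias_abs_difference))))
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param report An `stabgvp_report`.
#' @param path Output .json path.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
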