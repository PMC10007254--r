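# Evaluation: confusion matrices, the binary triple (accuracy, sensitivity,
# specificity), Cohen's kappa, macro F1, and mean +/- sd aggregation over
# repeats. Undefined quantities (zero denominators, degenerate agreement)
# are reported as NA, never as 0.

#' Confusion matrix
#'
#' @param true_labels,predicted_labels equal-length label vectors.
#' @param label_order class order for rows (true) and columns (predicted);
#'   labels outside it are an error.
#' @return K x K integer count matrix, rows = true classes.
#' @export
confusion_matrix <- function(true_labels, predicted_labels, label_order) {
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors must have equal length")
  bad <- setdiff(unique(c(true_labels, predicted_labels)), label_order)
  if (length(bad))
    stop("label(s) outside label_order: ", paste(bad, collapse = ", "))
  K <- length(label_order)
  M <- matrix(0L, K, K, dimnames = list(true = label_order,
                                        predicted = label_order))
  for (i in seq_along(true_labels))
    M[true_labels[i], predicted_labels[i]] <-
      M[true_labels[i], predicted_labels[i]] + 1L
  M
}

#' Accuracy, sensitivity and specificity from a 2x2 confusion matrix
#'
#' `sensitivity = TP/(TP+FN)`, `specificity = TN/(TN+FP)`,
#' `accuracy = (TP+TN)/total`, with the positive class given by name. A zero
#' denominator yields `NA` for that metric.
#'
#' @param confusion 2x2 count matrix with dimnames (rows = true).
#' @param positive_label name of the positive class.
#' @return named numeric vector `accuracy`, `sensitivity`, `specificity`.
#' @export
binary_metrics <- function(confusion, positive_label) {
  if (!all(dim(confusion) == c(2, 2))) stop("confusion must be 2x2")
  labs <- rownames(confusion)
  if (!positive_label %in% labs) stop("unknown positive label")
  neg <- setdiff(labs, positive_label)
  tp <- confusion[positive_label, positive_label]
  fn <- confusion[positive_label, neg]
  tn <- confusion[neg, neg]
  fp <- confusion[neg, positive_label]
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  c(accuracy = safe(tp + tn, sum(confusion)),
    sensitivity = safe(tp, tp + fn),
    specificity = safe(tn, tn + fp))
}

#' Cohen's kappa
#'
#' `(p_o - p_e) / (1 - p_e)` with observed agreement `p_o` (the diagonal
#' fraction) and chance agreement `p_e = sum_k row_k * col_k / total^2`.
#' Degenerate tables with `p_e = 1` yield `NA`.
#'
#' @param confusion square count matrix.
#' @return kappa in `[-1, 1]`, or `NA`.
#' @export
cohen_kappa <- function(confusion) {
  if (nrow(confusion) != ncol(confusion)) stop("confusion must be square")
  n <- sum(confusion)
  if (n == 0) stop("empty confusion matrix")
  po <- sum(diag(confusion)) / n
  pe <- sum(rowSums(confusion) * colSums(confusion)) / n^2
  if (abs(1 - pe) < 1e-12) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Macro-averaged F1 score
#'
#' Unweighted mean over classes of `2PR/(P+R)`; classes with zero support
#' (no true instances) are excluded from the mean and reported in the
#' `"excluded"` attribute. A supported class that is never predicted
#' contributes F1 = 0.
#'
#' @param confusion square count matrix.
#' @return macro F1 in `[0, 1]` (attribute `excluded` lists zero-support
#'   classes).
#' @export
f1_macro <- function(confusion) {
  if (nrow(confusion) != ncol(confusion)) stop("confusion must be square")
  K <- nrow(confusion)
  f1 <- numeric(0)
  excluded <- character(0)
  labs <- rownames(confusion)
  if (is.null(labs)) labs <- as.character(seq_len(K))
  for (k in seq_len(K)) {
    support <- sum(confusion[k, ])
    if (support == 0) {
      excluded <- c(excluded, labs[k])
      next
    }
    tp <- confusion[k, k]
    prec_den <- sum(confusion[, k])
    p <- if (prec_den == 0) 0 else tp / prec_den
    r <- tp / support
    f1 <- c(f1, if (p + r == 0) 0 else 2 * p * r / (p + r))
  }
  structure(mean(f1), excluded = excluded)
}

#' Build an evaluation report from labels
#'
#' @param true_labels,predicted_labels equal-length label vectors.
#' @param label_order class order; for binary tasks the first positive
#'   metrics use `positive_label`.
#' @param positive_label positive class for sensitivity/specificity
#'   (binary tasks only).
#' @param repeat_index repeat identifier carried into aggregation.
#' @return an `eval_report`: confusion matrix plus accuracy, sensitivity,
#'   specificity (binary), Cohen's kappa and macro F1.
#' @export
eval_report <- function(true_labels, predicted_labels, label_order,
                        positive_label = NULL, repeat_index = 1L) {
  M <- confusion_matrix(true_labels, predicted_labels, label_order)
  acc <- sum(diag(M)) / sum(M)
  bm <- if (length(label_order) == 2 && !is.null(positive_label))
    binary_metrics(M, positive_label)
  else c(accuracy = acc, sensitivity = NA_real_, specificity = NA_real_)
  structure(list(confusion = M, accuracy = acc,
                 sensitivity = unname(bm["sensitivity"]),
                 specificity = unname(bm["specificity"]),
                 kappa = cohen_kappa(M), f1_macro = as.numeric(f1_macro(M)),
                 n_classes = length(label_order),
                 repeat_index = repeat_index),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d classes, n = %d\n", x$n_classes,
              sum(x$confusion)))
  cat(sprintf("  accuracy %.4f  kappa %.4f  macro-F1 %.4f\n",
              x$accuracy, x$kappa, x$f1_macro))
  if (!is.na(x$sensitivity))
    cat(sprintf("  sensitivity %.4f  specificity %.4f\n", x$sensitivity,
                x$specificity))
  print(x$confusion)
  invisible(x)
}

#' Aggregate evaluation reports over repeats
#'
#' Sample (n-1) standard deviation; a single report yields sd 0 with the
#' `single_report` flag set. Mixed class counts are an error.
#'
#' @param reports list of `eval_report` objects.
#' @return data.frame with `metric`, `mean`, `sd`, and a formatted
#'   `"mean (+/-sd)"` column.
#' @export
aggregate_reports <- function(reports) {
  stopifnot(length(reports) >= 1)
  K <- unique(vapply(reports, `[[`, numeric(1), "n_classes"))
  if (length(K) != 1) stop("reports have mixed class counts")
  metrics <- c("accuracy", "sensitivity", "specificity", "kappa", "f1_macro")
  single <- length(reports) == 1
  out <- do.call(rbind, lapply(metrics, function(m) {
    v <- vapply(reports, function(r) {
      x <- r[[m]]
      if (is.null(x)) NA_real_ else as.numeric(x)
    }, numeric(1))
    if (all(is.na(v))) return(NULL)
    mu <- mean(v)
    s <- if (single) 0 else sd(v)
    data.frame(metric = m, mean = mu, sd = s,
               formatted = sprintf("%.4f (±%.4f)", mu, s))
  }))
  attr(out, "single_report") <- single
  out
}

#' Plot a confusion matrix
#'
#' Renders counts (and row-normalized fractions) as a tile plot; class order
#' defaults to AASM display order when the labels allow it.
#'
#' @param report an `eval_report`.
#' @param order optional class display order.
#' @return a ggplot object.
#' @export
plot_confusion <- function(report, order = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_confusion requires ggplot2")
  M <- report$confusion
  if (is.null(order)) {
    aasm <- c("W", "REM", "N1", "N2", "N3")
    order <- if (setequal(rownames(M), aasm)) aasm else rownames(M)
  }
  df <- as.data.frame(as.table(M[order, order]))
  names(df) <- c("true", "predicted", "count")
  tot <- stats::ave(df$count, df$true, FUN = sum)
  df$frac <- ifelse(tot > 0, df$count / tot, 0)
  ggplot2::ggplot(df, ggplot2::aes(x = predicted, y = true, fill = frac)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%d\n%.2f", count, frac))) +
    ggplot2::scale_y_discrete(limits = rev(order)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "Predicted", y = "True", fill = "Row fraction")
}
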