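# Multi-class evaluation: confusion matrices, accuracy, macro-averaged
# precision/recall/F1, and top-k accuracy.

#' Confusion matrix
#'
#' Entry (i, j) counts items of true class i predicted as class j.
#'
#' @param true,predicted equal-length label vectors.
#' @param labels class set defining row/column order; defaults to the sorted
#'   union of the classes appearing in either vector. Supplying the full
#'   class list includes classes absent from both vectors in the matrix (and
#'   hence in macro averages).
#' @return An integer matrix of class `confusion_matrix` with the class
#'   labels as dimnames.
#' @examples
#' confusion_matrix(c(1, 1, 1, 2), c(1, 1, 2, 2))
#' @export
confusion_matrix <- function(true, predicted, labels = NULL) {
  if (length(true) == 0L) stop("label vectors are empty")
  if (length(true) != length(predicted))
    stop("`true` and `predicted` must have the same length")
  true <- as.character(true); predicted <- as.character(predicted)
  if (is.null(labels)) labels <- sort(unique(c(true, predicted)))
  if (!all(c(true, predicted) %in% labels))
    stop("labels appear in the data that are missing from `labels`")
  f1 <- factor(true, levels = labels)
  f2 <- factor(predicted, levels = labels)
  m <- unclass(table(f1, f2))
  dimnames(m) <- list(true = labels, predicted = labels)
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("Confusion matrix (%d classes, %d items)\n", nrow(x), sum(x)))
  print(unclass(x), ...)
  invisible(x)
}

#' Overall accuracy
#'
#' Fraction of predictions that are correct; equals the trace of the
#' confusion matrix over its total.
#'
#' @inheritParams confusion_matrix
#' @return A number in \[0, 1\].
#' @export
accuracy <- function(true, predicted) {
  if (length(true) == 0L) stop("label vectors are empty")
  if (length(true) != length(predicted))
    stop("`true` and `predicted` must have the same length")
  mean(as.character(true) == as.character(predicted))
}

#' Macro-averaged precision, recall and F1
#'
#' Per class i, precision = TP_i / (TP_i + FP_i), recall =
#' TP_i / (TP_i + FN_i), F1 their harmonic mean; the macro value is the
#' unweighted mean over classes. A per-class ratio with a zero denominator
#' (class never predicted, or never present) contributes 0 to the mean --
#' the documented convention for sparse test sets.
#'
#' @param cm a [confusion_matrix()].
#' @return A list with `macro_precision`, `macro_recall`, `macro_f1`, and a
#'   `per_class` data frame.
#' @examples
#' cm <- confusion_matrix(c(1, 1, 1, 2), c(1, 1, 2, 2))
#' macro_metrics(cm)$macro_precision  # (1 + 0.5) / 2
#' @export
macro_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (sum(cm) == 0L) stop("confusion matrix is empty")
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  prec <- safe_div(tp, tp + fp)
  rec <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * prec * rec, prec + rec)
  list(macro_precision = mean(prec),
       macro_recall = mean(rec),
       macro_f1 = mean(f1),
       per_class = data.frame(class = rownames(cm), precision = prec,
                              recall = rec, f1 = f1, row.names = NULL))
}

#' Top-k accuracy
#'
#' Fraction of items whose true class appears among the first k entries of
#' the ranked prediction list. Top-1 equals [accuracy()] on the top-ranked
#' calls; top-k is non-decreasing in k and reaches 1 at k = number of
#' classes.
#'
#' @param true true label vector.
#' @param ranked a character matrix (rows = items, columns = rank order, as
#'   returned by `predict(fit, type = "rank")`) or a list of ranked label
#'   vectors.
#' @param k_values the k values to evaluate.
#' @return Named numeric vector, one entry per k.
#' @export
topk_accuracy <- function(true, ranked, k_values = c(1, 5, 10, 15, 20)) {
  if (is.list(ranked)) {
    nr <- max(lengths(ranked))
    ranked <- t(vapply(ranked, function(r) c(r, rep(NA_character_,
                                                    nr - length(r))),
                       character(nr)))
  }
  if (length(true) == 0L || nrow(ranked) == 0L)
    stop("no predictions to score")
  if (length(true) != nrow(ranked))
    stop("`true` must have one entry per ranked prediction row")
  true <- as.character(true)
  out <- vapply(k_values, function(k) {
    kk <- min(k, ncol(ranked))
    mean(vapply(seq_along(true), function(i)
      true[i] %in% ranked[i, seq_len(kk)], logical(1)))
  }, numeric(1))
  stats::setNames(out, paste0("top", k_values))
}

#' Full metric report for a set of ranked predictions
#'
#' Convenience wrapper computing accuracy, macro metrics and top-k accuracy
#' in one pass; the shape consumed by the command-line `evaluate` step.
#'
#' @inheritParams topk_accuracy
#' @param labels optional full class list for the confusion matrix.
#' @return A list with `accuracy`, `macro_precision`, `macro_recall`,
#'   `macro_f1`, `top_k`, and the `confusion` matrix.
#' @export
metric_report <- function(true, ranked, k_values = c(1, 5, 10, 15, 20),
                          labels = NULL) {
  if (is.list(ranked)) ranked <- do.call(rbind, ranked)
  top1 <- ranked[, 1]
  cm <- confusion_matrix(true, top1, labels = labels)
  mm <- macro_metrics(cm)
  list(accuracy = accuracy(true, top1),
       macro_precision = mm$macro_precision,
       macro_recall = mm$macro_recall,
       macro_f1 = mm$macro_f1,
       top_k = topk_accuracy(true, ranked, k_values),
       confusion = cm)
}
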