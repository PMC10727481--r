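#' Confusion matrix
#'
#' Standard k-by-k contingency table of true versus predicted labels (rows =
#' truth, columns = predictions). Predictions carrying a label never seen in
#' the truth are an error.
#'
#' @param truth,predicted Label vectors of equal length.
#' @return A `confusion_matrix` (a table, truth in rows).
#' @export
#' @examples
#' confusion(c("a", "a", "b"), c("a", "b", "b"))
confusion <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop("'truth' and 'predicted' must have equal lengths", call. = FALSE)
  }
  lev <- if (is.factor(truth)) levels(truth) else sort(unique(as.character(truth)))
  bad <- setdiff(unique(as.character(predicted)), lev)
  if (length(bad)) {
    stop("prediction label(s) not present in truth: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  cm <- table(truth = factor(truth, levels = lev),
              predicted = factor(predicted, levels = lev))
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

cm_counts <- function(cm) {
  cm <- unclass(cm)
  tp <- diag(cm)
  data.frame(class = rownames(cm),
             tp = as.numeric(tp),
             fp = as.numeric(colSums(cm) - tp),
             fn = as.numeric(rowSums(cm) - tp),
             stringsAsFactors = FALSE)
}

#' Per-class precision, recall and F1
#'
#' For each class c with true positives TP, false positives FP and false
#' negatives FN:
#' \deqn{P = TP / (TP + FP), \quad R = TP / (TP + FN), \quad
#'       F_1 = 2 TP / (2 TP + FP + FN).}
#' When TP = 0 but FP + FN > 0 all three are 0; a class absent from both
#' truth and predictions has undefined metrics, reported as `NaN` with a
#' warning.
#'
#' @param cm A [confusion()] matrix.
#' @return Data frame `class, tp, fp, fn, precision, recall, f1`.
#' @export
#' @examples
#' class_metrics(confusion(rep(c("a", "b"), c(3, 4)), rep(c("a", "b"), c(5, 2))))
class_metrics <- function(cm) {
  d <- cm_counts(cm)
  denom_p <- d$tp + d$fp
  denom_r <- d$tp + d$fn
  d$precision <- ifelse(denom_p > 0, d$tp / denom_p, 0)
  d$recall <- ifelse(denom_r > 0, d$tp / denom_r, 0)
  d$f1 <- ifelse(2 * d$tp + d$fp + d$fn > 0,
                 2 * d$tp / (2 * d$tp + d$fp + d$fn), 0)
  absent <- d$tp + d$fp + d$fn == 0
  if (any(absent)) {
    warning("class(es) absent from truth and predictions: ",
            paste(d$class[absent], collapse = ", "),
            "; metrics undefined (NaN)", call. = FALSE)
    d[absent, c("precision", "recall", "f1")] <- NaN
  }
  d
}

#' Micro-averaged F1
#'
#' \deqn{\mathrm{micro}\,F_1 = \frac{2 \sum_c TP_c}
#'   {2 \sum_c TP_c + \sum_c FP_c + \sum_c FN_c}.}
#' For single-label classification every error is one class's FP and
#' another's FN, so \eqn{\sum FP = \sum FN} and the micro-F1 equals overall
#' accuracy. (Published statements of this formula occasionally write "true
#' negatives" in the denominator where false positives belong; the standard
#' definition above is the one consistent with all reported values.)
#'
#' @param cm A [confusion()] matrix.
#' @return Micro-F1 in `[0, 1]`.
#' @export
micro_f1 <- function(cm) {
  d <- cm_counts(cm)
  total <- 2 * sum(d$tp) + sum(d$fp) + sum(d$fn)
  if (sum(unclass(cm)) == 0) stop("empty confusion matrix", call. = FALSE)
  2 * sum(d$tp) / total
}

#' Reconstruct integer confusion counts from rounded precision/recall
#'
#' Published performance tables usually print per-class precision and recall
#' as integer percentages. Given those printed values and the known per-class
#' test-set sizes, this searches all integer confusion matrices consistent
#' with the rounding (half-up to whole percent) and returns the solution(s).
#' For two classes the off-diagonal structure is fully determined:
#' \eqn{FP_1 = FN_2 = n_2 - TP_2} and \eqn{FP_2 = n_1 - TP_1}, so the search
#' runs over \eqn{TP_1 \le n_1, TP_2 \le n_2} only. No consistent solution
#' signals a transcription error in the printed values.
#'
#' @param precision_pct,recall_pct Printed integer percentages, one per
#'   class, in class order.
#' @param class_sizes True class sizes in the test set, same order; names
#'   are used as class labels when present.
#' @return A single `confusion_matrix` when the solution is unique,
#'   otherwise a list of all consistent matrices (with a warning).
#' @export
#' @examples
#' reconstruct_confusion(c(75, 100), c(100, 75), c(pattern1 = 3, pattern2 = 4))
reconstruct_confusion <- function(precision_pct, recall_pct, class_sizes) {
  k <- length(class_sizes)
  if (k != 2) stop("reconstruction is implemented for 2 classes", call. = FALSE)
  if (length(precision_pct) != k || length(recall_pct) != k) {
    stop("need one precision and recall value per class", call. = FALSE)
  }
  labels <- names(class_sizes) %||% paste0("class", seq_len(k))
  n1 <- class_sizes[[1]]; n2 <- class_sizes[[2]]
  sols <- list()
  for (tp1 in 0:n1) {
    for (tp2 in 0:n2) {
      fp1 <- n2 - tp2   # 2-class: class 1's false positives are class 2's misses
      fp2 <- n1 - tp1
      ok <- matches_pct(tp1, fp1, n1, precision_pct[1], recall_pct[1]) &&
        matches_pct(tp2, fp2, n2, precision_pct[2], recall_pct[2])
      if (ok) {
        # rows = truth: class 1's misses (fn1 = fp2) sit in row 1, column 2
        cm <- matrix(c(tp1, fp2, fp1, tp2), 2, 2, byrow = TRUE,
                     dimnames = list(truth = labels, predicted = labels))
        cm <- as.table(cm)
        class(cm) <- c("confusion_matrix", class(cm))
        sols[[length(sols) + 1]] <- cm
      }
    }
  }
  if (!length(sols)) {
    stop("no integer confusion matrix reproduces the printed precision/recall",
         call. = FALSE)
  }
  if (length(sols) == 1) return(sols[[1]])
  warning(length(sols), " confusion matrices are consistent with the printed values",
          call. = FALSE)
  sols
}

matches_pct <- function(tp, fp, size, prec_pct, rec_pct) {
  if (tp + fp == 0) return(FALSE)  # printed precision implies predictions exist
  round_half_up(100 * tp / (tp + fp)) == prec_pct &&
    round_half_up(100 * tp / size) == rec_pct
}

#' Evaluate a fitted model on the test set
#'
#' @param model A `pattern_model` from [train_suite()].
#' @param test Test feature table (normalised with the training constants),
#'   with a `label` column.
#' @return An `evaluation_report`: list with `confusion`, `metrics`
#'   (per-class precision/recall/F1) and `micro_f1`.
#' @export
evaluate_model <- function(model, test) {
  pred <- predict(model, test)
  cm <- confusion(factor(test$label, levels = model$levels), pred)
  structure(list(confusion = cm, metrics = class_metrics(cm),
                 micro_f1 = micro_f1(cm)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> micro-F1 =", sprintf("%.3f", x$micro_f1), "\n")
  print(x$confusion)
  print(x$metrics[, c("class", "precision", "recall", "f1")], row.names = FALSE)
  invisible(x)
}

#' Reported per-window test-set performance of the original study
#'
#' The printed test-set precision and recall (integer percent) of the
#' original exploratory clinical study, per monitoring window (first 5-8
#' rehabilitation days) and pattern class (upward-linear, S-shape), together
#' with the test-set class sizes (3 upward-linear, 4 S-shape) and the name of
#' each window's winning classifier. These published summary values are the
#' input to [reconstruct_confusion()], from which the per-class F1 and
#' micro-F1 are recomputed rather than copied.
#'
#' @return Data frame `window, class, size, precision_pct, recall_pct,
#'   final_model` read from the package's `extdata`.
#' @export
#' @examples
#' reported_performance()
reported_performance <- function() {
  utils::read.csv(system.file("extdata", "reported_performance.csv",
                              package = "rehabpattern"),
                  stringsAsFactors = FALSE)
}

#' Recompute published F1 scores from printed precision/recall
#'
#' For every monitoring window in [reported_performance()], reconstructs the
#' integer confusion matrix from the printed precision/recall percentages and
#' the known test-set composition, then recomputes the per-class F1 and the
#' micro-F1 from the reconstructed counts.
#'
#' @param reported Data frame in the format of [reported_performance()].
#' @return Data frame `window, class, precision, recall, f1, micro_f1` (one
#'   row per window and class; `micro_f1` repeated within window).
#' @export
recompute_reported_f1 <- function(reported = reported_performance()) {
  out <- lapply(split(reported, reported$window), function(w) {
    w <- w[order(w$class), ]
    sizes <- stats::setNames(w$size, w$class)
    cm <- reconstruct_confusion(w$precision_pct, w$recall_pct, sizes)
    if (is.list(cm)) cm <- cm[[1]]
    m <- class_metrics(cm)
    data.frame(window = w$window[1], class = m$class,
               precision = m$precision, recall = m$recall, f1 = m$f1,
               micro_f1 = micro_f1(cm), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
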