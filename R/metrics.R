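# Multi-label evaluation: micro- and macro-averaged precision/recall/F1
# over the example x label prediction matrix, plus long-tailed-label
# metrics restricted to rare codes.

check_pred_gold <- function(predictions, gold) {
  predictions <- as.matrix(predictions)
  gold <- as.matrix(gold)
  if (!all(dim(predictions) == dim(gold))) {
    stop("`predictions` and `gold` must have identical dimensions", call. = FALSE)
  }
  if (!all(predictions %in% c(0, 1)) || !all(gold %in% c(0, 1))) {
    stop("`predictions` and `gold` must be binary 0/1 matrices", call. = FALSE)
  }
  list(pred = predictions, gold = gold)
}

safe_div <- function(num, den) ifelse(den > 0, num / den, 0)

#' Micro-averaged precision, recall and F1
#'
#' True/false positives and false negatives are pooled over every
#' example-label cell, then
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`. Any ratio with a
#' zero denominator is 0 by convention.
#'
#' @param predictions,gold Binary example x label matrices of identical
#'   shape.
#' @return List with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
micro_metrics <- function(predictions, gold) {
  m <- check_pred_gold(predictions, gold)
  tp <- sum(m$pred == 1 & m$gold == 1)
  fp <- sum(m$pred == 1 & m$gold == 0)
  fn <- sum(m$pred == 0 & m$gold == 1)
  p <- safe_div(tp, tp + fp)
  r <- safe_div(tp, tp + fn)
  list(tp = tp, fp = fp, fn = fn,
       precision = p, recall = r, f1 = safe_div(2 * p * r, p + r))
}

#' Macro-averaged precision, recall and F1
#'
#' Per-label precision and recall are computed for every one of the `|L|`
#' catalog labels (labels with no predicted or no gold positives use the
#' 0/0 = 0 convention) and arithmetically averaged:
#' `Pmacro = mean_l P_l`, `Rmacro = mean_l R_l`. The macro F1 is then the
#' harmonic mean of `Pmacro` and `Rmacro` — note this is *not* the mean of
#' per-label F1 scores.
#'
#' @param predictions,gold Binary example x label matrices; columns must
#'   cover the full label catalog.
#' @return List with `precision`, `recall`, `f1`, `n_labels`.
#' @export
macro_metrics <- function(predictions, gold) {
  m <- check_pred_gold(predictions, gold)
  L <- ncol(m$gold)
  if (L == 0L) stop("label catalog is empty", call. = FALSE)
  tp <- colSums(m$pred == 1 & m$gold == 1)
  fp <- colSums(m$pred == 1 & m$gold == 0)
  fn <- colSums(m$pred == 0 & m$gold == 1)
  p <- mean(safe_div(tp, tp + fp))
  r <- mean(safe_div(tp, tp + fn))
  list(precision = p, recall = r, f1 = safe_div(2 * p * r, p + r), n_labels = L)
}

#' Combined micro/macro report
#'
#' @inheritParams micro_metrics
#' @return A `micro_macro_report` list: pooled `tp`, `fp`, `fn`, the micro
#'   and macro precision/recall/F1, and `n_labels`.
#' @export
micro_macro_report <- function(predictions, gold) {
  mi <- micro_metrics(predictions, gold)
  ma <- macro_metrics(predictions, gold)
  structure(list(tp = mi$tp, fp = mi$fp, fn = mi$fn,
                 p_micro = mi$precision, r_micro = mi$recall, f1_micro = mi$f1,
                 p_macro = ma$precision, r_macro = ma$recall, f1_macro = ma$f1,
                 n_labels = ma$n_labels),
            class = "micro_macro_report")
}

#' @export
print.micro_macro_report <- function(x, ...) {
  cat(sprintf("micro  P %.4f  R %.4f  F1 %.4f   (TP %d FP %d FN %d)\n",
              x$p_micro, x$r_micro, x$f1_micro, x$tp, x$fp, x$fn))
  cat(sprintf("macro  P %.4f  R %.4f  F1 %.4f   (|L| = %d)\n",
              x$p_macro, x$r_macro, x$f1_macro, x$n_labels))
  invisible(x)
}

#' Long-tailed-label precision and recall
#'
#' Labels whose training-set frequency (number of training examples
#' carrying the label) is strictly below the threshold `gamma` are the
#' long-tailed labels; micro precision and recall are pooled over those
#' label columns only. They isolate a model's ability to learn rare codes.
#'
#' @param predictions,gold Binary example x label matrices whose columns
#'   are the label catalog.
#' @param train_label_freqs Named integer vector of per-label training
#'   frequencies, aligned with (or named by) the matrix columns.
#' @param gamma Frequency threshold (default 219); a label qualifies iff
#'   `freq < gamma`.
#' @return List with `n_labels` (qualifying count), `precision`, `recall`,
#'   `empty` (TRUE when no label qualifies; precision/recall are then `NA`).
#' @export
longtail_metrics <- function(predictions, gold, train_label_freqs, gamma = 219) {
  m <- check_pred_gold(predictions, gold)
  if (length(train_label_freqs) != ncol(m$gold)) {
    stop("`train_label_freqs` must have one entry per label column", call. = FALSE)
  }
  if (!is.null(names(train_label_freqs)) && !is.null(colnames(m$gold))) {
    train_label_freqs <- train_label_freqs[colnames(m$gold)]
  }
  if (gamma < 0) stop("`gamma` must be >= 0", call. = FALSE)
  tail_cols <- which(train_label_freqs < gamma)
  if (length(tail_cols) == 0L) {
    return(list(n_labels = 0L, precision = NA_real_, recall = NA_real_, empty = TRUE))
  }
  mi <- micro_metrics(m$pred[, tail_cols, drop = FALSE],
                      m$gold[, tail_cols, drop = FALSE])
  list(n_labels = length(tail_cols), precision = mi$precision,
       recall = mi$recall, empty = FALSE)
}

#' Per-label training frequencies
#'
#' Number of training examples carrying each catalog label — the counts the
#' long-tail threshold `gamma` is compared against.
#'
#' @param corpus A `labeled_corpus` or `encoded_corpus` (training split).
#' @return Named integer vector over the catalog.
#' @export
label_frequencies <- function(corpus) {
  if (inherits(corpus, "encoded_corpus")) {
    counts <- colSums(corpus$label_matrix)
    storage.mode(counts) <- "integer"
    return(counts)
  }
  sets <- label_sets_of(corpus)
  catalog <- catalog_of(corpus)
  counts <- table(factor(unlist(sets, use.names = FALSE), levels = catalog))
  out <- as.integer(counts)
  names(out) <- catalog
  out
}

#' Write a one-row metric report as TSV
#'
#' @param report A `micro_macro_report`.
#' @param path File path.
#' @param run Optional run identifier written as the first column.
#' @param longtail Optional result of [longtail_metrics()] appended as
#'   extra columns.
#' @export
write_metrics_tsv <- function(report, path, run = "run", longtail = NULL) {
  stopifnot(inherits(report, "micro_macro_report"))
  df <- data.frame(run = run,
                   p_micro = report$p_micro, r_micro = report$r_micro,
                   f1_micro = report$f1_micro,
                   p_macro = report$p_macro, r_macro = report$r_macro,
                   f1_macro = report$f1_macro)
  if (!is.null(longtail)) {
    df$lt_precision <- longtail$precision
    df$lt_recall <- longtail$recall
    df$lt_n_labels <- longtail$n_labels
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
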