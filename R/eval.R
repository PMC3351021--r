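#' Per-class confusion counts
#'
#' @param truth,pred character vectors of true and predicted labels.
#' @return An `ec_confusion`: data frame with columns `label`, `tp`, `fp`,
#'   `fn`, plus attributes `total` and `n_correct`.
#' @export
confusion_summary <- function(truth, pred) {
  truth <- as.character(truth); pred <- as.character(pred)
  stopifnot(length(truth) == length(pred))
  labels <- sort(unique(c(truth, pred)))
  tp <- vapply(labels, function(l) sum(truth == l & pred == l), numeric(1))
  fp <- vapply(labels, function(l) sum(truth != l & pred == l), numeric(1))
  fn <- vapply(labels, function(l) sum(truth == l & pred != l), numeric(1))
  out <- data.frame(label = labels, tp = tp, fp = fp, fn = fn,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "total") <- length(truth)
  attr(out, "n_correct") <- sum(truth == pred)
  class(out) <- c("ec_confusion", "data.frame")
  out
}

#' Precision, recall and overall accuracy from confusion counts
#'
#' Rates are percentages. A label with `tp + fp = 0` has undefined precision,
#' reported as `NA` (never 0); likewise recall for `tp + fn = 0`.
#'
#' @param confusion an `ec_confusion` from [confusion_summary()], or any data
#'   frame with `label`, `tp`, `fp`, `fn` columns (then `total` must be
#'   given).
#' @param total total instance count, if not carried by `confusion`.
#' @return Data frame `label`, `tp`, `fp`, `fn`, `precision`, `recall`;
#'   attribute `accuracy` = 100 * sum(tp) / total.
#' @export
class_metrics <- function(confusion, total = attr(confusion, "total")) {
  stopifnot(!is.null(total), total > 0)
  pr <- ifelse(confusion$tp + confusion$fp > 0,
               100 * confusion$tp / (confusion$tp + confusion$fp), NA_real_)
  rc <- ifelse(confusion$tp + confusion$fn > 0,
               100 * confusion$tp / (confusion$tp + confusion$fn), NA_real_)
  out <- data.frame(confusion[c("label", "tp", "fp", "fn")],
                    precision = pr, recall = rc, stringsAsFactors = FALSE)
  attr(out, "accuracy") <- 100 * sum(confusion$tp) / total
  out
}

#' Allocate carry-over errors across sub-classes
#'
#' Distributes a main class's level-2 error total over its sub-classes
#' proportionally to their test sizes, using the largest-remainder method:
#' each sub-class gets the floor of its exact proportional share, and the
#' remaining units go to the largest fractional parts (ties broken by
#' sub-class label order). The result sums exactly to `total` and each entry
#' is within 1 of its exact share.
#'
#' @param total carry-over count to distribute (>= 0).
#' @param sizes named vector of per-sub-class test sizes (> 0).
#' @return Named integer vector of allocations.
#' @export
allocate_carryover <- function(total, sizes) {
  if (total < 0) stop("total must be >= 0", call. = FALSE)
  stopifnot(length(sizes) > 0, all(sizes > 0), !is.null(names(sizes)))
  share <- total * sizes / sum(sizes)
  base <- floor(share)
  left <- as.integer(round(total - sum(base)))
  if (left > 0) {
    frac <- share - base
    ord <- order(-frac, names(sizes))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  setNames(as.integer(base), names(sizes))
}

#' Carry-over-adjusted precision
#'
#' `100 * tp / (tp + fp + carry_fp)`: plain precision with the main-class
#' false positives carried into the sub-class denominator. Equals plain
#' precision when `carry_fp = 0`; `NA` when the denominator is 0.
#'
#' @param tp,fp,carry_fp counts (vectorized).
#' @return Percentages.
#' @export
adjusted_precision <- function(tp, fp, carry_fp) {
  den <- tp + fp + carry_fp
  ifelse(den > 0, 100 * tp / den, NA_real_)
}

#' Carry-over-adjusted recall
#'
#' `100 * tp / (tp + fn + carry_fn)`; see [adjusted_precision()].
#'
#' @param tp,fn,carry_fn counts (vectorized).
#' @return Percentages.
#' @export
adjusted_recall <- function(tp, fn, carry_fn) {
  den <- tp + fn + carry_fn
  ifelse(den > 0, 100 * tp / den, NA_real_)
}

#' Sub-class metrics with carry-over adjustment
#'
#' Evaluates cascade predictions at the sub-class level while propagating
#' main-class (level-2) errors. For each main class, its level-2 false
#' positives / negatives are allocated across its sub-classes by test size
#' ([allocate_carryover()]); plain precision/recall are computed among the
#' correctly routed rows, and the adjusted ("new") rates add the carry-over
#' counts to the denominators. The overall row aggregates raw counts before
#' computing rates (micro-averaging).
#'
#' @param predictions data frame from [predict.ec_cascade()].
#' @param truth character vector of true labels aligned with `predictions`
#'   (`"X.Y"` or `"non_enzyme"`).
#' @param level2_confusion optional `ec_confusion` of main-class predictions
#'   (labels "1".."6"); computed from `predictions`/`truth` when omitted.
#' @return Data frame with one row per sub-class plus an `"overall"` row:
#'   `sub_class`, `size`, `tp`, `fp`, `fn`, `carry_fp`, `carry_fn`,
#'   `precision`, `new_precision`, `recall`, `new_recall`.
#' @export
evaluate_cascade <- function(predictions, truth, level2_confusion = NULL) {
  truth <- as.character(truth)
  stopifnot(nrow(predictions) == length(truth))
  true_main <- label_main_class(truth)
  enz <- !is.na(true_main)
  if (any(enz & !grepl("\\.", truth)))
    stop("every enzyme row needs a true sub-class label", call. = FALSE)

  pred_main <- predictions$main_class
  if (is.null(level2_confusion)) {
    keep <- enz & predictions$is_enzyme
    level2_confusion <- confusion_summary(as.character(true_main[keep]),
                                          as.character(pred_main[keep]))
  }

  rows <- list()
  for (k in sort(unique(true_main[enz]))) {
    kc <- as.character(k)
    routed <- enz & !is.na(pred_main) & pred_main == k & true_main == k
    subs <- sort(unique(truth[enz & true_main == k]))
    sizes <- vapply(subs, function(s) sum(routed & truth == s), numeric(1))
    # sub-classes never routed still get a row (tp = 0); allocation needs
    # positive sizes, so use the true test size per sub-class
    sizes_true <- vapply(subs, function(s) sum(enz & truth == s), numeric(1))
    l2 <- level2_confusion[level2_confusion$label == kc, ]
    cfp <- allocate_carryover(if (nrow(l2)) l2$fp else 0,
                              setNames(sizes_true, subs))
    cfn <- allocate_carryover(if (nrow(l2)) l2$fn else 0,
                              setNames(sizes_true, subs))
    for (s in subs) {
      tp <- sum(routed & truth == s & predictions$sub_class == s)
      fp <- sum(routed & truth != s & predictions$sub_class == s)
      fn <- sum(routed & truth == s & predictions$sub_class != s)
      rows[[s]] <- data.frame(
        sub_class = s, size = sizes_true[[s]], tp = tp, fp = fp, fn = fn,
        carry_fp = cfp[[s]], carry_fn = cfn[[s]], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  tot <- data.frame(sub_class = "overall", size = sum(out$size),
                    tp = sum(out$tp), fp = sum(out$fp), fn = sum(out$fn),
                    carry_fp = sum(out$carry_fp), carry_fn = sum(out$carry_fn),
                    stringsAsFactors = FALSE)
  out <- rbind(out, tot)
  rownames(out) <- NULL
  out$precision <- adjusted_precision(out$tp, out$fp, 0)
  out$new_precision <- adjusted_precision(out$tp, out$fp, out$carry_fp)
  out$recall <- adjusted_recall(out$tp, out$fn, 0)
  out$new_recall <- adjusted_recall(out$tp, out$fn, out$carry_fn)
  out
}

#' One-vs-rest ROC area
#'
#' Area under the ROC curve by the rank statistic: the probability that a
#' positive's score outranks a negative's, ties counted one half. Invariant
#' under strictly increasing transforms of the scores. A class with no
#' positives or no negatives gets `NA`.
#'
#' @param scores numeric vector, or a matrix of per-class vote fractions
#'   (columns named by class).
#' @param truth true labels; for the vector form, a logical/0-1 vector of
#'   positives.
#' @return A single area, or a named vector per class for the matrix form.
#' @export
roc_area <- function(scores, truth) {
  if (is.matrix(scores)) {
    truth <- as.character(truth)
    return(vapply(colnames(scores), function(cl)
      roc_area(scores[, cl], truth == cl), numeric(1)))
  }
  pos <- as.logical(truth)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Write a sub-class metrics table as TSV
#'
#' Column layout mirrors the adjusted-metrics report: class, size, FP,
#' carry-over FP, precision, new precision, recall, carry-over FN, new recall
#' (plus a ROC-area column when supplied).
#'
#' @param metrics data frame from [evaluate_cascade()].
#' @param path output TSV path.
#' @param roc optional named vector of per-sub-class ROC areas.
#' @return `path` invisibly.
#' @export
write_metrics <- function(metrics, path, roc = NULL) {
  df <- metrics[, c("sub_class", "size", "fp", "carry_fp", "precision",
                    "new_precision", "recall", "carry_fn", "new_recall")]
  if (!is.null(roc)) df$roc_area <- roc[df$sub_class]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
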