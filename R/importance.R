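#' Permutation feature importance (mean decrease in accuracy)
#'
#' For each feature, the forest's out-of-bag accuracy is measured before and
#' after randomly permuting that feature's column; the score is the mean
#' accuracy drop over `repeats` independent permutations. OOB rows are used
#' (every `ec_forest` carries its in-bag record), so no separate validation
#' split is needed. Scores are fractions in \[0, 1\] (a 0.30 score means the
#' permutation costs 30 accuracy points).
#'
#' @param forest a trained [train_forest()] model.
#' @param x,y the training feature matrix and labels (row-aligned with the
#'   forest's in-bag record).
#' @param repeats number of permutations per feature (>= 1).
#' @param seed permutation seed.
#' @return Data frame `feature`, `mean_decrease_accuracy`, `rank` (1 = most
#'   important; ties broken by feature name), ordered by rank; attributes
#'   `repeats` and `seed`. The forest's Gini importance (total impurity
#'   decrease) is attached read-only as attribute `gini_importance` for
#'   comparison, but ranking always uses mean decrease in accuracy.
#' @export
permutation_importance <- function(forest, x, y, repeats = 10L, seed = 1L) {
  stopifnot(inherits(forest, "ec_forest"))
  if (repeats < 1L) stop("repeats must be >= 1", call. = FALSE)
  x <- check_schema_match(forest, x)
  y <- factor(as.character(y), levels = forest$classes)
  stopifnot(nrow(x) == length(y), !anyNA(y))
  drops <- rf_perm_importance_cpp(forest$trees, forest$inbag, x,
                                  as.integer(y) - 1L,
                                  length(forest$classes),
                                  as.integer(repeats), seed)
  score <- rowMeans(drops)
  out <- data.frame(feature = colnames(x),
                    mean_decrease_accuracy = score,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_decrease_accuracy, out$feature), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "repeats") <- as.integer(repeats)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "gini_importance") <- forest$gini_importance
  out
}

# inclusive median-of-halves quartiles (Tukey hinges): for odd n the median
# belongs to both halves
five_number <- function(v) {
  v <- sort(unname(v))
  n <- length(v)
  med <- median(v)
  lower <- v[seq_len(ceiling(n / 2))]
  upper <- v[seq.int(floor(n / 2) + 1L, n)]
  c(min = v[1], q1 = median(lower), median = med, q3 = median(upper),
    max = v[n])
}

#' Per-class distribution summary of one feature
#'
#' Five-number summary (min, lower quartile, median, upper quartile, max;
#' quartiles by the inclusive median-of-halves convention) of a named feature
#' within each class — the box-plot view used to inspect, e.g., cysteine
#' composition across the six EC main classes.
#'
#' @param x feature matrix.
#' @param labels class labels, one per row.
#' @param feature feature (column) name.
#' @return Data frame: `class`, `min`, `q1`, `median`, `q3`, `max`.
#' @export
class_distribution <- function(x, labels, feature) {
  x <- as.matrix(x)
  if (!feature %in% colnames(x))
    stop("unknown feature: ", feature, call. = FALSE)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  cls <- sort(unique(labels))
  out <- do.call(rbind, lapply(cls, function(cl)
    as.data.frame(as.list(five_number(x[labels == cl, feature])))))
  cbind(data.frame(class = cls, stringsAsFactors = FALSE), out)
}
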