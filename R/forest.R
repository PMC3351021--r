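#' Random forest parameters
#'
#' @param ntree number of trees.
#' @param mtry size of the random feature subset tried at each split.
#' @param seed integer seed controlling bootstrap and feature sampling.
#' @return A `forest_params` list.
#' @export
forest_params <- function(ntree = 200L, mtry = 7L, seed = 1L) {
  stopifnot(ntree >= 1, mtry >= 1)
  structure(list(ntree = as.integer(ntree), mtry = as.integer(mtry),
                 seed = as.integer(seed)), class = "forest_params")
}

#' Train a classification random forest
#'
#' Grows `ntree` CART trees, each on a bootstrap sample of the rows, choosing
#' at every node the best Gini split among `mtry` randomly drawn features.
#' The out-of-bag (OOB) error is the fraction of training rows misclassified
#' by the majority vote of the trees whose bootstrap sample excluded them.
#' Vote ties are broken in favor of the lowest class label (sorted order).
#' Fully reproducible given `params$seed`. Feature values are used
#' unnormalized.
#'
#' @param x numeric feature matrix (rows = instances).
#' @param y class labels (coerced to factor; levels sorted).
#' @param params a [forest_params()] object.
#' @return An `ec_forest` object with elements `trees`, `inbag`, `classes`,
#'   `feature_names`, `params`, `oob_error`, `oob_votes`, `gini_importance`.
#' @export
train_forest <- function(x, y, params = forest_params()) {
  x <- as.matrix(x)
  y <- factor(as.character(y), levels = sort(unique(as.character(y))))
  stopifnot(nrow(x) == length(y))
  if (nlevels(y) < 2L) stop("training data has a single class", call. = FALSE)
  if (params$mtry > ncol(x))
    stop("mtry (", params$mtry, ") exceeds feature count (", ncol(x), ")",
         call. = FALSE)
  fit <- rf_train_cpp(x, as.integer(y) - 1L, nlevels(y), params$ntree,
                      params$mtry, 1L, params$seed)
  structure(list(
    trees = fit$trees,
    inbag = fit$inbag,
    classes = levels(y),
    feature_names = colnames(x),
    params = params,
    oob_error = fit$oob_error,
    oob_votes = fit$oob_votes,
    gini_importance = setNames(fit$gini_importance, colnames(x))
  ), class = "ec_forest")
}

check_schema_match <- function(object, x) {
  if (is.null(object$feature_names) || is.null(colnames(x)))
    return(as.matrix(x))
  missing <- setdiff(object$feature_names, colnames(x))
  extra <- setdiff(colnames(x), object$feature_names)
  if (length(missing) || length(extra))
    stop("feature schema mismatch; missing: [",
         paste(missing, collapse = ", "), "], extra: [",
         paste(extra, collapse = ", "), "]", call. = FALSE)
  as.matrix(x)[, object$feature_names, drop = FALSE]
}

#' Predict with a trained forest
#'
#' @param object an `ec_forest`.
#' @param newdata numeric matrix with the training feature columns.
#' @param type `"class"` for labels, `"vote"` for the matrix of per-class
#'   vote fractions (rows sum to 1).
#' @param ... unused.
#' @return Character vector of labels, or a numeric vote-fraction matrix.
#' @export
predict.ec_forest <- function(object, newdata, type = c("class", "vote"),
                              ...) {
  type <- match.arg(type)
  x <- check_schema_match(object, newdata)
  votes <- rf_votes_cpp(object$trees, x, length(object$classes))
  colnames(votes) <- object$classes
  if (type == "vote") return(votes / length(object$trees))
  object$classes[max.col(votes, ties.method = "first")]
}

#' @export
print.ec_forest <- function(x, ...) {
  cat("Random forest:", length(x$trees), "trees, mtry", x$params$mtry,
      "|", length(x$classes), "classes | OOB error",
      format(x$oob_error, digits = 4), "\n")
  invisible(x)
}

#' Tune ntree and mtry by OOB error
#'
#' Trains a forest at every grid point (same seed throughout) and returns the
#' point with the lowest OOB error; ties are broken by smaller `ntree`, then
#' smaller `mtry`.
#'
#' @inheritParams train_forest
#' @param ntree_grid,mtry_grid integer vectors of candidate values.
#' @param seed seed used for every grid point.
#' @return A list with `best` ([forest_params()]) and `surface` (data frame
#'   `ntree`, `mtry`, `oob_error`).
#' @export
tune_parameters <- function(x, y, ntree_grid = c(50L, 100L, 200L),
                            mtry_grid = c(5L, 7L, 15L, 25L), seed = 1L) {
  stopifnot(length(ntree_grid) > 0, length(mtry_grid) > 0)
  grid <- expand.grid(ntree = sort(as.integer(ntree_grid)),
                      mtry = sort(as.integer(mtry_grid)))
  grid$oob_error <- vapply(seq_len(nrow(grid)), function(i) {
    train_forest(x, y, forest_params(grid$ntree[i], grid$mtry[i],
                                     seed))$oob_error
  }, numeric(1))
  ord <- order(grid$oob_error, grid$ntree, grid$mtry)
  best <- grid[ord[1], ]
  list(best = forest_params(best$ntree, best$mtry, seed), surface = grid)
}
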