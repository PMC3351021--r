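#' Per-level parameters for the three-tier cascade
#'
#' Defaults are the tuned values from the study design this package
#' implements: level 1 (enzyme vs non-enzyme) ntree = 200, mtry = 25;
#' levels 2 and 3 (main class, sub-class) ntree = 200, mtry = 7.
#'
#' @param level1,level2,level3 [forest_params()] per level.
#' @param seed base seed recorded in model metadata.
#' @return A `cascade_params` list.
#' @export
cascade_params <- function(seed = 1L,
                           level1 = forest_params(200L, 25L, seed),
                           level2 = forest_params(200L, 7L, seed + 1L),
                           level3 = forest_params(200L, 7L, seed + 2L)) {
  structure(list(level1 = level1, level2 = level2, level3 = level3,
                 seed = as.integer(seed)), class = "cascade_params")
}

constant_classifier <- function(label) {
  structure(list(classes = label), class = "ec_constant")
}

#' @export
predict.ec_constant <- function(object, newdata, type = c("class", "vote"),
                                ...) {
  type <- match.arg(type)
  n <- nrow(as.matrix(newdata))
  if (type == "class") return(rep(object$classes, n))
  matrix(1, n, 1, dimnames = list(NULL, object$classes))
}

#' Train the three-tier top-down cascade (Model 1)
#'
#' Level 1 separates enzymes from non-enzymes (training is balanced by
#' down-sampling the larger pool to the smaller, seeded); level 2 classifies
#' enzymes into the six EC main classes; level 3 holds one sub-class
#' classifier per main class, trained on that class's level-2 training rows
#' relabeled with their sub-class. A main class with fewer than two distinct
#' sub-classes gets a constant predictor, flagged in `metadata$constant_level3`.
#'
#' @param enzyme_x feature matrix of enzyme sequences.
#' @param enzyme_labels character sub-class labels ("X.Y"), one per row.
#' @param nonenzyme_x feature matrix of non-enzyme sequences.
#' @param params a [cascade_params()] object.
#' @return An `ec_cascade` object.
#' @export
train_cascade <- function(enzyme_x, enzyme_labels, nonenzyme_x,
                          params = cascade_params()) {
  enzyme_x <- as.matrix(enzyme_x)
  nonenzyme_x <- as.matrix(nonenzyme_x)
  stopifnot(nrow(enzyme_x) == length(enzyme_labels))
  parsed <- lapply(as.character(enzyme_labels), parse_ec_label)
  if (any(vapply(parsed, function(p) is.na(p$sub_class), logical(1))))
    stop("every enzyme label must carry a sub-class (\"X.Y\")", call. = FALSE)
  main <- vapply(parsed, function(p) p$main_class, integer(1))
  sub <- vapply(parsed, function(p) p$sub_class, character(1))

  # level 1: balanced enzyme vs non-enzyme
  n_bal <- min(nrow(enzyme_x), nrow(nonenzyme_x))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(params$level1$seed)
  ei <- sample(nrow(enzyme_x), n_bal)
  ni <- sample(nrow(nonenzyme_x), n_bal)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  x1 <- rbind(enzyme_x[ei, , drop = FALSE], nonenzyme_x[ni, , drop = FALSE])
  y1 <- rep(c("enzyme", "non_enzyme"), each = n_bal)
  level1 <- train_forest(x1, y1, params$level1)

  level2 <- train_forest(enzyme_x, as.character(main), params$level2)

  level3 <- list()
  constant <- character(0)
  for (k in sort(unique(main))) {
    rows <- main == k
    subs <- sub[rows]
    if (length(unique(subs)) < 2L) {
      level3[[as.character(k)]] <- constant_classifier(unique(subs))
      constant <- c(constant, as.character(k))
    } else {
      level3[[as.character(k)]] <-
        train_forest(enzyme_x[rows, , drop = FALSE], subs, params$level3)
    }
  }

  structure(list(
    level1 = level1, level2 = level2, level3 = level3,
    params = params,
    schema_version = attr(enzyme_x, "schema_version"),
    feature_names = colnames(enzyme_x),
    metadata = list(
      n_enzyme = nrow(enzyme_x), n_nonenzyme = nrow(nonenzyme_x),
      n_level1_balanced = n_bal,
      class_counts = table(main), subclass_counts = table(sub),
      constant_level3 = constant, seed = params$seed)
  ), class = "ec_cascade")
}

#' Predict with the cascade
#'
#' Rows classified non-enzyme stop at level 1 (main and sub-class are NA);
#' the rest get a main class from level 2 and a sub-class from the level-3
#' classifier of that main class, so the predicted sub-class prefix always
#' equals the predicted main class.
#'
#' @param object an `ec_cascade`.
#' @param newdata feature matrix with the training columns.
#' @param ... unused.
#' @return Data frame: `id`, `is_enzyme`, `enzyme_vote`, `main_class`,
#'   `main_vote`, `sub_class`, `sub_vote`.
#' @export
predict.ec_cascade <- function(object, newdata, ...) {
  x <- check_schema_match(object$level1, newdata)
  n <- nrow(x)
  v1 <- predict(object$level1, x, type = "vote")
  is_enz <- v1[, "enzyme"] >= v1[, "non_enzyme"] # tie -> lowest label
  out <- data.frame(
    id = if (!is.null(rownames(x))) rownames(x) else as.character(seq_len(n)),
    is_enzyme = is_enz,
    enzyme_vote = v1[, "enzyme"],
    main_class = NA_integer_, main_vote = NA_real_,
    sub_class = NA_character_, sub_vote = NA_real_,
    stringsAsFactors = FALSE)
  if (!any(is_enz)) return(out)

  xe <- x[is_enz, , drop = FALSE]
  v2 <- predict(object$level2, xe, type = "vote")
  main <- object$level2$classes[max.col(v2, ties.method = "first")]
  out$main_class[is_enz] <- as.integer(main)
  out$main_vote[is_enz] <- v2[cbind(seq_len(nrow(v2)),
                                    match(main, colnames(v2)))]

  enz_idx <- which(is_enz)
  for (k in unique(main)) {
    rows <- enz_idx[main == k]
    clf <- object$level3[[k]]
    if (is.null(clf))
      stop("no level-3 classifier for main class ", k, call. = FALSE)
    v3 <- predict(clf, x[rows, , drop = FALSE], type = "vote")
    lab <- colnames(v3)[max.col(v3, ties.method = "first")]
    out$sub_class[rows] <- lab
    out$sub_vote[rows] <- v3[cbind(seq_along(rows), match(lab, colnames(v3)))]
  }
  out
}

#' @export
print.ec_cascade <- function(x, ...) {
  cat("Three-tier EC cascade:", x$metadata$n_enzyme, "enzymes /",
      x$metadata$n_nonenzyme, "non-enzymes;",
      length(x$level3), "level-3 classifiers\n")
  invisible(x)
}

#' Train the direct sub-class model (Model 2)
#'
#' A single multi-class forest over all sub-class labels. Supplying
#' `nonenzyme_x` adds a `non_enzyme` class, the mixed-background variant.
#' Default tuned parameters: ntree = 200, mtry = 5.
#'
#' @inheritParams train_cascade
#' @param params [forest_params()]; default `forest_params(200, 5)`.
#' @return An `ec_direct` object.
#' @export
train_direct <- function(enzyme_x, enzyme_labels,
                         params = forest_params(200L, 5L), nonenzyme_x = NULL) {
  enzyme_x <- as.matrix(enzyme_x)
  labs <- as.character(enzyme_labels)
  for (l in unique(labs)) {
    p <- parse_ec_label(l)
    if (is.na(p$sub_class)) stop("label without sub-class: ", l, call. = FALSE)
  }
  x <- enzyme_x
  if (!is.null(nonenzyme_x)) {
    nonenzyme_x <- as.matrix(nonenzyme_x)
    x <- rbind(enzyme_x, nonenzyme_x)
    labs <- c(labs, rep("non_enzyme", nrow(nonenzyme_x)))
  }
  fit <- train_forest(x, labs, params)
  structure(list(forest = fit, params = params,
                 includes_nonenzyme = !is.null(nonenzyme_x),
                 schema_version = attr(enzyme_x, "schema_version")),
            class = "ec_direct")
}

#' @export
predict.ec_direct <- function(object, newdata, type = c("class", "vote"),
                              ...) {
  predict(object$forest, newdata, type = match.arg(type))
}

#' Stratified k-fold cross-validation of a forest
#'
#' Rows are assigned to folds stratified by label (seeded); each row is
#' predicted exactly once by the forest trained on the other folds. With
#' `k = nrow(x)` this is leave-one-out (stratification is then vacuous).
#'
#' @inheritParams train_forest
#' @param k number of folds (>= 2).
#' @param seed fold-assignment seed.
#' @return A list: `confusion` (an `ec_confusion`), `accuracy` (percent),
#'   `predictions` (character vector aligned with rows).
#' @export
cross_validate <- function(x, y, k = 10L, params = forest_params(),
                           seed = 1L) {
  x <- as.matrix(x)
  y <- as.character(y)
  n <- nrow(x)
  stopifnot(k >= 2L)
  if (k > n) stop("k exceeds the number of rows", call. = FALSE)
  sizes <- table(y)
  if (k < n && any(sizes < k))
    stop("class(es) with fewer rows than k = ", k, ": ",
         paste(names(sizes)[sizes < k], collapse = ", "),
         "; use a smaller k", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  fold <- integer(n)
  for (cl in names(sizes)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())

  pred <- character(n)
  for (f in seq_len(k)) {
    test <- fold == f
    fit <- train_forest(x[!test, , drop = FALSE], y[!test], params)
    pred[test] <- predict(fit, x[test, , drop = FALSE])
  }
  conf <- confusion_summary(y, pred)
  list(confusion = conf, accuracy = 100 * mean(pred == y), predictions = pred)
}

#' Persist / restore a trained model
#'
#' The model is written as a directory holding a JSON manifest (model type,
#' schema version, parameters, seed, label sets, class counts, package
#' version) and the serialized classifiers. `load_model()` restores an object
#' that yields identical predictions.
#'
#' @param model an `ec_cascade`, `ec_direct` or `ec_forest`.
#' @param dir target directory (created if needed).
#' @return `dir` invisibly; `load_model()` returns the model.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    type = class(model)[1],
    package_version = as.character(utils::packageVersion("ecforest")),
    schema_version = model$schema_version,
    params = unclass(model$params),
    classes = switch(class(model)[1],
                     ec_cascade = lapply(model$level3, function(m) m$classes),
                     ec_direct = model$forest$classes,
                     ec_forest = model$classes),
    metadata = if (!is.null(model$metadata))
      lapply(model$metadata, function(v)
        if (is.table(v)) as.list(setNames(as.integer(v), names(v))) else v)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  saveRDS(model, file.path(dir, "model.rds"))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  readRDS(file.path(dir, "model.rds"))
}
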