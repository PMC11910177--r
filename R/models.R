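# Tree-ensemble classifier configurations and fitting. Six user-facing
# families (random_forest, xgb, lgbm, extra_trees, bagging, stacking) plus
# the ridge-penalised logistic learner used as a stacking base and as the
# stacking meta-model. Fitting returns a classed S3 object (driver_model)
# with predict/print/summary methods.

CLASSIFIER_FAMILIES <- c("random_forest", "xgb", "lgbm", "extra_trees",
                         "bagging", "stacking", "logistic")

# Allowed hyperparameter names per family; unknown names are rejected.
.allowed_params <- list(
  random_forest = c("n_estimators", "max_depth", "oob_score", "n_jobs",
                    "warm_start", "max_features"),
  xgb           = c("n_estimators", "max_depth", "learning_rate"),
  lgbm          = c("n_estimators", "num_leaves", "learning_rate"),
  extra_trees   = c("n_estimators", "max_depth", "oob_score", "warm_start"),
  bagging       = c("n_estimators", "oob_score", "warm_start"),
  stacking      = c("base_families", "meta_family", "internal_folds"),
  logistic      = c("alpha", "lambda"))

#' Construct a classifier specification
#'
#' @param family One of `"random_forest"`, `"xgb"`, `"lgbm"`,
#'   `"extra_trees"`, `"bagging"`, `"stacking"` or `"logistic"`.
#' @param params Named list of hyperparameters; unknown names are
#'   rejected. Omitted names keep the family defaults of
#'   [default_spec()].
#' @param seed Integer seed making training reproducible.
#' @return A `classifier_spec` object.
#' @export
classifier_spec <- function(family, params = list(), seed = NULL) {
  if (length(family) != 1L || !family %in% CLASSIFIER_FAMILIES) {
    stop("unknown classifier family: ", paste(family, collapse = ", "),
         "; expected one of ", paste(CLASSIFIER_FAMILIES, collapse = ", "),
         call. = FALSE)
  }
  base <- default_spec(family)
  unknown <- setdiff(names(params), .allowed_params[[family]])
  if (length(unknown) > 0L) {
    stop("unknown hyperparameter(s) for ", family, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  base$params[names(params)] <- params
  if (!is.null(seed)) base$seed <- as.integer(seed)
  base
}

#' Default configuration of each classifier family
#'
#' Returns the tuned configurations the predictor ships with:
#' random forest with 50 trees of maximum depth 25, out-of-bag scoring and
#' a sqrt feature-subset rule; XGB with 100 rounds of depth 9 and seed 0;
#' the leaf-wise histogram gradient-boosting machine (lgbm) with library
#' defaults and seed 42; extremely randomised trees with 100 unlimited-depth
#' trees; bagging of 10 full-feature trees; and a stacking ensemble whose
#' bases are xgb, random forest, logistic regression and the leaf-wise GBM,
#' with a logistic meta-learner fed by out-of-fold base scores.
#'
#' `warm_start` and `n_jobs` are carried in the specification for fidelity
#' to that tuning but are inert here: the package never refits
#' incrementally, and training is single-threaded so that a fixed seed
#' gives bit-identical models.
#'
#' @param family Classifier family name.
#' @return A `classifier_spec`.
#' @export
#' @examples
#' default_spec("random_forest")$params$n_estimators  # 50
default_spec <- function(family) {
  specs <- list(
    random_forest = list(
      params = list(n_estimators = 50L, max_depth = 25L, oob_score = TRUE,
                    n_jobs = -1L, warm_start = TRUE, max_features = "sqrt"),
      seed = 1L),
    xgb = list(
      params = list(n_estimators = 100L, max_depth = 9L,
                    learning_rate = 0.3),
      seed = 0L),
    lgbm = list(
      params = list(n_estimators = 100L, num_leaves = 31L,
                    learning_rate = 0.1),
      seed = 42L),
    extra_trees = list(
      params = list(n_estimators = 100L, max_depth = NULL,
                    oob_score = FALSE, warm_start = FALSE),
      seed = 1L),
    bagging = list(
      params = list(n_estimators = 10L, oob_score = FALSE,
                    warm_start = FALSE),
      seed = 1L),
    stacking = list(
      params = list(base_families = c("xgb", "random_forest", "logistic",
                                      "lgbm"),
                    meta_family = "logistic", internal_folds = 5L),
      seed = 1L),
    logistic = list(
      params = list(alpha = 0, lambda = 1e-3),
      seed = 1L))
  if (length(family) != 1L || !family %in% names(specs)) {
    stop("unknown classifier family: ", paste(family, collapse = ", "),
         call. = FALSE)
  }
  structure(c(list(family = family), specs[[family]]),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat("Classifier spec:", x$family, "(seed", x$seed, ")\n")
  p <- x$params
  for (nm in names(p)) {
    v <- p[[nm]]
    cat("  ", nm, " = ", if (is.null(v)) "NULL" else
      paste(v, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Build a stacking specification
#'
#' The meta-learner is trained on leakage-free meta-features: out-of-fold
#' scores of each base learner from stratified internal folds, so no base
#' score fed to the meta-model was produced by a model that saw that row.
#'
#' @param base_families Character vector of at least two base families.
#' @param meta_family Meta-learner family (default `"logistic"`).
#' @param internal_folds Number of stratified internal folds (default 5).
#' @param seed Integer seed.
#' @return A `classifier_spec` with family `"stacking"`.
#' @export
build_stacking <- function(base_families = c("xgb", "random_forest",
                                             "logistic", "lgbm"),
                           meta_family = "logistic", internal_folds = 5L,
                           seed = 1L) {
  if (length(base_families) < 2L) {
    stop("stacking needs at least 2 base learners", call. = FALSE)
  }
  bad <- setdiff(c(base_families, meta_family),
                 setdiff(CLASSIFIER_FAMILIES, "stacking"))
  if (length(bad) > 0L) {
    stop("unknown stacking component(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  classifier_spec("stacking",
                  list(base_families = base_families,
                       meta_family = meta_family,
                       internal_folds = as.integer(internal_folds)),
                  seed = seed)
}

# ---- fitting -------------------------------------------------------------

check_training_table <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(table$labels)) {
    stop("training requires a labeled feature table", call. = FALSE)
  }
  if (length(unique(table$labels)) < 2L) {
    stop("training requires both classes to be present", call. = FALSE)
  }
  if (!all(is.finite(table$matrix))) {
    stop("feature table contains non-finite values", call. = FALSE)
  }
  invisible(table)
}

fit_single <- function(family, params, seed, X, y) {
  set.seed(seed)
  switch(family,
    random_forest = ranger::ranger(
      x = X, y = factor(y, levels = c(0L, 1L)),
      num.trees = params$n_estimators, max.depth = params$max_depth,
      mtry = floor(sqrt(ncol(X))), oob.error = isTRUE(params$oob_score),
      probability = TRUE, seed = seed, num.threads = 1L),
    extra_trees = ranger::ranger(
      x = X, y = factor(y, levels = c(0L, 1L)),
      num.trees = params$n_estimators,
      max.depth = if (is.null(params$max_depth)) 0L else params$max_depth,
      splitrule = "extratrees", num.random.splits = 1L,
      replace = FALSE, sample.fraction = 1,
      mtry = floor(sqrt(ncol(X))), oob.error = isTRUE(params$oob_score),
      probability = TRUE, seed = seed, num.threads = 1L),
    bagging = ranger::ranger(
      x = X, y = factor(y, levels = c(0L, 1L)),
      num.trees = params$n_estimators, mtry = ncol(X),
      replace = TRUE, sample.fraction = 1,
      oob.error = isTRUE(params$oob_score),
      probability = TRUE, seed = seed, num.threads = 1L),
    xgb = xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = params$max_depth,
                    eta = params$learning_rate,
                    nthread = 1L, seed = seed),
      data = xgboost::xgb.DMatrix(X, label = y),
      nrounds = params$n_estimators, verbose = 0),
    lgbm = xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    tree_method = "hist", grow_policy = "lossguide",
                    max_leaves = params$num_leaves, max_depth = 0L,
                    eta = params$learning_rate,
                    nthread = 1L, seed = seed),
      data = xgboost::xgb.DMatrix(X, label = y),
      nrounds = params$n_estimators, verbose = 0),
    logistic = glmnet::glmnet(
      x = X, y = factor(y, levels = c(0L, 1L)), family = "binomial",
      alpha = params$alpha,
      lambda = sort(c(params$lambda, params$lambda * c(100, 10)),
                    decreasing = TRUE)),
    stop("unsupported single-learner family: ", family, call. = FALSE))
}

predict_single <- function(family, params, fit, X) {
  switch(family,
    random_forest = ,
    extra_trees = ,
    bagging = {
      pr <- stats::predict(fit, data = X, num.threads = 1L)$predictions
      pr[, "1"]
    },
    xgb = ,
    lgbm = stats::predict(fit, xgboost::xgb.DMatrix(X)),
    logistic = as.numeric(stats::predict(fit, newx = X, s = params$lambda,
                                         type = "response")),
    stop("unsupported single-learner family: ", family, call. = FALSE))
}

# Stratified fold assignment: within each class, a random permutation is
# dealt round-robin over folds, so per-fold class proportions are within
# one sample of the global proportions.
stratified_folds <- function(labels, k) {
  if (any(table(labels) < k)) {
    stop("each class needs at least k = ", k, " rows", call. = FALSE)
  }
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Out-of-fold scores of one base learner over stratified folds. Generic in
# (fitfun, predfun) so the no-leakage property is directly testable with
# substitute learners.
oof_scores <- function(X, y, fold, fitfun, predfun) {
  out <- numeric(length(y))
  for (f in sort(unique(fold))) {
    test <- fold == f
    fit <- fitfun(X[!test, , drop = FALSE], y[!test])
    out[test] <- predfun(fit, X[test, , drop = FALSE])
  }
  out
}

fit_stacking <- function(params, seed, X, y) {
  set.seed(seed)
  fold <- stratified_folds(y, params$internal_folds)
  bases <- params$base_families
  meta_X <- matrix(0, nrow(X), length(bases),
                   dimnames = list(NULL, bases))
  for (b in seq_along(bases)) {
    bspec <- default_spec(bases[b])
    meta_X[, b] <- oof_scores(
      X, y, fold,
      fitfun = function(Xt, yt) fit_single(bases[b], bspec$params,
                                           seed + b, Xt, yt),
      predfun = function(fit, Xt) predict_single(bases[b], bspec$params,
                                                 fit, Xt))
  }
  base_fits <- lapply(seq_along(bases), function(b) {
    bspec <- default_spec(bases[b])
    fit_single(bases[b], bspec$params, seed + b, X, y)
  })
  mspec <- default_spec(params$meta_family)
  meta_fit <- fit_single(params$meta_family, mspec$params, seed, meta_X, y)
  list(base_families = bases, base_fits = base_fits, meta_fit = meta_fit,
       meta_spec = mspec)
}

predict_stacking <- function(params, fit, X) {
  meta_X <- vapply(seq_along(fit$base_families), function(b) {
    bspec <- default_spec(fit$base_families[b])
    predict_single(fit$base_families[b], bspec$params, fit$base_fits[[b]], X)
  }, numeric(nrow(X)))
  meta_X <- matrix(meta_X, nrow = nrow(X),
                   dimnames = list(NULL, fit$base_families))
  predict_single(fit$meta_spec$family, fit$meta_spec$params, fit$meta_fit,
                 meta_X)
}

#' Fit a classifier on a labeled feature table
#'
#' Trains the configuration described by a [classifier_spec()] on a
#' labeled [feature_table()]. Training is deterministic given the spec
#' seed and the table. The fitted model remembers the table's layout tag
#' and refuses to score tables encoded under a different layout.
#'
#' @param spec A `classifier_spec` (or family name, taken through
#'   [default_spec()]).
#' @param table A labeled `feature_table` with both classes present and
#'   finite entries.
#' @return A `driver_model` object.
#' @export
#' @examples
#' \donttest{
#' ds <- generate_dataset(synthetic_config(n_per_class = 15,
#'   length_range = c(60, 120), signal = "strong", seed = 1))
#' tab <- encode_dataset(ds)
#' fit <- fit_classifier(default_spec("random_forest"), tab)
#' mean(predict(fit, tab, type = "class") == tab$labels)
#' }
fit_classifier <- function(spec, table) {
  if (is.character(spec)) spec <- default_spec(spec)
  stopifnot(inherits(spec, "classifier_spec"))
  check_training_table(table)
  X <- table$matrix
  y <- table$labels
  t0 <- Sys.time()
  fit <- if (spec$family == "stacking") {
    fit_stacking(spec$params, spec$seed, X, y)
  } else {
    fit_single(spec$family, spec$params, spec$seed, X, y)
  }
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  message(sprintf(
    "trained %s on %d rows (%d positive / %d negative) in %.2f s",
    spec$family, length(y), sum(y == 1L), sum(y == 0L), elapsed))
  structure(list(spec = spec, fit = fit, layout_tag = table$layout_tag,
                 classes = c(0L, 1L), n_train = length(y),
                 train_seconds = elapsed),
            class = "driver_model")
}

check_layout <- function(model, table) {
  stopifnot(inherits(model, "driver_model"), inherits(table, "feature_table"))
  if (!identical(model$layout_tag, table$layout_tag)) {
    stop("feature layout mismatch: model was trained on '",
         model$layout_tag, "' but the table is '", table$layout_tag, "'",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Predict from a fitted driver-gene classifier
#'
#' @param object A `driver_model`.
#' @param table A `feature_table` with the same layout tag the model was
#'   trained on.
#' @param type `"response"` for positive-class scores in `[0, 1]`,
#'   `"class"` for 0/1 labels (`1` iff score >= `threshold`).
#' @param threshold Decision threshold for `type = "class"`.
#' @param ... Unused.
#' @return Numeric scores or integer labels, one per table row.
#' @export
predict.driver_model <- function(object, table,
                                 type = c("response", "class"),
                                 threshold = 0.5, ...) {
  type <- match.arg(type)
  check_layout(object, table)
  X <- table$matrix
  scores <- if (object$spec$family == "stacking") {
    predict_stacking(object$spec$params, object$fit, X)
  } else {
    predict_single(object$spec$family, object$spec$params, object$fit, X)
  }
  stopifnot(all(is.finite(scores)))
  if (type == "response") return(scores)
  as.integer(scores >= threshold)
}

#' Positive-class scores for a feature table
#' @param model A `driver_model`.
#' @param table A `feature_table`.
#' @return Numeric vector of scores in `[0, 1]`.
#' @export
predict_scores <- function(model, table) {
  stats::predict(model, table, type = "response")
}

#' Thresholded 0/1 labels for a feature table
#' @inheritParams predict_scores
#' @param threshold Decision threshold (label 1 iff score >= threshold).
#' @return Integer vector of 0/1 labels.
#' @export
predict_labels <- function(model, table, threshold = 0.5) {
  stats::predict(model, table, type = "class", threshold = threshold)
}

#' @export
print.driver_model <- function(x, ...) {
  cat("Driver-gene classifier:", x$spec$family, "\n")
  cat("Trained on", x$n_train, "rows; layout", x$layout_tag, "; seed",
      x$spec$seed, "\n")
  invisible(x)
}

#' @export
summary.driver_model <- function(object, ...) {
  print(object)
  print(object$spec)
  invisible(object)
}

#' Save / load a fitted model
#'
#' The file embeds a manifest (spec, layout tag, package version) next to
#' the fitted state, so a loaded model still enforces layout compatibility.
#'
#' @param model A `driver_model`.
#' @param path File path.
#' @return `save_model` returns `path` invisibly; `load_model` returns
#'   the `driver_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "driver_model"))
  payload <- list(manifest = list(
    family = model$spec$family, layout_tag = model$layout_tag,
    seed = model$spec$seed,
    package_version = as.character(utils::packageVersion("seqmoments"))),
    model = model)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- readRDS(path)
  if (!is.list(payload) || !inherits(payload$model, "driver_model")) {
    stop("not a saved driver model: ", path, call. = FALSE)
  }
  payload$model
}
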