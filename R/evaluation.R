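# Metrics (Acc, Sn, Sp, MCC), ROC/AUC and the three validation protocols:
# self-consistency, repeated independent 70/30 splits and stratified
# k-fold cross-validation. Reports are classed S3 objects serialisable to
# JSON and CSV.

#' Confusion counts for binary predictions
#'
#' Positive class is 1. In the driver/passenger vocabulary: tp + fn is
#' the number of actual driver genes, tn + fp the actual passengers, fn
#' the drivers predicted as passengers and fp the passengers predicted as
#' drivers.
#'
#' @param y_true,y_pred Equal-length 0/1 vectors.
#' @return List with integer fields `tp`, `fn`, `tn`, `fp` (class
#'   `confusion_counts`).
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1))) {
    stop("confusion counts need binary 0/1 inputs", call. = FALSE)
  }
  structure(list(tp = sum(y_true == 1 & y_pred == 1),
                 fn = sum(y_true == 1 & y_pred == 0),
                 tn = sum(y_true == 0 & y_pred == 0),
                 fp = sum(y_true == 0 & y_pred == 1)),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Sensitivity `sn = tp/(tp+fn)` (accuracy on actual positives),
#' specificity `sp = tn/(tn+fp)` (accuracy on actual negatives), overall
#' accuracy `acc = (tp+tn)/N`, and the Matthews correlation coefficient
#' `mcc = (tp*tn - fp*fn)/sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))` with
#' `mcc = 0` when any denominator factor vanishes. When a class is absent
#' the corresponding rate is reported as `NaN` with a warning.
#'
#' Acc, Sn and Sp are kept on the `[0, 1]` scale here; reports convert to
#' percent.
#'
#' @param counts A `confusion_counts` object (or list with tp/fn/tn/fp).
#' @return Named numeric vector with elements `acc`, `sn`, `sp`, `mcc`.
#' @export
metrics <- function(counts) {
  tp <- counts$tp; fn <- counts$fn; tn <- counts$tn; fp <- counts$fp
  n <- tp + fn + tn + fp
  if (n == 0) stop("all confusion counts are zero", call. = FALSE)
  if (tp + fn == 0 || tn + fp == 0) {
    warning("a class is absent; its rate is undefined (NaN)")
  }
  sn <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  acc <- (tp + tn) / n
  denom <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom)
  c(acc = acc, sn = sn, sp = sp, mcc = mcc)
}

#' ROC points and AUC
#'
#' Sweeps every observed score as a decision threshold (predict positive
#' when score >= threshold), yielding one (fpr, tpr) point per threshold
#' plus the (0,0) and (1,1) anchors; AUC is the trapezoid-rule area under
#' the resulting curve.
#'
#' @param y_true 0/1 vector with both classes present.
#' @param scores Finite numeric scores, higher = more positive.
#' @return List with `points` (data frame: threshold, fpr, tpr) and `auc`.
#' @export
roc_points <- function(y_true, scores) {
  if (length(unique(y_true)) < 2L) {
    stop("ROC needs both classes present", call. = FALSE)
  }
  if (!all(is.finite(scores)) || length(scores) != length(y_true)) {
    stop("scores must be finite and parallel to y_true", call. = FALSE)
  }
  np <- sum(y_true == 1)
  nn <- sum(y_true == 0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & y_true == 1) / np, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & y_true == 0) / nn, 0)
  pts <- data.frame(threshold = thr, fpr = fpr, tpr = tpr)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

new_eval_report <- function(protocol, runs, rocs, seed, description,
                            spec_family) {
  per_run <- do.call(rbind, lapply(runs, function(r) r$metrics))
  aggregate <- colMeans(per_run)
  structure(list(protocol = protocol, spec_family = spec_family,
                 runs = runs, per_run = as.data.frame(per_run),
                 aggregate = aggregate,
                 roc = rocs, seed = seed, description = description),
            class = "eval_report")
}

run_one <- function(spec, train_tab, test_tab) {
  model <- fit_classifier(spec, train_tab)
  scores <- predict_scores(model, test_tab)
  pred <- as.integer(scores >= 0.5)
  cm <- confusion(test_tab$labels, pred)
  list(confusion = unclass(cm), metrics = metrics(cm),
       roc = roc_points(test_tab$labels, scores))
}

subset_table <- function(table, idx) {
  feature_table(table$matrix[idx, , drop = FALSE], ids = table$ids[idx],
                labels = table$labels[idx], layout_tag = table$layout_tag)
}

#' Self-consistency validation
#'
#' Trains on every row and evaluates on the same rows -- the basic sanity
#' protocol for a sequence predictor (a flexible model is expected to
#' reproduce its training labels; failure indicates an encoding or
#' fitting defect, success says nothing about generalisation).
#'
#' @param table Labeled [feature_table()].
#' @param spec [classifier_spec()] or family name.
#' @return An `eval_report` with a single run.
#' @export
self_consistency <- function(table, spec) {
  if (is.character(spec)) spec <- default_spec(spec)
  check_training_table(table)
  run <- run_one(spec, table, table)
  new_eval_report("self_consistency", list(run),
                  list(list(points = run$roc$points, auc = run$roc$auc)),
                  seed = spec$seed,
                  description = "train and evaluate on all rows",
                  spec_family = spec$family)
}

# Stratified train/test split: per class, a random `fraction` of rows go
# to training.
stratified_split <- function(labels, fraction) {
  train <- logical(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_tr <- round(fraction * length(idx))
    n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
    train[sample(idx, n_tr)] <- TRUE
  }
  train
}

#' Repeated independent train/test evaluation
#'
#' Repeats a stratified random split (default 70% training / 30% testing,
#' 10 repeats), reporting per-repeat metrics and their mean. Splits are
#' reproducible from `seed`.
#'
#' @param table Labeled [feature_table()] with at least 2 rows per class.
#' @param spec [classifier_spec()] or family name.
#' @param train_fraction Fraction of each class used for training.
#' @param repeats Number of reseeded splits (>= 1).
#' @param seed Integer seed for the split sequence.
#' @return An `eval_report`.
#' @export
independent_eval <- function(table, spec, train_fraction = 0.70,
                             repeats = 10L, seed = 1L) {
  if (is.character(spec)) spec <- default_spec(spec)
  check_training_table(table)
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop("train_fraction must lie in (0, 1)", call. = FALSE)
  }
  if (repeats < 1L) stop("repeats must be >= 1", call. = FALSE)
  if (any(table(table$labels) < 2L)) {
    stop("each class needs at least 2 rows", call. = FALSE)
  }
  runs <- vector("list", repeats)
  rocs <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    set.seed(seed + r - 1L)
    train <- stratified_split(table$labels, train_fraction)
    runs[[r]] <- run_one(spec, subset_table(table, train),
                         subset_table(table, !train))
    rocs[[r]] <- list(points = runs[[r]]$roc$points,
                      auc = runs[[r]]$roc$auc)
  }
  new_eval_report("independent", runs, rocs, seed,
                  sprintf("%d stratified splits, %.0f%% training",
                          repeats, 100 * train_fraction),
                  spec$family)
}

#' Stratified k-fold cross-validation
#'
#' Partitions the rows into k stratified folds; each fold is tested once
#' with the remaining k-1 folds as training data, so every row is tested
#' exactly once. Per-fold metrics and their mean are reported.
#'
#' @param table Labeled [feature_table()] with at least k rows per class.
#' @param spec [classifier_spec()] or family name.
#' @param k Number of folds (>= 2); 5 and 10 are the conventional
#'   choices.
#' @param seed Integer seed for the fold assignment.
#' @return An `eval_report`.
#' @export
kfold_eval <- function(table, spec, k = 10L, seed = 1L) {
  if (is.character(spec)) spec <- default_spec(spec)
  check_training_table(table)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  set.seed(seed)
  fold <- stratified_folds(table$labels, k)
  runs <- vector("list", k)
  rocs <- vector("list", k)
  for (f in seq_len(k)) {
    test <- fold == f
    runs[[f]] <- run_one(spec, subset_table(table, !test),
                         subset_table(table, test))
    rocs[[f]] <- list(points = runs[[f]]$roc$points,
                      auc = runs[[f]]$roc$auc)
  }
  rep <- new_eval_report("kfold", runs, rocs, seed,
                         sprintf("stratified %d-fold cross-validation", k),
                         spec$family)
  rep$fold <- fold
  rep
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Evaluation report --", x$protocol, "(", x$description, ")\n")
  cat("Classifier:", x$spec_family, "; seed:", x$seed, ";",
      length(x$runs), "run(s)\n")
  agg <- x$aggregate
  cat(sprintf("Mean metrics: Acc %.2f%%  Sn %.2f%%  Sp %.2f%%  MCC %.4f\n",
              100 * agg[["acc"]], 100 * agg[["sn"]], 100 * agg[["sp"]],
              agg[["mcc"]]))
  cat(sprintf("Mean AUC: %.4f\n",
              mean(vapply(x$roc, function(r) r$auc, 0))))
  invisible(x)
}

#' @export
summary.eval_report <- function(object, ...) {
  print(object)
  cat("\nPer-run metrics (percent; MCC on [-1,1]):\n")
  print(round(as.data.frame.eval_report(object), 3))
  invisible(object)
}

#' @export
as.data.frame.eval_report <- function(x, ...) {
  df <- x$per_run
  df$acc <- 100 * df$acc
  df$sn <- 100 * df$sn
  df$sp <- 100 * df$sp
  df$auc <- vapply(x$roc, function(r) r$auc, 0)
  df$run <- seq_len(nrow(df))
  df[, c("run", "acc", "sn", "sp", "mcc", "auc")]
}

#' Plot ROC curves of an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.eval_report <- function(x, ...) {
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = paste("ROC --", x$protocol, "--", x$spec_family),
                 ...)
  graphics::abline(0, 1, lty = 3, col = "grey60")
  for (r in x$roc) {
    graphics::lines(r$points$fpr, r$points$tpr, col = "steelblue")
  }
  graphics::legend("bottomright", bty = "n",
                   legend = sprintf("mean AUC = %.3f",
                                    mean(vapply(x$roc, function(r) r$auc,
                                                0))))
  invisible(x)
}

#' Serialise / restore an evaluation report
#'
#' `write_report` writes the full report (counts, per-run metrics,
#' aggregate, ROC points, seeds, description) as JSON, plus an optional
#' CSV summary table (one row per run, metrics in percent). Round-trip
#' through `read_report` is lossless.
#'
#' @param report An `eval_report`.
#' @param json_path Output JSON path.
#' @param csv_path Optional CSV summary path.
#' @return `json_path`, invisibly.
#' @export
write_report <- function(report, json_path, csv_path = NULL) {
  stopifnot(inherits(report, "eval_report"))
  payload <- list(
    protocol = report$protocol,
    spec_family = report$spec_family,
    seed = report$seed,
    description = report$description,
    confusion = do.call(rbind, lapply(report$runs, function(r)
      as.data.frame(r$confusion))),
    metrics = report$per_run,
    auc = vapply(report$roc, function(r) r$auc, 0),
    roc_points = lapply(report$roc, function(r) r$points),
    aggregate = as.list(report$aggregate))
  if (!is.null(report$fold)) payload$fold <- report$fold
  jsonlite::write_json(payload, json_path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns", na = "null")
  if (!is.null(csv_path)) {
    utils::write.csv(as.data.frame.eval_report(report), csv_path,
                     row.names = FALSE)
  }
  invisible(json_path)
}

#' @rdname write_report
#' @export
read_report <- function(json_path) {
  p <- jsonlite::read_json(json_path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  n_runs <- length(p$metrics$acc)
  # Inf thresholds serialise as null; restore them
  fix_pts <- function(pt) {
    pt <- as.data.frame(pt)
    pt$threshold[is.na(pt$threshold)] <- Inf
    pt[, c("threshold", "fpr", "tpr")]
  }
  runs <- lapply(seq_len(n_runs), function(i) {
    pts <- fix_pts(lapply(p$roc_points[[i]], unlist))
    list(confusion = lapply(p$confusion, `[[`, i),
         metrics = c(acc = p$metrics$acc[i], sn = p$metrics$sn[i],
                     sp = p$metrics$sp[i], mcc = p$metrics$mcc[i]),
         roc = list(points = pts, auc = p$auc[i]))
  })
  rocs <- lapply(runs, function(r) r$roc)
  rep <- new_eval_report(p$protocol, runs, rocs, p$seed, p$description,
                         p$spec_family)
  if (!is.null(p$fold)) rep$fold <- p$fold
  rep
}
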