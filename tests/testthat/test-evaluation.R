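# Metrics, ROC, validation protocols and report serialisation.

test_that("confusion counts follow the positive-class-1 convention", {
  cm <- confusion(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_identical(unclass(cm)[c("tp", "fn", "tn", "fp")],
                   list(tp = 2L, fn = 0L, tn = 2L, fp = 0L))
  cm2 <- confusion(c(1, 0), c(0, 1))
  expect_identical(c(cm2$tp, cm2$fn, cm2$tn, cm2$fp), c(0L, 1L, 0L, 1L))
  set.seed(41)
  y <- rbinom(1000, 1, 0.4)
  p <- rbinom(1000, 1, 0.5)
  cm3 <- confusion(y, p)
  expect_identical(cm3$tp + cm3$fn + cm3$tn + cm3$fp, 1000L)
  expect_error(confusion(c(1, 0), c(1)), "equal length")
  expect_error(confusion(c(1, 2), c(1, 0)), "binary")
})

test_that("metrics hit the stated limits and the formula oracle", {
  perfect <- metrics(confusion(c(1, 1, 0, 0), c(1, 1, 0, 0)))
  expect_equal(unname(perfect), c(1, 1, 1, 1))
  inverted <- metrics(confusion(c(1, 1, 0, 0), c(0, 0, 1, 1)))
  expect_equal(inverted[["acc"]], 0)
  expect_equal(inverted[["mcc"]], -1)

  m <- metrics(list(tp = 50, fn = 5, tn = 40, fp = 10))
  expect_equal(m[["acc"]], 90 / 105)
  expect_equal(m[["sn"]], 50 / 55)
  expect_equal(m[["sp"]], 40 / 50)
  mcc_oracle <- (50 * 40 - 10 * 5) /
    sqrt((50 + 10) * (50 + 5) * (40 + 10) * (40 + 5))
  expect_equal(m[["mcc"]], mcc_oracle)

  expect_equal(metrics(list(tp = 3, fn = 0, tn = 2, fp = 0))[["mcc"]], 1)
  # a vanishing denominator factor pins MCC at 0
  expect_equal(metrics(list(tp = 0, fn = 2, tn = 2, fp = 0))[["mcc"]], 0)
  expect_error(metrics(list(tp = 0, fn = 0, tn = 0, fp = 0)), "zero")
  expect_warning(m1 <- metrics(list(tp = 2, fn = 0, tn = 0, fp = 0)),
                 "absent")
  expect_true(is.nan(m1[["sp"]]))
})

test_that("self-prediction scores perfectly for any non-degenerate labels", {
  set.seed(42)
  for (rep in 1:20) {
    y <- c(0L, 1L, rbinom(20, 1, runif(1, 0.2, 0.8)))
    expect_equal(unname(metrics(confusion(y, y))), c(1, 1, 1, 1))
  }
})

test_that("accuracy is the prevalence-weighted blend of Sn and Sp", {
  set.seed(43)
  for (rep in 1:200) {
    counts <- list(tp = sample(0:50, 1), fn = sample(0:50, 1),
                   tn = sample(0:50, 1), fp = sample(0:50, 1))
    a_pos <- counts$tp + counts$fn
    a_neg <- counts$tn + counts$fp
    if (a_pos == 0 || a_neg == 0) next
    m <- metrics(counts)
    expect_equal(m[["acc"]],
                 (a_pos * m[["sn"]] + a_neg * m[["sp"]]) / (a_pos + a_neg))
  }
})

test_that("ROC endpoints, degenerate scores and the pROC cross-check", {
  y <- c(1, 1, 1, 0, 0, 0)
  expect_equal(roc_points(y, c(.9, .8, .7, .3, .2, .1))$auc, 1)
  expect_equal(roc_points(y, rep(0.5, 6))$auc, 0.5)
  expect_equal(roc_points(y, c(.1, .2, .3, .7, .8, .9))$auc, 0)
  set.seed(44)
  yy <- rbinom(80, 1, 0.5)
  yy[1:2] <- c(0, 1)
  ss <- runif(80)
  ours <- roc_points(yy, ss)
  independent <- as.numeric(pROC::auc(pROC::roc(yy, ss, quiet = TRUE,
                                                direction = "<")))
  expect_equal(ours$auc, independent, tolerance = 1e-12)
  expect_true(all(diff(ours$points$fpr) >= 0))
  expect_true(all(diff(ours$points$tpr) >= 0))
  expect_error(roc_points(c(1, 1), c(.2, .3)), "both classes")
})

test_that("self-consistency reproduces training labels on separable data", {
  tab <- make_sep_table(15, seed = 45)
  for (fam in c("random_forest", "bagging")) {
    rep <- quiet(self_consistency(tab, fam))
    expect_equal(unname(rep$aggregate), c(1, 1, 1, 1))
  }
  one_class <- feature_table(tab$matrix[1:10, ], ids = tab$ids[1:10],
                             labels = rep(1L, 10))
  expect_error(quiet(self_consistency(one_class, "random_forest")),
               "both classes")
})

test_that("independent splits are stratified and reproducible", {
  labels <- rep(c(1L, 0L), c(60, 40))
  for (s in 1:5) {
    set.seed(s)
    tr <- seqmoments:::stratified_split(labels, 0.7)
    expect_identical(sum(tr & labels == 1L), 42L)
    expect_identical(sum(tr & labels == 0L), 28L)
  }
  tab <- make_sep_table(10, seed = 46)
  r1 <- quiet(independent_eval(tab, "xgb", repeats = 2, seed = 9))
  r2 <- quiet(independent_eval(tab, "xgb", repeats = 2, seed = 9))
  expect_identical(r1$per_run, r2$per_run)
  expect_error(quiet(independent_eval(tab, "xgb", repeats = 0)), ">= 1")
  expect_error(quiet(independent_eval(tab, "xgb", train_fraction = 1.2)),
               "0, 1")
})

test_that("k-fold partitions test every row exactly once, stratified", {
  tab <- make_sep_table(15, seed = 47)
  rep <- quiet(kfold_eval(tab, "random_forest", k = 5, seed = 2))
  expect_identical(sort(unique(rep$fold)), 1:5)
  expect_identical(tabulate(rep$fold), rep.int(6L, 5))
  for (f in 1:5) {
    expect_identical(sum(tab$labels[rep$fold == f]), 3L)
  }
  total_tested <- sum(vapply(rep$runs, function(r)
    with(r$confusion, tp + fn + tn + fp), 0))
  expect_identical(total_tested, 30)
  expect_error(quiet(kfold_eval(tab, "random_forest", k = 16)),
               "at least k")
  expect_error(quiet(kfold_eval(tab, "random_forest", k = 1)), ">= 2")
})

test_that("reports round-trip losslessly through JSON and summarise to CSV", {
  tab <- make_sep_table(10, seed = 48)
  rep <- quiet(independent_eval(tab, "random_forest", repeats = 3,
                                seed = 4))
  json <- withr::local_tempfile(fileext = ".json")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_report(rep, json, csv)
  back <- read_report(json)
  expect_equal(back$per_run, rep$per_run)
  expect_equal(back$aggregate, rep$aggregate)
  expect_identical(back$protocol, rep$protocol)
  expect_identical(back$spec_family, rep$spec_family)
  for (i in seq_along(rep$runs)) {
    expect_equal(back$runs[[i]]$confusion, rep$runs[[i]]$confusion)
    expect_equal(back$roc[[i]]$auc, rep$roc[[i]]$auc)
    expect_equal(back$roc[[i]]$points, rep$roc[[i]]$points)
  }
  df <- utils::read.csv(csv)
  expect_identical(names(df), c("run", "acc", "sn", "sp", "mcc", "auc"))
  expect_identical(nrow(df), 3L)
})
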