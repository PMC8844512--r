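test_that("confusion_counts tallies the four cells", {
  expect_equal(confusion_counts(c(1, 1, 0, 0), c(1, 1, 0, 0)),
               c(TP = 2L, TN = 2L, FP = 0L, FN = 0L))
  expect_equal(confusion_counts(c(1, 0), c(0, 1)),
               c(TP = 0L, TN = 0L, FP = 1L, FN = 1L))
  expect_equal(confusion_counts(c(1, 1, 1, 0), c(1, 0, 1, 0)),
               c(TP = 2L, TN = 1L, FP = 0L, FN = 1L))
  expect_error(confusion_counts(c(1, 0), c(1)), "lengths differ")
})

test_that("metrics reproduces the printed formulas including degenerate cases", {
  perfect <- metrics(c(TP = 50, TN = 50, FP = 0, FN = 0))
  expect_equal(unname(perfect), c(100, 100, 100, 1))

  m <- metrics(c(TP = 98, TN = 96, FP = 4, FN = 2))
  expect_equal(unname(m[c("Sn", "Sp", "Acc")]), c(98, 96, 97))
  expect_equal(unname(m["MCC"]), 0.9402, tolerance = 5e-5)

  degen <- metrics(c(TP = 0, TN = 10, FP = 0, FN = 10))
  expect_equal(unname(degen), c(0, 100, 50, 0))  # MCC zero-denominator -> 0

  expect_error(metrics(c(TP = 0, TN = 0, FP = 0, FN = 0)), "empty")
})

test_that("metrics invariants: label swap maps Sn<->Sp, keeps Acc and MCC", {
  set.seed(8)
  for (i in 1:20) {
    y <- sample(0:1, 40, replace = TRUE)
    p <- sample(0:1, 40, replace = TRUE)
    if (length(unique(y)) < 2) next
    m <- metrics(confusion_counts(y, p))
    sw <- metrics(confusion_counts(1 - y, 1 - p))
    expect_equal(unname(sw["Sn"]), unname(m["Sp"]))
    expect_equal(unname(sw["Sp"]), unname(m["Sn"]))
    expect_equal(unname(sw["Acc"]), unname(m["Acc"]))
    expect_equal(unname(sw["MCC"]), unname(m["MCC"]), tolerance = 1e-12)
    expect_true(m["MCC"] >= -1 && m["MCC"] <= 1)
  }
})

test_that("auroc implements the Mann-Whitney formulation with tie rule 1/2", {
  expect_equal(auroc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(auroc(c(1, 1, 0, 0), rep(0.5, 4)), 0.5)
  expect_equal(auroc(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1)), 0.75)
  expect_error(auroc(c(1, 1), c(0.2, 0.4)), "both classes")
})

test_that("rank-based auroc equals brute-force pairwise comparison", {
  brute <- function(y, s) {
    ps <- s[y == 1]; ns <- s[y == 0]
    wins <- 0
    for (p in ps) for (q in ns) wins <- wins + (p > q) + 0.5 * (p == q)
    wins / (length(ps) * length(ns))
  }
  set.seed(77)
  for (n in 2:8) {
    for (rep in 1:10) {
      y <- sample(0:1, n, replace = TRUE)
      if (length(unique(y)) < 2) next
      s <- sample(seq(0.1, 0.9, by = 0.2), n, replace = TRUE)  # forces ties
      expect_equal(auroc(y, s), brute(y, s))
    }
  }
})

test_that("auroc is invariant under increasing transforms and flips under negation", {
  set.seed(14)
  y <- rep(0:1, each = 25)
  s <- runif(50)
  a <- auroc(y, s)
  expect_equal(auroc(y, exp(3 * s) + 2), a)
  expect_equal(auroc(y, -s), 1 - a)
})

test_that("roc_curve is monotone, anchored and consistent with auroc", {
  set.seed(19)
  y <- rep(0:1, each = 30)
  s <- runif(60)
  cur <- roc_curve(y, s)
  expect_equal(unlist(cur[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(cur[nrow(cur), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(cur$fpr) >= 0) && all(diff(cur$tpr) >= 0))
  area <- sum(diff(cur$fpr) * (cur$tpr[-1] + cur$tpr[-nrow(cur)]) / 2)
  expect_equal(area, auroc(y, s), tolerance = 1e-12)

  # perfect scores pass through (0, 1); binary scores give a 3-point curve
  perf <- roc_curve(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
  expect_true(any(perf$fpr == 0 & perf$tpr == 1))
  expect_equal(nrow(roc_curve(c(1, 0, 1, 0), c(1, 0, 1, 1))), 3L)
})

test_that("auroc agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  for (i in 1:10) {
    y <- rep(0:1, each = 20)
    s <- round(runif(40), 2)  # rounding introduces occasional ties
    ref <- as.numeric(suppressMessages(pROC::auc(y, s, direction = "<")))
    expect_equal(auroc(y, s), ref, tolerance = 1e-12)
  }
})

test_that("stratified_kfold stratifies exactly and is reproducible", {
  fm <- gauss_fm(n_per = 50L, p = 3L, shift = 1, seed = 40L)
  rep1 <- stratified_kfold(fm, classifier_spec("decision_tree"), k = 10L,
                           seed = 5L)
  for (f in 1:10) {
    expect_equal(sum(fm$y[rep1$folds == f] == 1L), 5L)
    expect_equal(sum(fm$y[rep1$folds == f] == 0L), 5L)
  }
  rep2 <- stratified_kfold(fm, classifier_spec("decision_tree"), k = 10L,
                           seed = 5L)
  expect_identical(rep1$per_fold, rep2$per_fold)
  expect_identical(rep1$mean, rep2$mean)
  expect_error(stratified_kfold(gauss_fm(n_per = 4L), k = 10L),
               "at least k")
})

test_that("well-separated classes reach perfect cross-validated accuracy", {
  fm <- separable_fm(n_per = 30L)
  rep_ <- stratified_kfold(fm, classifier_spec("random_forest",
                                               list(ntree = 100L)),
                           k = 5L, seed = 2L)
  expect_equal(unname(rep_$mean["Acc"]), 100)
  expect_equal(unname(rep_$mean["AUROC"]), 1)
})

test_that("label-shuffled data yields chance-level accuracy (no leakage)", {
  set.seed(60)
  fm0 <- gauss_fm(n_per = 40L, p = 5L, shift = 3, seed = 61L)
  y_shuf <- sample(fm0$y)
  rep_ <- stratified_kfold(feature_matrix(fm0$x, y_shuf),
                           classifier_spec("decision_tree"), k = 5L,
                           seed = 62L)
  # binomial 3-sigma band around 50% for n = 80
  expect_lt(abs(rep_$mean["Acc"] - 50), 3 * 100 * sqrt(0.25 / 80))
})

test_that("cv reports serialize to JSON and Table-style TSV", {
  fm <- separable_fm(n_per = 12L)
  rep_ <- stratified_kfold(fm, classifier_spec("decision_tree"), k = 3L,
                           seed = 1L)
  jp <- tempfile(fileext = ".json"); tp <- tempfile(fileext = ".tsv")
  write_cv_report(rep_, jp, tp)
  parsed <- jsonlite::read_json(jp)
  expect_equal(length(parsed$per_fold), 3L)
  tab <- read.delim(tp)
  expect_equal(names(tab), c("Sn", "Sp", "Acc", "MCC", "AUROC"))
})
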