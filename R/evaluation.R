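# Confusion-matrix metrics, rank-based AUROC, ROC curves and stratified
# k-fold cross-validation.

#' Confusion counts for binary predictions
#'
#' @param y_true,y_pred Binary (0/1) vectors of equal length; positive
#'   class is 1.
#' @return Named integer vector TP, TN, FP, FN.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred lengths differ")
  if (length(y_true) < 1L) stop("no samples to evaluate")
  stopifnot(all(y_true %in% 0:1), all(y_pred %in% 0:1))
  c(TP = sum(y_true == 1L & y_pred == 1L),
    TN = sum(y_true == 0L & y_pred == 0L),
    FP = sum(y_true == 0L & y_pred == 1L),
    FN = sum(y_true == 1L & y_pred == 0L))
}

#' Classification metrics from confusion counts
#'
#' Sensitivity Sn = TP/(TP+FN), specificity Sp = TN/(TN+FP) and accuracy
#' Acc = (TP+TN)/total, all reported in percent; Matthews correlation
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)) on the
#' [-1, 1] scale. A zero MCC denominator yields MCC = 0; a zero Sn or Sp
#' denominator (a class absent from `y_true`) yields NA for that entry.
#'
#' @param counts Named vector from [confusion_counts()].
#' @return Named numeric vector Sn, Sp, Acc (percent), MCC.
#' @examples
#' metrics(c(TP = 98, TN = 96, FP = 4, FN = 2))  # Sn 98, Sp 96, Acc 97
#' @export
metrics <- function(counts) {
  tp <- as.numeric(counts[["TP"]]); tn <- as.numeric(counts[["TN"]])
  fp <- as.numeric(counts[["FP"]]); fn <- as.numeric(counts[["FN"]])
  total <- tp + tn + fp + fn
  if (total == 0) stop("empty confusion matrix")
  sn <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den > 0) (tp * tn - fp * fn) / sqrt(den) else 0
  c(Sn = sn, Sp = sp, Acc = 100 * (tp + tn) / total, MCC = mcc)
}

#' Area under the ROC curve (rank-based)
#'
#' The probability that a uniformly chosen positive sample outscores a
#' uniformly chosen negative one, with ties counted 1/2 — the
#' Mann-Whitney formulation, equal to the trapezoidal area under the ROC
#' curve.
#'
#' @param y_true Binary labels (both classes present).
#' @param scores Numeric scores, higher = more positive.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(y_true, scores) {
  stopifnot(length(y_true) == length(scores), all(y_true %in% 0:1))
  n1 <- sum(y_true == 1L); n0 <- sum(y_true == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)  # average ranks implement the tie = 1/2 rule
  (sum(r[y_true == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' Thresholds at every distinct score value; the curve starts at (0, 0),
#' ends at (1, 1) and is monotone non-decreasing in both coordinates. Its
#' trapezoidal area equals [auroc()].
#'
#' @inheritParams auroc
#' @return Data frame with columns `fpr`, `tpr`.
#' @export
roc_curve <- function(y_true, scores) {
  stopifnot(length(y_true) == length(scores), all(y_true %in% 0:1))
  n1 <- sum(y_true == 1L); n0 <- sum(y_true == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  y <- y_true[ord]; s <- scores[ord]
  cut <- c(which(diff(s) != 0), length(s))  # last index at each threshold
  tpr <- c(0, cumsum(y == 1L)[cut] / n1)
  fpr <- c(0, cumsum(y == 0L)[cut] / n0)
  data.frame(fpr = fpr, tpr = tpr)
}

roc_area <- function(curve)
  sum(diff(curve$fpr) * (curve$tpr[-1] + curve$tpr[-nrow(curve)]) / 2)

# deterministic stratified fold assignment: shuffle within class, deal round-robin
make_folds <- function(y, k, seed) {
  if (min(table(y)) < k)
    stop("each class needs at least k = ", k,
         " samples for stratified k-fold CV; reduce k or add samples")
  fold <- integer(length(y))
  rng <- local({ set.seed(seed); list(p0 = sample(which(y == 0L)),
                                      p1 = sample(which(y == 1L))) })
  fold[rng$p0] <- rep_len(seq_len(k), length(rng$p0))
  fold[rng$p1] <- rep_len(seq_len(k), length(rng$p1))
  fold
}

#' Stratified k-fold cross-validation
#'
#' Splits samples into k class-stratified folds, trains the classifier on
#' k-1 folds and evaluates Sn/Sp/Acc/MCC and AUROC (from the classifier's
#' continuous score) on the held-out fold. Reports per-fold metrics, their
#' unweighted mean, and metrics pooled over the concatenated out-of-fold
#' predictions. Fully reproducible given `seed`.
#'
#' @param fm A labelled `feature_matrix`.
#' @param spec A [classifier_spec()].
#' @param k Number of folds (default 10).
#' @param seed Seed for fold assignment.
#' @return Object of class `cv_report`: `per_fold` (data frame), `mean`
#'   (named vector, unweighted fold mean), `pooled` (named vector over
#'   concatenated predictions), `folds`, `seed`, `spec`, plus pooled
#'   out-of-fold `scores` and `y`.
#' @export
stratified_kfold <- function(fm, spec = classifier_spec("random_forest"),
                             k = 10L, seed = 42L) {
  stopifnot(inherits(fm, "feature_matrix"))
  y <- fm$y
  if (is.null(y) || anyNA(y)) stop("cross-validation needs labelled data")
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  fold <- make_folds(y, k, seed)
  per <- vector("list", k)
  oof_score <- numeric(length(y)); oof_pred <- integer(length(y))
  for (f in seq_len(k)) {
    tr <- fold != f
    model <- train(feature_matrix(fm$x[tr, , drop = FALSE], y[tr]), spec)
    pr <- predict(model, feature_matrix(fm$x[!tr, , drop = FALSE]))
    oof_score[!tr] <- pr$score; oof_pred[!tr] <- pr$label
    m <- metrics(confusion_counts(y[!tr], pr$label))
    per[[f]] <- c(m, AUROC = auroc(y[!tr], pr$score))
  }
  per_fold <- as.data.frame(do.call(rbind, per))
  per_fold$fold <- seq_len(k)
  mean_m <- colMeans(per_fold[, c("Sn", "Sp", "Acc", "MCC", "AUROC")])
  pooled <- c(metrics(confusion_counts(y, oof_pred)),
              AUROC = auroc(y, oof_score))
  structure(list(per_fold = per_fold, mean = mean_m, pooled = pooled,
                 folds = fold, seed = seed, spec = spec,
                 scores = oof_score, y = y),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold stratified CV, %s (seed %d)\n",
              max(x$folds), x$spec$family, x$seed))
  cat("mean over folds:\n")
  print(round(x$mean, 4))
  invisible(x)
}

#' Serialize a CV report
#'
#' Writes the report as JSON (per-fold + mean + pooled) and, optionally,
#' the mean metrics as a one-row TSV with columns Sn, Sp, Acc, MCC, AUROC.
#'
#' @param report A `cv_report`.
#' @param json_path Output JSON path (NULL to skip).
#' @param tsv_path Output TSV path (NULL to skip).
#' @return `report`, invisibly.
#' @export
write_cv_report <- function(report, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(list(per_fold = report$per_fold,
                              mean = as.list(report$mean),
                              pooled = as.list(report$pooled),
                              seed = report$seed,
                              family = report$spec$family),
                         json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(tsv_path))
    write.table(as.data.frame(t(report$mean)), tsv_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(report)
}
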