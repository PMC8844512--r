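# ANOVA F-score feature ranking, incremental feature selection (IFS) and
# PCA projection.

#' Rank features by the two-class ANOVA F-statistic
#'
#' For each feature, F = MSB / MSW with
#' MSB = sum_g n_g (xbar_g - xbar)^2 / (k - 1) and
#' MSW = sum_g sum_i (x_gi - xbar_g)^2 / (N - k), k = 2 classes.
#' Degenerate cases: a feature with zero within-class variance but positive
#' between-class variance separates the classes perfectly and gets
#' F = +Inf (ranked first); a constant feature gets F = 0. Ties are broken
#' by ascending feature index, making the ranking deterministic.
#'
#' @param fm A labelled `feature_matrix` with at least 2 samples per class.
#' @return Object of class `feature_ranking`: list with `f_scores` (named,
#'   per input column) and `order` (column indices in descending F order).
#' @examples
#' x <- cbind(a = c(1, 2, 3, 4), b = c(5, 5, 5, 5))
#' anova_f(feature_matrix(x, c(0, 0, 1, 1)))$f_scores  # a: 8, b: 0
#' @export
anova_f <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  y <- fm$y
  if (is.null(y) || anyNA(y)) stop("anova_f needs fully labelled data")
  if (!setequal(unique(y), c(0L, 1L))) stop("labels must contain both classes")
  n0 <- sum(y == 0L); n1 <- sum(y == 1L)
  if (min(n0, n1) < 2L) stop("each class needs at least 2 samples")
  x <- fm$x
  N <- n0 + n1
  m0 <- colMeans(x[y == 0L, , drop = FALSE])
  m1 <- colMeans(x[y == 1L, , drop = FALSE])
  gm <- (n0 * m0 + n1 * m1) / N
  msb <- n0 * (m0 - gm)^2 + n1 * (m1 - gm)^2                # k - 1 = 1
  ssw <- colSums((x[y == 0L, , drop = FALSE] -
                    matrix(m0, n0, ncol(x), byrow = TRUE))^2) +
         colSums((x[y == 1L, , drop = FALSE] -
                    matrix(m1, n1, ncol(x), byrow = TRUE))^2)
  msw <- ssw / (N - 2L)
  f <- ifelse(msw > 0, msb / msw, ifelse(msb > 0, Inf, 0))
  names(f) <- colnames(x)
  ord <- order(-f, seq_along(f))
  structure(list(f_scores = f, order = ord), class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  top <- x$order[seq_len(min(5L, length(x$order)))]
  cat("<feature_ranking>", length(x$f_scores), "features; top:\n")
  print(data.frame(rank = seq_along(top), feature = names(x$f_scores)[top],
                   F = x$f_scores[top], row.names = NULL))
  invisible(x)
}

#' Write a feature ranking as TSV
#'
#' Columns: rank, feature index, canonical feature name, F-score.
#'
#' @param ranking A `feature_ranking`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  df <- data.frame(rank = seq_along(ranking$order),
                   index = ranking$order,
                   feature = names(ranking$f_scores)[ranking$order],
                   f_score = ranking$f_scores[ranking$order],
                   row.names = NULL)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict a feature matrix to the top-ranked features
#'
#' @param fm A `feature_matrix`.
#' @param ranking A `feature_ranking` over the columns of `fm`.
#' @param d Number of top-ranked features to keep (1..ncol).
#' @return A `feature_matrix` whose columns are the first `d` entries of the
#'   ranking, in rank order; labels unchanged.
#' @export
select_top <- function(fm, ranking, d) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(ranking, "feature_ranking"))
  if (!is.numeric(d) || length(d) != 1L || d < 1L || d > ncol(fm$x) ||
      d != as.integer(d))
    stop("d must be an integer in 1..", ncol(fm$x))
  feature_matrix(fm$x[, ranking$order[seq_len(d)], drop = FALSE], fm$y)
}

#' Incremental feature selection (IFS)
#'
#' Evaluates mean cross-validated performance of a classifier on growing
#' rank-ordered feature prefixes and selects the prefix size with the best
#' score. The optimum is the smallest d attaining the maximum, so the
#' search is deterministic given the seeds in `cv`.
#'
#' @param fm A labelled `feature_matrix`.
#' @param ranking A `feature_ranking` over its columns.
#' @param spec A [classifier_spec()]; default random forest.
#' @param d_grid Integer vector of prefix sizes to evaluate (default: every
#'   size from 1 to the number of features).
#' @param k Folds for cross-validation (default 10).
#' @param seed Seed for fold assignment.
#' @param objective `"accuracy"` (default) or `"mcc"`.
#' @return Object of class `ifs_result`: `curve` (data frame d, score),
#'   `optimal_d`, `optimal_score`, `objective`.
#' @export
ifs_search <- function(fm, ranking, spec = classifier_spec("random_forest"),
                       d_grid = seq_len(ncol(fm$x)), k = 10L, seed = 42L,
                       objective = c("accuracy", "mcc")) {
  objective <- match.arg(objective)
  d_grid <- as.integer(d_grid)
  if (length(d_grid) == 0L || any(d_grid < 1L) || any(d_grid > ncol(fm$x)))
    stop("d_grid values must lie in 1..", ncol(fm$x))
  score <- vapply(d_grid, function(d) {
    rep_ <- stratified_kfold(select_top(fm, ranking, d), spec, k = k,
                             seed = seed)
    if (objective == "accuracy") rep_$mean["Acc"] else rep_$mean["MCC"]
  }, numeric(1))
  best <- max(score)
  opt <- d_grid[which(score == best)[1]]  # smallest d attaining the max
  structure(list(curve = data.frame(d = d_grid, score = score),
                 optimal_d = opt, optimal_score = best,
                 objective = objective),
            class = "ifs_result")
}

#' @export
print.ifs_result <- function(x, ...) {
  cat(sprintf("<ifs_result> optimal d = %d (%s = %.3f) over %d prefix sizes\n",
              x$optimal_d, x$objective, x$optimal_score, nrow(x$curve)))
  invisible(x)
}

#' PCA projection of a feature matrix
#'
#' Principal-component scores for visualisation (e.g. class separation of a
#' selected feature subset). Components are ordered by decreasing explained
#' variance; each component's sign is fixed so that its largest-magnitude
#' loading is positive, making the projection reproducible.
#'
#' @param fm A `feature_matrix`.
#' @param n_components Number of components (default 2).
#' @return List with `scores` (n x n_components), `explained` (fraction of
#'   variance per component) and `rotation`.
#' @export
pca_project <- function(fm, n_components = 2L) {
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > min(dim(fm$x)))
    stop("n_components must be in 1..", min(dim(fm$x)))
  pc <- stats::prcomp(fm$x, center = TRUE, scale. = FALSE)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    l <- pc$rotation[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  rot <- sweep(pc$rotation, 2L, flip, `*`)
  scores <- sweep(pc$x, 2L, flip, `*`)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = scores[, seq_len(n_components), drop = FALSE],
       explained = expl[seq_len(n_components)],
       rotation = rot[, seq_len(n_components), drop = FALSE])
}
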