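# Class-ratio dataset assembly and stratified hold-out splitting.

#' Assemble a labelled dataset at a given class ratio
#'
#' Keeps every positive record and samples `ratio` times as many negatives
#' uniformly without replacement (or all negatives for `ratio = "all"`),
#' then shuffles the combined set deterministically. This reproduces
#' class-imbalance experiments at positive:negative ratios 1:1, 1:2, ...
#' up to the full negative pool.
#'
#' @param pos,neg Record data frames (positive and negative pools).
#' @param ratio Positive integer r (negatives = r x positives) or `"all"`.
#' @param seed Seed for negative subsampling and shuffling.
#' @return Record data frame with labels 1 (all positives) and 0.
#' @export
assemble <- function(pos, neg, ratio = 1L, seed = 42L) {
  if (nrow(pos) == 0L || nrow(neg) == 0L) stop("empty record pool")
  pos$label <- 1L; neg$label <- 0L
  if (identical(ratio, "all")) {
    take <- neg
  } else {
    r <- as.integer(ratio)
    if (is.na(r) || r < 1L) stop("ratio must be a positive integer or 'all'")
    n_need <- r * nrow(pos)
    if (n_need > nrow(neg))
      stop(sprintf("ratio 1:%d needs %d negatives but only %d available",
                   r, n_need, nrow(neg)))
    set.seed(seed)
    take <- neg[sample(nrow(neg), n_need), , drop = FALSE]
  }
  out <- rbind(pos, take)
  set.seed(seed + 1L)
  out <- out[sample(nrow(out)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stratified hold-out split
#'
#' @param records Labelled record data frame (both classes present).
#' @param fraction Fraction of each class assigned to the test side,
#'   in (0, 1); each side must end up non-empty for each class.
#' @param seed Seed for the split.
#' @return List with elements `train` and `test`; disjoint, union = input.
#' @export
split_holdout <- function(records, fraction = 0.2, seed = 42L) {
  y <- records$label
  if (anyNA(y) || length(unique(y)) < 2L)
    stop("split_holdout needs labelled records with both classes")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  set.seed(seed)
  test_idx <- unlist(lapply(c(0L, 1L), function(cl) {
    idx <- which(y == cl)
    n_test <- round(fraction * length(idx))
    if (n_test < 1L || n_test >= length(idx))
      stop("fraction ", fraction, " leaves an empty side for class ", cl)
    sample(idx, n_test)
  }))
  out <- list(train = records[-test_idx, , drop = FALSE],
              test = records[test_idx, , drop = FALSE])
  rownames(out$train) <- rownames(out$test) <- NULL
  out
}
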