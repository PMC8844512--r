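# The 188-dimensional global protein sequence descriptor (GPSD):
# 20 amino-acid composition features + 8 physicochemical properties, each
# contributing 21 CTD (composition / transition / distribution) features.

seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

# integer group index (1..3) per residue of seq under a partition
group_index <- function(chars, partition) {
  map <- integer(0)
  for (k in 1:3) map[partition$groups[[k]]] <- k
  unname(map[chars])
}

#' Amino-acid composition (AAC)
#'
#' Frequency of each of the 20 canonical amino acids in the sequence, in the
#' fixed alphabetical order of [aa_alphabet()]. Entries sum to 1.
#'
#' @param seq Validated sequence string (uppercase canonical alphabet,
#'   length >= 2).
#' @return Named numeric vector of length 20.
#' @examples
#' aac("AAC")  # A = 2/3, C = 1/3
#' @export
aac <- function(seq) {
  chars <- seq_chars(seq)
  tab <- table(factor(chars, levels = AA_ALPHABET))
  setNames(as.numeric(tab) / length(chars), AA_ALPHABET)
}

#' CTD composition descriptor
#'
#' Fraction of residues falling in each of the partition's three groups.
#'
#' @param seq Validated sequence string.
#' @param partition A [property_partition].
#' @return Numeric vector of length 3 (group order), summing to 1.
#' @export
ctd_composition <- function(seq, partition) {
  g <- group_index(seq_chars(seq), partition)
  setNames(tabulate(g, 3L) / length(g), names(partition$groups))
}

#' CTD transition descriptor
#'
#' For each unordered pair of distinct groups, the fraction of adjacent
#' residue pairs (i, i+1) whose two residues fall one in each group of the
#' pair, in either direction, divided by L - 1. Pairs are reported in the
#' order (group1, group2), (group2, group3), (group1, group3), which places
#' the neutral/hydrophobic hydrophobicity transition at global feature
#' index 26.
#'
#' @inheritParams ctd_composition
#' @return Numeric vector of length 3; each entry in [0, 1], sum <= 1.
#' @export
ctd_transition <- function(seq, partition) {
  g <- group_index(seq_chars(seq), partition)
  n <- length(g)
  a <- g[-n]; b <- g[-1]
  lab <- names(partition$groups)
  cnt <- c(sum((a == 1 & b == 2) | (a == 2 & b == 1)),
           sum((a == 2 & b == 3) | (a == 3 & b == 2)),
           sum((a == 1 & b == 3) | (a == 3 & b == 1)))
  setNames(cnt / (n - 1L),
           c(paste(lab[1], lab[2], sep = "_"),
             paste(lab[2], lab[3], sep = "_"),
             paste(lab[1], lab[3], sep = "_")))
}

#' CTD distribution descriptor
#'
#' For each group and each quantile q in {first, 25%, 50%, 75%, last}: the
#' 1-based sequence position of the m-th residue of that group divided by
#' the sequence length, where m = 1 for "first", m = n_k for "last" and
#' m = max(1, ceiling(q * n_k)) otherwise (n_k = number of group-k
#' residues). A group with no residues contributes five zeros.
#'
#' @inheritParams ctd_composition
#' @return Numeric vector of length 15 (group-major, 5 quantiles per
#'   group), values in [0, 1], non-decreasing within each group.
#' @export
ctd_distribution <- function(seq, partition) {
  g <- group_index(seq_chars(seq), partition)
  L <- length(g)
  lab <- names(partition$groups)
  out <- numeric(0)
  for (k in 1:3) {
    pos <- which(g == k)
    n_k <- length(pos)
    if (n_k == 0L) {
      vals <- rep(0, 5L)
    } else {
      m <- pmax(1L, ceiling(DIST_QUANTILES * n_k))
      m[1] <- 1L; m[5] <- n_k
      vals <- pos[m] / L
    }
    out <- c(out, setNames(vals, paste(lab[k], names(DIST_QUANTILES),
                                       sep = ".")))
  }
  out
}

#' Encode one sequence into the 188-dimensional descriptor
#'
#' Concatenates the 20 AAC features with, for each of the 8 property
#' partitions in schema order, 3 composition + 3 transition + 15
#' distribution features (8 x 21 = 168). All entries lie in [0, 1];
#' the encoding is deterministic.
#'
#' @param seq Validated sequence string.
#' @param schema An [encoder_schema()].
#' @return Named numeric vector of length 188.
#' @examples
#' v <- encode_188("MKVLWAALLVTFLAGCQA")
#' length(v)  # 188
#' @export
encode_188 <- function(seq, schema = encoder_schema()) {
  chk <- validate_record("x", seq)
  if (!chk$ok) stop("invalid sequence (", chk$reason, "): cannot encode")
  v <- aac(chk$seq)
  for (p in schema$partitions)
    v <- c(v, ctd_composition(chk$seq, p), ctd_transition(chk$seq, p),
           ctd_distribution(chk$seq, p))
  setNames(as.numeric(v), schema$feature_names)
}

#' Encode a set of records into a labelled feature matrix
#'
#' @param records Record data frame (columns `id`, `seq`, `label`).
#' @param schema An [encoder_schema()].
#' @return A `feature_matrix`: list with `x` (n x 188 numeric matrix, rows
#'   named by record id, columns by canonical feature name) and `y`
#'   (integer label vector, possibly NA).
#' @export
encode_matrix <- function(records, schema = encoder_schema()) {
  if (nrow(records) == 0L) stop("no records to encode")
  x <- t(vapply(records$seq, encode_188, numeric(188L), schema = schema,
                USE.NAMES = FALSE))
  rownames(x) <- records$id
  colnames(x) <- schema$feature_names
  feature_matrix(x, records$label)
}

#' Construct a feature matrix object
#'
#' @param x Numeric matrix, samples in rows, named feature columns.
#' @param y Optional binary labels (one per row; NA allowed for unlabelled
#'   data).
#' @return Object of class `feature_matrix`.
#' @export
feature_matrix <- function(x, y = NULL) {
  stopifnot(is.matrix(x), is.numeric(x), !is.null(colnames(x)))
  if (!is.null(y)) {
    stopifnot(length(y) == nrow(x))
    y <- as.integer(y)
    if (!all(y %in% c(0L, 1L) | is.na(y)))
      stop("labels must be binary (0/1) or NA")
  }
  structure(list(x = x, y = y), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d features", nrow(x$x),
              ncol(x$x)))
  if (!is.null(x$y))
    cat(sprintf("; labels: %d positive / %d negative",
                sum(x$y == 1L, na.rm = TRUE), sum(x$y == 0L, na.rm = TRUE)))
  cat("\n")
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$x)

#' Write a feature matrix as delimited text
#'
#' CSV layout: `id` column, 188 canonical feature-name columns, `label`
#' column (empty for unlabelled rows).
#'
#' @param fm A `feature_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(id = rownames(fm$x), fm$x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  df$label <- if (is.null(fm$y)) NA_integer_ else fm$y
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path CSV path.
#' @return A `feature_matrix`.
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(names(df)[1] == "id", names(df)[ncol(df)] == "label")
  x <- as.matrix(df[, -c(1L, ncol(df)), drop = FALSE])
  rownames(x) <- df$id
  y <- df$label
  feature_matrix(x, if (all(is.na(y))) NULL else y)
}
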