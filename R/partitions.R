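#' @importFrom stats predict rnorm runif setNames
#' @importFrom utils read.delim write.table
NULL

# Canonical 20-letter amino-acid alphabet, alphabetical by one-letter code.
# This order fixes features 1-20 (amino-acid composition) of the descriptor.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

DIST_QUANTILES <- c(first = 0, q25 = 0.25, q50 = 0.50, q75 = 0.75, last = 1)

#' Construct a physicochemical property partition
#'
#' A partition assigns each of the 20 canonical amino acids to exactly one of
#' three property groups (e.g. hydrophobic / polar / neutral). Partitions are
#' the basis of the composition/transition/distribution (CTD) descriptors.
#'
#' @param name Property name (e.g. `"hydrophobicity"`).
#' @param groups Named list of exactly 3 character vectors of one-letter
#'   residue codes; the three sets must be disjoint and cover the 20 canonical
#'   amino acids. Group order is significant: it fixes the feature ordering
#'   within this property's CTD block.
#' @return An object of class `property_partition`.
#' @examples
#' property_partition("charge",
#'   list(positive = c("K", "R"),
#'        neutral  = setdiff(aa_alphabet(), c("K", "R", "D", "E")),
#'        negative = c("D", "E")))
#' @export
property_partition <- function(name, groups) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.list(groups) || length(groups) != 3L)
    stop("a property partition needs exactly 3 residue groups")
  labels <- names(groups)
  if (is.null(labels) || anyDuplicated(labels) || any(!nzchar(labels)))
    stop("group labels must be distinct non-empty names")
  residues <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(residues))
    stop("partition groups overlap: ", name)
  if (!setequal(residues, AA_ALPHABET))
    stop("partition groups must cover exactly the 20 canonical amino acids: ",
         name)
  structure(list(name = name, groups = lapply(groups, sort)),
            class = "property_partition")
}

#' @export
print.property_partition <- function(x, ...) {
  cat("<property_partition>", x$name, "\n")
  for (g in names(x$groups))
    cat(sprintf("  %-12s %s\n", g, paste(x$groups[[g]], collapse = "")))
  invisible(x)
}

#' Default CTD property partitions
#'
#' The eight standard physicochemical properties used by the 188D global
#' protein sequence descriptor, each dividing the 20 amino acids into three
#' groups. The tables are the widely used CTD groupings of Dubchak et al.
#' (PNAS 1995) as propagated by SVM-Prot/PROFEAT and descriptor toolkits.
#'
#' The hydrophobicity partition leads the list with its hydrophobic group
#' first, which places the hydrophobic composition feature at global index 21
#' and the neutral/hydrophobic transition feature at global index 26 — the
#' two most discriminative features for membrane-channel recognition.
#'
#' @return Named list of 8 [property_partition] objects, in descriptor order.
#' @export
default_partitions <- function() {
  p <- list(
    property_partition("hydrophobicity", list(
      hydrophobic = c("C", "L", "V", "I", "M", "F", "W"),
      polar       = c("R", "K", "E", "D", "Q", "N"),
      neutral     = c("G", "A", "S", "T", "P", "H", "Y"))),
    property_partition("vdw_volume", list(
      small  = c("G", "A", "S", "T", "P", "D", "C"),
      medium = c("N", "V", "E", "Q", "I", "L"),
      large  = c("M", "H", "K", "F", "R", "Y", "W"))),
    property_partition("polarity", list(
      low    = c("L", "I", "F", "W", "C", "M", "V", "Y"),
      medium = c("P", "A", "T", "G", "S"),
      high   = c("H", "Q", "R", "K", "N", "E", "D"))),
    property_partition("polarizability", list(
      low    = c("G", "A", "S", "D", "T"),
      medium = c("C", "P", "N", "V", "E", "Q", "I", "L"),
      high   = c("K", "M", "H", "F", "R", "Y", "W"))),
    property_partition("charge", list(
      positive = c("K", "R"),
      neutral  = c("A", "N", "C", "Q", "G", "H", "I", "L",
                   "M", "F", "P", "S", "T", "W", "Y", "V"),
      negative = c("D", "E"))),
    property_partition("surface_tension", list(
      low    = c("G", "Q", "D", "N", "A", "H", "R"),
      medium = c("K", "T", "S", "E", "C"),
      high   = c("I", "L", "M", "F", "P", "W", "Y", "V"))),
    property_partition("secondary_structure", list(
      helix  = c("E", "A", "L", "M", "Q", "K", "R", "H"),
      strand = c("V", "I", "Y", "C", "W", "F", "T"),
      coil   = c("G", "N", "P", "S", "D"))),
    property_partition("solvent_accessibility", list(
      buried       = c("A", "L", "F", "C", "G", "I", "V", "W"),
      exposed      = c("R", "K", "Q", "E", "N", "D"),
      intermediate = c("M", "S", "P", "T", "H", "Y")))
  )
  names(p) <- vapply(p, function(x) x$name, character(1))
  p
}

#' The canonical amino-acid alphabet
#'
#' @return The 20 one-letter codes in the fixed order used for the first 20
#'   descriptor features.
#' @export
aa_alphabet <- function() AA_ALPHABET

#' Encoder schema: the canonical 188-feature layout
#'
#' Defines the fixed ordering of the 188-dimensional descriptor: features
#' 1-20 are amino-acid composition (alphabetical one-letter order); features
#' 21-188 are 8 blocks of 21 CTD features, one block per property partition.
#' Within a block: 3 composition entries (group order), 3 transition entries
#' (group pairs in order 1-2, 2-3, 1-3), and 15 distribution entries (per
#' group: position of the first, 25%, 50%, 75% and last group residue).
#'
#' @param partitions List of 8 [property_partition]s; defaults to
#'   [default_partitions()].
#' @return An object of class `encoder_schema` with elements `partitions`,
#'   `feature_names` (length 188) and `quantiles`.
#' @examples
#' sch <- encoder_schema()
#' sch$feature_names[c(21, 26)]
#' @export
encoder_schema <- function(partitions = default_partitions()) {
  if (length(partitions) != 8L)
    stop("the 188D descriptor uses exactly 8 property partitions")
  stopifnot(all(vapply(partitions, inherits, logical(1), "property_partition")))
  nm <- AA_ALPHABET
  for (p in partitions) {
    g <- names(p$groups)
    nm <- c(nm,
            paste(p$name, "C", g, sep = "."),
            paste(p$name, "T", c(paste(g[1], g[2], sep = "_"),
                                 paste(g[2], g[3], sep = "_"),
                                 paste(g[1], g[3], sep = "_")), sep = "."),
            paste(p$name, "D",
                  rep(g, each = 5L),
                  rep(names(DIST_QUANTILES), times = 3L), sep = "."))
  }
  stopifnot(length(nm) == 188L, !anyDuplicated(nm))
  structure(list(partitions = partitions, feature_names = nm,
                 quantiles = DIST_QUANTILES),
            class = "encoder_schema")
}

#' @export
print.encoder_schema <- function(x, ...) {
  cat("<encoder_schema> 188 features: 20 AAC + 8 properties x 21 CTD\n")
  cat("properties:", paste(names(x$partitions), collapse = ", "), "\n")
  invisible(x)
}

#' Canonical name of a descriptor feature
#'
#' @param index 1-based feature index in 1..188.
#' @param schema An [encoder_schema()].
#' @return The canonical feature name (stable across runs).
#' @examples
#' feature_name(21)  # hydrophobicity.C.hydrophobic
#' feature_name(26)  # hydrophobicity.T.neutral_hydrophobic (group pair 1-3)
#' @export
feature_name <- function(index, schema = encoder_schema()) {
  if (!is.numeric(index) || any(index < 1L) || any(index > 188L) ||
      any(index != as.integer(index)))
    stop("feature index must be an integer in 1..188")
  schema$feature_names[as.integer(index)]
}

#' Read property partitions from a plain-text table
#'
#' Allows the default CTD groupings to be overridden from a tab-separated
#' file with columns `property`, `group`, `residues` (residues as an
#' unseparated string of one-letter codes); one row per group, three rows
#' per property, properties in descriptor order.
#'
#' @param path Path to the TSV file.
#' @return Named list of [property_partition]s.
#' @export
read_partitions <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("property", "group", "residues")
  if (!all(need %in% names(tab)))
    stop("partition table needs columns: ", paste(need, collapse = ", "))
  out <- lapply(split(tab, factor(tab$property, levels = unique(tab$property))),
                function(d) {
    groups <- lapply(d$residues, function(s) strsplit(toupper(s), "")[[1]])
    names(groups) <- d$group
    property_partition(d$property[1], groups)
  })
  out[unique(tab$property)]
}
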