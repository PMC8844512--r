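# Reading, validating and deduplicating protein sequences.
#
# Records are held in a plain data frame with columns id, seq and label
# (1 = aquaporin/positive, 0 = negative, NA = unlabelled). All downstream
# code consumes this shape.

VALID_AA_RE <- "^[ACDEFGHIKLMNPQRSTVWY]+$"

new_records <- function(id, seq, label = NA_integer_) {
  data.frame(id = as.character(id), seq = as.character(seq),
             label = as.integer(label), stringsAsFactors = FALSE)
}

#' Validate a protein sequence record
#'
#' A record is accepted iff, after uppercasing, its sequence consists only of
#' the 20 canonical amino-acid letters and has length at least 2 (the
#' shortest sequence for which transition descriptors are defined).
#' Non-canonical residues (B, J, O, U, X, Z, gaps) cause whole-record
#' rejection rather than character stripping, so descriptor semantics stay
#' clean; rejection is a return value, not an error.
#'
#' @param id Record identifier (non-empty string).
#' @param seq Raw sequence string.
#' @return A list with `ok` (logical); on success `seq` (uppercased), on
#'   failure `reason` and `offending` (the invalid characters, if any).
#' @export
validate_record <- function(id, seq) {
  if (!is.character(id) || length(id) != 1L || is.na(id) || !nzchar(id))
    return(list(ok = FALSE, reason = "empty-id", offending = character(0)))
  s <- toupper(as.character(seq))
  if (is.na(s) || nchar(s) < 2L)
    return(list(ok = FALSE, reason = "too-short", offending = character(0)))
  if (!grepl(VALID_AA_RE, s)) {
    bad <- sort(unique(setdiff(strsplit(s, "")[[1]], AA_ALPHABET)))
    return(list(ok = FALSE, reason = "non-canonical-residue", offending = bad))
  }
  list(ok = TRUE, id = id, seq = s)
}

validate_records <- function(id, seq, label = NA_integer_, quiet = FALSE) {
  checks <- mapply(validate_record, id, seq, SIMPLIFY = FALSE)
  ok <- vapply(checks, `[[`, logical(1), "ok")
  rejected <- data.frame(
    id = as.character(id)[!ok],
    reason = vapply(checks[!ok], `[[`, character(1), "reason"),
    stringsAsFactors = FALSE)
  if (!quiet && nrow(rejected) > 0L)
    warning(sprintf("rejected %d record(s): %s", nrow(rejected),
                    paste(rejected$id, " (", rejected$reason, ")",
                          sep = "", collapse = ", ")), call. = FALSE)
  seqs <- vapply(checks[ok], `[[`, character(1), "seq")
  recs <- new_records(as.character(id)[ok],
                      if (length(seqs)) seqs else character(0), label)
  attr(recs, "rejected") <- rejected
  recs
}

#' Read protein sequences from a FASTA file
#'
#' Parses a (possibly line-wrapped) FASTA file, uppercases sequences, applies
#' [validate_record()] to each entry and returns the accepted records.
#' Rejected entries are reported via a warning and attached as the
#' `"rejected"` attribute (a data frame of id and reason).
#'
#' @param path Path to a FASTA file.
#' @param label Optional class label applied to every record (1 = positive /
#'   aquaporin, 0 = negative); `NA` for unlabelled input.
#' @return Data frame with columns `id`, `seq`, `label`.
#' @export
read_fasta <- function(path, label = NA_integer_) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("cannot parse FASTA file ", path,
                                           ": ", conditionMessage(e)))
  if (length(set) == 0L) stop("no FASTA entries found in ", path)
  # id = first whitespace-delimited token of the header
  ids <- vapply(strsplit(names(set), "[ \t]+"), function(x)
    if (length(x)) x[1] else "", character(1))
  validate_records(ids, as.character(set), label)
}

#' Write records to a FASTA file
#'
#' @param records Record data frame (columns `id`, `seq`).
#' @param path Output path.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$id[i]), con)
    s <- records$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Remove exact duplicate sequences
#'
#' Keeps the first occurrence of each distinct sequence string, preserving
#' input order. This implements only the exact-identity subset of redundancy
#' removal; similarity-based clustering (e.g. CD-HIT at 90% identity) is an
#' upstream external step that this package expects to have been applied to
#' real datasets.
#'
#' @param records Record data frame.
#' @return The deduplicated records, with the number of removed records in
#'   the `"removed"` attribute.
#' @export
dedupe_exact <- function(records) {
  keep <- !duplicated(records$seq)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- sum(!keep)
  out
}

#' Write a rejection report
#'
#' @param records Record data frame as returned by [read_fasta()].
#' @param path Output path for a tab-separated file with columns `id`,
#'   `reason`.
#' @return `path`, invisibly.
#' @export
write_rejections <- function(records, path) {
  rej <- attr(records, "rejected")
  if (is.null(rej)) rej <- data.frame(id = character(0), reason = character(0))
  write.table(rej, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
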