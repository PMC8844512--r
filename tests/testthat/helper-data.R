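# Small in-code fixtures shared across test files.

# two-class Gaussian feature matrix; class signal (mean shift) only in the
# first `n_informative` columns
gauss_fm <- function(n_per = 20L, p = 5L, shift = 0, n_informative = 1L,
                     seed = 1L) {
  set.seed(seed)
  x <- matrix(rnorm(2L * n_per * p), 2L * n_per, p)
  if (n_informative > 0L && shift != 0)
    x[seq_len(n_per), seq_len(n_informative)] <-
      x[seq_len(n_per), seq_len(n_informative)] + shift
  colnames(x) <- paste0("f", seq_len(p))
  rownames(x) <- paste0("s", seq_len(2L * n_per))
  feature_matrix(x, rep(c(1L, 0L), each = n_per))
}

write_tmp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}

# records with disjoint single-feature supports: classes trivially separable
separable_fm <- function(n_per = 30L, seed = 7L) {
  set.seed(seed)
  x <- cbind(f1 = c(runif(n_per, 0, 1), runif(n_per, 2, 3)))
  rownames(x) <- paste0("s", seq_len(2L * n_per))
  feature_matrix(x, rep(c(0L, 1L), each = n_per))
}
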