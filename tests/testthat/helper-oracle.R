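# Naive direct-count reference encoder, written independently of the
# package's optimized path: explicit per-residue loops, no vectorized
# group indexing. Used to verify all 188 descriptor entries.

oracle_encode_188 <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  v <- numeric(0)
  for (a in aa_alphabet()) v <- c(v, sum(ch == a) / L)
  for (p in default_partitions()) {
    lab <- names(p$groups)
    grp <- character(L)
    for (i in seq_len(L))
      for (g in lab) if (ch[i] %in% p$groups[[g]]) grp[i] <- g
    # composition
    for (g in lab) v <- c(v, sum(grp == g) / L)
    # transitions, pair order (1,2), (2,3), (1,3)
    for (pr in list(c(1L, 2L), c(2L, 3L), c(1L, 3L))) {
      cnt <- 0L
      for (i in seq_len(L - 1L)) {
        ab <- c(grp[i], grp[i + 1L])
        if (setequal(ab, lab[pr]) && ab[1] != ab[2]) cnt <- cnt + 1L
      }
      v <- c(v, cnt / (L - 1L))
    }
    # distribution
    for (g in lab) {
      pos <- which(grp == g)
      n <- length(pos)
      if (n == 0L) {
        v <- c(v, rep(0, 5))
      } else {
        for (q in c(0, 0.25, 0.5, 0.75, 1)) {
          m <- if (q == 0) 1L else if (q == 1) n else max(1L, ceiling(q * n))
          v <- c(v, pos[m] / L)
        }
      }
    }
  }
  v
}

random_seq <- function(len) paste(sample(aa_alphabet(), len, replace = TRUE),
                                  collapse = "")
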