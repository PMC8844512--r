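hydro <- default_partitions()$hydrophobicity

test_that("schema defines 188 uniquely named features with the documented layout", {
  sch <- encoder_schema()
  expect_length(sch$feature_names, 188L)
  expect_false(anyDuplicated(sch$feature_names) > 0)
  expect_equal(sch$feature_names[1:20], aa_alphabet())
  # each property contributes a 21-feature C/T/D block
  for (p in names(sch$partitions)) {
    blk <- grep(paste0("^", p, "\\."), sch$feature_names, value = TRUE)
    expect_length(blk, 21L)
    expect_length(grep("\\.C\\.", blk), 3L)
    expect_length(grep("\\.T\\.", blk), 3L)
    expect_length(grep("\\.D\\.", blk), 15L)
  }
})

test_that("features 21 and 26 are the hydrophobic composition and neutral/hydrophobic transition", {
  expect_equal(feature_name(21), "hydrophobicity.C.hydrophobic")
  expect_equal(feature_name(26), "hydrophobicity.T.hydrophobic_neutral")
  expect_equal(feature_name(1), "A")
  expect_error(feature_name(0), "1..188")
  expect_error(feature_name(189), "1..188")
})

test_that("aac computes residue frequencies in fixed order", {
  v <- aac("AAAAA")
  expect_equal(unname(v["A"]), 1)
  expect_equal(sum(v), 1)
  expect_equal(unname(aac("ACDEFGHIKLMNPQRSTVWY")), rep(0.05, 20))
  v3 <- aac("AAC")
  expect_equal(unname(v3[c("A", "C")]), c(2 / 3, 1 / 3))
  expect_equal(sum(v3[-match(c("A", "C"), names(v3))]), 0)
})

test_that("ctd_composition counts group fractions", {
  expect_equal(unname(ctd_composition("CCCC", hydro)), c(1, 0, 0))
  expect_equal(unname(ctd_composition("RRGG", hydro)), c(0, 0.5, 0.5))
  expect_equal(unname(ctd_composition("RGCRGC", hydro)), rep(1 / 3, 3))
})

test_that("ctd_transition counts unordered cross-group adjacencies over L-1", {
  expect_equal(unname(ctd_transition("RRRR", hydro)), c(0, 0, 0))
  rg <- ctd_transition("RG", hydro)
  expect_equal(unname(rg["polar_neutral"]), 1)
  expect_equal(sum(rg), 1)
  # RGCRGC adjacent pairs: RG, GC, CR, RG, GC
  tr <- ctd_transition("RGCRGC", hydro)
  expect_equal(unname(tr["polar_neutral"]), 2 / 5)
  expect_equal(unname(tr["hydrophobic_neutral"]), 2 / 5)
  expect_equal(unname(tr["hydrophobic_polar"]), 1 / 5)
})

test_that("ctd_distribution follows the ceil-with-floor quantile convention", {
  d <- ctd_distribution("CCCC", hydro)
  expect_equal(unname(d[1:5]), c(1, 1, 2, 3, 4) / 4)  # hydrophobic group
  # no polar residues -> polar block all zero
  expect_equal(unname(ctd_distribution("GGGG", hydro)[6:10]), rep(0, 5))
  # RRGG: polar at positions 1,2 (n=2, indices 1,1,1,2,2), L = 4
  expect_equal(unname(ctd_distribution("RRGG", hydro)[6:10]),
               c(0.25, 0.25, 0.25, 0.5, 0.5))
})

test_that("encode_188 produces a deterministic 188-vector with 168 CTD entries", {
  s <- random_seq(80L)
  v <- encode_188(s)
  expect_length(v, 188L)
  expect_length(v[21:188], 168L)
  expect_identical(v, encode_188(s))
  expect_error(encode_188("MKXZ"), "invalid sequence")
})

test_that("descriptor invariants hold on random sequences", {
  set.seed(101)
  sch <- encoder_schema()
  for (i in 1:25) {
    s <- random_seq(sample(2:200, 1))
    v <- encode_188(s, sch)
    expect_true(all(v >= 0 & v <= 1))
    expect_equal(sum(v[1:20]), 1, tolerance = 1e-12)
    for (b in seq_len(8)) {
      blk <- v[(21 + 21 * (b - 1)):(41 + 21 * (b - 1))]
      expect_equal(sum(blk[1:3]), 1, tolerance = 1e-12)   # C sums to 1
      expect_lte(sum(blk[4:6]), 1 + 1e-12)                # T block sum <= 1
      for (g in 0:2) {
        d <- blk[(7 + 5 * g):(11 + 5 * g)]
        expect_true(all(diff(d) >= -1e-15))               # D non-decreasing
      }
    }
    # C and T are invariant under sequence reversal (unordered pairs)
    rv <- encode_188(paste(rev(strsplit(s, "")[[1]]), collapse = ""), sch)
    ct_idx <- unlist(lapply(0:7, function(b) 21 + 21 * b + 0:5))
    expect_equal(rv[ct_idx], v[ct_idx], tolerance = 1e-12)
  }
})

test_that("single-group sequences give degenerate C/T/D patterns", {
  v <- encode_188("CLVIMFWC")
  expect_equal(unname(v[21:23]), c(1, 0, 0))      # all hydrophobic
  expect_equal(unname(v[24:26]), c(0, 0, 0))      # no transitions
  expect_true(all(v[27:31] > 0))                  # hydrophobic D populated
  expect_true(all(v[32:41] == 0))                 # other groups empty
})

test_that("optimized encoder matches the naive direct-count oracle", {
  set.seed(2024)
  for (i in 1:60) {
    s <- random_seq(sample(2:30, 1))
    expect_equal(unname(encode_188(s)), oracle_encode_188(s),
                 tolerance = 1e-12)
  }
})

test_that("encode_matrix preserves row order, labels and names", {
  recs <- data.frame(id = c("a", "b", "c"),
                     seq = c("MKVLW", "ACDEF", "GGGGHH"),
                     label = c(1L, 0L, 1L))
  fm <- encode_matrix(recs)
  expect_equal(dim(fm), c(3L, 188L))
  expect_equal(rownames(fm$x), recs$id)
  expect_equal(fm$y, recs$label)
  expect_equal(fm$x["a", ], encode_188("MKVLW"))

  perm <- recs[c(3, 1, 2), ]
  expect_equal(encode_matrix(perm)$x, fm$x[c(3, 1, 2), ])
  expect_error(encode_matrix(recs[0, ]), "no records")
})

test_that("feature matrix CSV round-trips", {
  recs <- data.frame(id = c("a", "b"), seq = c("MKVLWA", "ACDEFG"),
                     label = c(1L, 0L))
  fm <- encode_matrix(recs)
  path <- tempfile(fileext = ".csv")
  write_feature_matrix(fm, path)
  back <- read_feature_matrix(path)
  expect_equal(back$y, fm$y)
  expect_equal(colnames(back$x), colnames(fm$x))
  expect_equal(unname(back$x), unname(fm$x), tolerance = 1e-12)
})

test_that("partition invariants are enforced and tables load from TSV", {
  expect_error(property_partition("bad", list(a = c("A"), b = c("C"),
                                              c = c("D"))),
               "cover exactly")
  expect_error(property_partition("bad", list(a = aa_alphabet()[1:7],
                                              b = aa_alphabet()[7:13],
                                              c = aa_alphabet()[14:20])),
               "overlap")
  # round-trip the default tables through the plain-text format
  defs <- default_partitions()
  tab <- do.call(rbind, lapply(defs, function(p)
    data.frame(property = p$name, group = names(p$groups),
               residues = vapply(p$groups, paste, "", collapse = ""))))
  path <- tempfile(fileext = ".tsv")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_partitions(path)
  expect_equal(back, defs)
})
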