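# A trio with a given exon/gene length for normalisation checks.
norm_trio <- function(l_e, l_g = 2000) {
  pad <- (l_g - 600 - l_e) / 2  # introns 300 each inside the gene
  stopifnot(pad >= 1, pad == floor(pad))
  exon_start <- 1000
  exon_trio("n", "c", "+",
            up_intron = c(exon_start - 300, exon_start),
            exon = c(exon_start, exon_start + l_e),
            down_intron = c(exon_start + l_e, exon_start + l_e + 300),
            up_flank_exon_end = exon_start - 300,
            down_flank_exon_start = exon_start + l_e + 300,
            gene = c(exon_start - 300 - pad,
                     exon_start + l_e + 300 + pad))
}

counts_of <- function(n_exon = 0, n_up = 0, n_down = 0, n_ni = 0,
                      n_ne = 0, n_gene = 0) {
  c(n_exon = n_exon, n_up_intron = n_up, n_down_intron = n_down,
    n_ni = n_ni, n_ne = n_ne, n_gene = n_gene)
}

test_that("normalisation matches hand-evaluated effective-length formulas", {
  # exon: 100 reads over effective length 131 - 32 + 1 = 100, T = 1e9
  trio <- norm_trio(l_e = 131, l_g = 2001)
  meta <- sample_meta("B", read_length = 32, anchor = 8,
                      total_mapped = 1e9)
  norm <- normalize_counts(counts_of(n_exon = 100), meta, trio)
  expect_equal(unname(norm["norm_exon"]), 1.0)

  # inclusion: 64 reads over 100 + 2 x 14 = 128 placements, T = 5e8
  trio2 <- norm_trio(l_e = 120, l_g = 2000)
  meta2 <- sample_meta("B", read_length = 21, anchor = 4,
                       total_mapped = 5e8)
  norm2 <- normalize_counts(counts_of(n_ni = 64), meta2, trio2)
  expect_equal(unname(norm2["norm_ni"]), 1.0)

  expect_equal(unname(normalize_counts(counts_of(), meta, trio)),
               rep(0, 6))
})

test_that("degenerate effective lengths raise errors naming the inequality", {
  trio <- norm_trio(l_e = 120, l_g = 2000)
  short_exon <- sample_meta("B", read_length = 150, anchor = 8,
                            total_mapped = 1e6)
  expect_error(normalize_counts(counts_of(), short_exon, trio),
               "L_e - L_r \\+ 1")
  expect_error(sample_meta("B", read_length = 32, anchor = 17,
                           total_mapped = 1e6),
               "anchor")
})

test_that("normalisation is invariant to common scaling of counts and T", {
  trio <- norm_trio(l_e = 150, l_g = 2000)
  meta1 <- sample_meta("B", 32, 8, total_mapped = 1e6)
  meta7 <- sample_meta("B", 32, 8, total_mapped = 7e6)
  cs <- counts_of(12, 3, 4, 20, 5, 80)
  expect_equal(normalize_counts(cs * 7, meta7, trio),
               normalize_counts(cs, meta1, trio))
})

test_that("P is the normalised inclusion fraction with a defined zero case", {
  expect_equal(p_feature(2, 2), 0.5)
  expect_equal(p_feature(3, 0), 1)
  expect_equal(p_feature(0, 0), 0)
  expect_error(p_feature(-1, 2), "non-negative")
  # invariance under common positive scaling, and range
  set.seed(8)
  for (i in 1:20) {
    ni <- runif(1, 0, 5); ne <- runif(1, 0, 5); k <- runif(1, 0.1, 100)
    expect_equal(p_feature(k * ni, k * ne), p_feature(ni, ne))
    expect_gte(p_feature(ni, ne), 0)
    expect_lte(p_feature(ni, ne), 1)
  }
})

test_that("divergences are brain minus muscle and antisymmetric", {
  brain <- list(norm_exon = 2.5, norm_up_intron = 1, norm_down_intron = 2,
                norm_ni = 3, norm_ne = 0.5, norm_gene = 4, p = 0.8)
  muscle <- list(norm_exon = 1.0, norm_up_intron = 1, norm_down_intron = 0,
                 norm_ni = 1, norm_ne = 1.5, norm_gene = 2, p = 0.3)
  delta <- divergence_features(brain, muscle)
  expect_equal(unname(delta["delta_exon"]), 1.5)
  expect_equal(unname(delta["delta_p"]), 0.5)
  expect_equal(divergence_features(muscle, brain), -delta)
  expect_equal(unname(divergence_features(brain, brain)), rep(0, 7))
})

test_that("the feature blocks have the documented sizes and compose", {
  expect_length(feature_set_columns("initial"), 12)
  expect_length(feature_set_columns("equilibrium"), 21)
  expect_length(feature_set_columns("rnaseq"), 33)
  expect_length(feature_set_columns("sequence"), 15)
  expect_length(feature_set_columns("rs"), 48)
  expect_equal(feature_set_columns("rnaseq"),
               c(feature_set_columns("initial"),
                 feature_set_columns("equilibrium")))
  expect_equal(feature_set_columns("rs"),
               c(feature_set_columns("rnaseq"),
                 feature_set_columns("sequence")))
  # the short-motif block: sequence features minus the three lengths
  motif <- grep("^[acgt]_", feature_set_columns("sequence"), value = TRUE)
  expect_length(motif, 12)
})

test_that("rs_features assembles the 48-vector consistently", {
  trio <- make_trio()
  genome <- make_genome()
  meta <- sample_meta("B", 32, 8, 1e6)
  counts_b <- counts_of(30, 2, 1, 40, 5, 100)
  counts_s <- counts_of(25, 1, 0, 20, 25, 90)
  out <- rs_features(counts_b, counts_s, meta, meta, trio, genome)
  fv <- out$features
  expect_named(fv, rs_feature_names())
  expect_false(out$no_junction_evidence)
  # initial block carries the raw counts, muscle first
  expect_equal(unname(fv[paste0("s_", names(counts_s))]),
               unname(counts_s))
  expect_equal(unname(fv[paste0("b_", names(counts_b))]),
               unname(counts_b))
  # equilibrium block agrees with a direct recomputation
  norm_b <- normalize_counts(counts_b, meta, trio)
  norm_s <- normalize_counts(counts_s, meta, trio)
  expect_equal(unname(fv["b_norm_ni"]), unname(norm_b["norm_ni"]))
  expect_equal(unname(fv["delta_ne"]),
               unname(norm_b["norm_ne"] - norm_s["norm_ne"]))
  expect_equal(unname(fv["b_p"]),
               p_feature(norm_b[["norm_ni"]], norm_b[["norm_ne"]]))
  # sequence block equals the standalone computation
  expect_equal(fv[sequence_feature_names()],
               sequence_feature_vector(trio, genome))
  # zero-evidence events are flagged
  out0 <- rs_features(counts_of(), counts_of(), meta, meta, trio, genome)
  expect_true(out0$no_junction_evidence)
  expect_equal(unname(out0$features["b_p"]), 0)
})

test_that("assemble_rs validates its parts", {
  trio <- make_trio()
  genome <- make_genome()
  seq_fv <- sequence_feature_vector(trio, genome)
  eq <- setNames(numeric(21), feature_set_columns("equilibrium"))
  cs <- counts_of(1, 1, 1, 1, 1, 1)
  expect_length(assemble_rs(cs, cs, eq, seq_fv), 48)
  expect_error(assemble_rs(cs[-1], cs, eq, seq_fv), "six basic counts")
  expect_error(assemble_rs(cs, cs, eq[-1], seq_fv), "21")
  expect_error(assemble_rs(cs, cs, eq, seq_fv[-1]), "15")
})

test_that("feature tables round-trip through TSV with labels", {
  st <- simulate_es_study(3, 3, seed = 21)
  fm <- build_feature_matrix(st$events, st$genome,
                             reads_b = st$reads$B, reads_s = st$reads$S,
                             meta_b = st$meta$B, meta_s = st$meta$S)
  expect_equal(dim(fm), c(6, 48))
  path <- tempfile(fileext = ".tsv")
  write_feature_table(fm, path, labels = st$labels)
  back <- read_feature_table(path)
  expect_equal(back$labels, as.character(st$labels))
  expect_equal(back$features, fm, tolerance = 1e-12)
  # selector projects exactly the sequence columns
  fm_seq <- build_feature_matrix(st$events, st$genome,
                                 reads_b = st$reads$B,
                                 reads_s = st$reads$S,
                                 meta_b = st$meta$B, meta_s = st$meta$S,
                                 feature_set = "sequence")
  expect_equal(fm_seq, fm[, feature_set_columns("sequence")])
})
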