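test_that("region counting is intersection-strict", {
  contained <- read_alignments("r1", "chrT", list(cbind(10, 42)))
  expect_equal(count_region_reads(contained, c(0, 100)), 1)
  straddling <- read_alignments("r2", "chrT", list(cbind(90, 122)))
  expect_equal(count_region_reads(straddling, c(0, 100)), 0)
  expect_equal(count_region_reads(straddling[0, ], c(0, 100)), 0)
  # a spliced read with all blocks inside the region counts
  spliced <- read_alignments("r3", "chrT",
                             list(cbind(c(10, 60), c(30, 90))))
  expect_equal(count_region_reads(spliced, c(0, 100)), 1)
})

test_that("tiling enumerations match the effective-length formulas", {
  l_r <- 32; o <- 8
  region <- c(100, 220)  # length 120
  tiles <- tile_region_reads(region, l_r)
  expect_equal(count_region_reads(tiles, region),
               (region[2] - region[1]) - l_r + 1)
  jr <- tile_junction_reads(500, 900, l_r, o)
  expect_equal(count_junction_reads(jr, 500, 900, o), l_r + 1 - 2 * o)
  # raising the anchor excludes the short-anchored placements
  expect_equal(count_junction_reads(jr, 500, 900, o + 1), l_r - 1 - 2 * o)
})

test_that("junction matching requires exact coordinates and both anchors", {
  read <- read_alignments("j1", "chrT",
                          list(cbind(c(92, 200), c(100, 224))))
  expect_equal(count_junction_reads(read, 100, 200, 8), 1)  # anchors 8, 24
  expect_equal(count_junction_reads(read, 100, 200, 9), 0)  # left anchor 8
  expect_equal(count_junction_reads(read, 100, 201, 8), 0)  # near miss
  expect_equal(count_junction_reads(read, 99, 200, 8), 0)
})

test_that("count_set composes body and junction evidence per the design", {
  trio <- make_trio()  # exon [500, 620), flanks end/start at 200 / 900
  l_r <- 32; o <- 8
  l_e <- 120
  inclusion <- rbind(
    tile_region_reads(trio$exon, l_r, "b"),
    tile_junction_reads(trio$up_flank_exon_end, trio$exon[1], l_r, o, "u"),
    tile_junction_reads(trio$exon[2], trio$down_flank_exon_start, l_r, o,
                        "d"))
  cs <- count_set(inclusion, trio, o = o)
  expect_equal(unname(cs["n_ni"]),
               (l_e - l_r + 1) + 2 * (l_r + 1 - 2 * o))
  expect_equal(unname(cs["n_ne"]), 0)

  exclusion <- tile_junction_reads(trio$up_flank_exon_end,
                                   trio$down_flank_exon_start, l_r, o, "e")
  cs2 <- count_set(exclusion, trio, o = o)
  expect_equal(unname(cs2["n_ne"]), l_r + 1 - 2 * o)
  expect_equal(unname(cs2["n_exon"]), 0)

  expect_equal(unname(count_set(inclusion[0, ], trio, o = o)),
               rep(0L, 6))
  wrong_chrom <- read_alignments("x", "chrZ", list(cbind(10, 42)))
  expect_error(count_set(wrong_chrom, trio, o = o), "chromosome")
})

test_that("count_set equals a brute-force per-read classifier", {
  trio <- make_trio()
  for (seed in 1:5) {
    set.seed(seed)
    reads <- random_reads(trio, n = 200)
    expect_equal(count_set(reads, trio, o = 8),
                 count_set_oracle(reads, trio, o = 8))
  }
})

test_that("adding reads never decreases counters; ni and ne are disjoint", {
  trio <- make_trio()
  set.seed(42)
  reads <- random_reads(trio, n = 120)
  prev <- count_set(reads[0, ], trio, o = 8)
  for (k in c(10, 40, 80, 120)) {
    cur <- count_set(reads[seq_len(k), ], trio, o = 8)
    expect_true(all(cur >= prev))
    prev <- cur
  }
  # per-read: a junction read cannot support both inclusion and skipping
  for (i in seq_len(nrow(reads))) {
    single <- count_set(reads[i, ], trio, o = 8)
    expect_lte(single[["n_ni"]] * single[["n_ne"]], 0)
  }
})

test_that("reads TSV round trip preserves alignments", {
  trio <- make_trio()
  set.seed(5)
  reads <- random_reads(trio, n = 30)
  path <- tempfile(fileext = ".tsv")
  write_reads_tsv(reads, path)
  back <- read_reads_tsv(path)
  expect_equal(back$read_id, reads$read_id)
  expect_equal(back$chrom, reads$chrom)
  expect_equal(count_set(back, trio, o = 8), count_set(reads, trio, o = 8))
})

test_that("the SAM adapter converts CIGAR blocks and drops unmapped reads", {
  sam <- c(
    "@HD\tVN:1.6",
    "@SQ\tSN:chrT\tLN:1200",
    # 1-based POS 93 -> 0-based 92; 8M100N24M spans the junction 100->200
    "jr\t0\tchrT\t93\t60\t8M100N24M\t*\t0\t0\t*\t*",
    # simple contained read, POS 11 -> [10, 42)
    "br\t0\tchrT\t11\t60\t32M\t*\t0\t0\t*\t*",
    # soft clip + deletion: 4S10M2D10M consumes 22 ref bases from 50
    "dr\t16\tchrT\t51\t60\t4S10M2D10M\t*\t0\t0\t*\t*",
    # unmapped
    "ur\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*")
  path <- tempfile(fileext = ".sam")
  writeLines(sam, path)
  reads <- read_sam_reads(path)
  expect_equal(reads$read_id, c("jr", "br", "dr"))
  expect_equal(reads$blocks[[1]],
               cbind(start = c(92, 200), end = c(100, 224)))
  expect_equal(reads$blocks[[2]], cbind(start = 10, end = 42))
  expect_equal(reads$blocks[[3]], cbind(start = 50, end = 72))
  expect_equal(count_junction_reads(reads, 100, 200, 8), 1)
})
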