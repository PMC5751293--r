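# Shared fixtures and tiny brute-force oracles, built in code.

# A standard well-formed event on its own small chromosome.
make_trio <- function(strand = "+") {
  exon_trio("evA", "chrT", strand,
            up_intron = c(200, 500), exon = c(500, 620),
            down_intron = c(620, 900),
            up_flank_exon_end = 200, down_flank_exon_start = 900,
            gene = c(50, 1100))
}

# Random chromosome long enough for make_trio().
make_genome <- function(len = 1200, seed = 99) {
  set.seed(seed)
  g <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
             collapse = "")
  c(chrT = g)
}

# Independent per-character tally (oracle for nucleotide_counts).
tally_oracle <- function(s) {
  ch <- strsplit(toupper(s), "")[[1]]
  c(A = sum(ch == "A"), C = sum(ch == "C"),
    G = sum(ch == "G"), T = sum(ch == "T"))
}

# Reverse complement without Biostrings (oracle for strand handling).
revcomp_oracle <- function(s) {
  ch <- rev(strsplit(toupper(s), "")[[1]])
  paste(chartr("ACGT", "TGCA", ch), collapse = "")
}

# All single-block reads of length l_r tiling [region[1], region[2]).
tile_region_reads <- function(region, l_r, prefix = "t") {
  starts <- region[1]:(region[2] - l_r)
  read_alignments(paste0(prefix, seq_along(starts)), "chrT",
                  lapply(starts, function(s) cbind(s, s + l_r)))
}

# All junction reads donor->acceptor with anchors from o to l_r - o.
tile_junction_reads <- function(donor, acceptor, l_r, o, prefix = "j") {
  anchors <- o:(l_r - o)
  read_alignments(paste0(prefix, seq_along(anchors)), "chrT",
                  lapply(anchors, function(a) {
                    cbind(c(donor - a, acceptor),
                          c(donor, acceptor + l_r - a))
                  }))
}

# Brute-force per-read classifier for the six counters: one read at a time,
# straight from the definitions.
count_set_oracle <- function(reads, trio, o) {
  inside <- function(b, iv) all(b[, 1] >= iv[1] & b[, 2] <= iv[2])
  junc <- function(b, donor, acceptor) {
    n <- nrow(b)
    if (n < 2) return(FALSE)
    for (i in seq_len(n - 1)) {
      if (b[i, 2] == donor && b[i + 1, 1] == acceptor)
        return((b[i, 2] - b[i, 1]) >= o &&
                 (b[i + 1, 2] - b[i + 1, 1]) >= o)
    }
    FALSE
  }
  out <- c(n_exon = 0, n_up_intron = 0, n_down_intron = 0, n_ni = 0,
           n_ne = 0, n_gene = 0)
  for (b in reads$blocks) {
    in_exon <- inside(b, trio$exon)
    out["n_exon"] <- out["n_exon"] + in_exon
    out["n_up_intron"] <- out["n_up_intron"] + inside(b, trio$up_intron)
    out["n_down_intron"] <- out["n_down_intron"] +
      inside(b, trio$down_intron)
    ji <- in_exon ||
      junc(b, trio$up_flank_exon_end, trio$exon[1]) ||
      junc(b, trio$exon[2], trio$down_flank_exon_start)
    out["n_ni"] <- out["n_ni"] + ji
    out["n_ne"] <- out["n_ne"] +
      junc(b, trio$up_flank_exon_end, trio$down_flank_exon_start)
    out["n_gene"] <- out["n_gene"] + inside(b, trio$gene)
  }
  out
}

# Random small read set mixing contained, boundary-crossing and spliced
# reads around a trio.
random_reads <- function(trio, n, l_r = 32, o = 8) {
  kinds <- sample(c("single", "junc_up", "junc_down", "junc_skip"),
                  n, replace = TRUE, prob = c(0.55, 0.15, 0.15, 0.15))
  blocks <- lapply(kinds, function(kind) {
    if (kind == "single") {
      s <- sample(trio$gene[1]:(trio$gene[2] - l_r + 10), 1) - 5
      cbind(s, s + l_r)
    } else {
      jc <- switch(kind,
                   junc_up = c(trio$up_flank_exon_end, trio$exon[1]),
                   junc_down = c(trio$exon[2], trio$down_flank_exon_start),
                   junc_skip = c(trio$up_flank_exon_end,
                                 trio$down_flank_exon_start))
      a <- sample(1:(l_r - 1), 1)  # anchors below o occur on purpose
      cbind(c(jc[1] - a, jc[2]), c(jc[1], jc[2] + l_r - a))
    }
  })
  read_alignments(paste0("r", seq_len(n)), trio$chrom, blocks)
}

# Mann-Whitney pair-concordance AUC oracle (ties get half credit).
auc_oracle <- function(scores, truth) {
  pos <- scores[truth]
  neg <- scores[!truth]
  pairs <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(pairs)
}

# Two well-separated Gaussian blobs for classifier checks.
make_blobs <- function(n_per_class = 100, d = 10, sep = 10, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * d), n_per_class),
             matrix(rnorm(n_per_class * d, mean = sep), n_per_class))
  colnames(x) <- paste0("f", seq_len(d))
  y <- factor(rep(c("non-ES", "ES"), each = n_per_class),
              levels = c("ES", "non-ES"))
  list(x = x, y = y)
}

# A rotation_forest-shaped stub whose trees are fixed single-leaf carts;
# used to verify confidence averaging and the tie rule in isolation.
make_stub_forest <- function(leaf_probs, levels = c("non-ES", "ES"),
                             positive = "ES", d = 2) {
  trees <- lapply(leaf_probs, function(p) {
    tree <- structure(list(feature = NA_integer_, threshold = NA_real_,
                           left = NA_integer_, right = NA_integer_,
                           prob = matrix(p, nrow = 1), levels = levels),
                      class = "cart_tree")
    rotation <- structure(list(rotation = diag(d), centers = numeric(d),
                               subsets = list(seq_len(d))),
                          class = "rotation_matrix")
    list(rotation = rotation, tree = tree)
  })
  structure(list(trees = trees, levels = levels, positive = positive,
                 feature_names = NULL,
                 config = list(n_trees = length(leaf_probs)),
                 n_train = 0L),
            class = "rotation_forest")
}
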