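#' Simulate one cassette-exon event
#'
#' Draws region lengths uniformly within the configured ranges, composes a
#' dedicated chromosome with the layout
#' `pad | upstream flank exon | upstream intron | cassette exon |
#' downstream intron | downstream flank exon | pad`, and fills it with
#' i.i.d. bases from `base_probs`. The gene span covers flank exon to flank
#' exon. Uses the current RNG state; seed at the study level for
#' reproducibility.
#'
#' @param event_id event identifier (also used as the chromosome name).
#' @param exon_length,intron_length integer ranges `c(min, max)` in bp.
#' @param flank_length flanking (constitutive) exon length in bp; must be
#'   at least `read_length - anchor` so junction reads fit.
#' @param gene_padding intergenic padding on each side in bp.
#' @param read_length read length the event must support
#'   (enforces `L_e - L_r + 1 >= 1`).
#' @param strand `"+"` or `"-"`.
#' @param base_probs named probabilities for A, C, G, T.
#' @return list with `trio` (an [exon_trio()]) and `sequence` (character
#'   chromosome).
#' @export
simulate_event <- function(event_id,
                           exon_length = c(100, 250),
                           intron_length = c(150, 600),
                           flank_length = 150,
                           gene_padding = 100,
                           read_length = 32,
                           strand = "+",
                           base_probs = c(A = 0.3, C = 0.2,
                                          G = 0.2, T = 0.3)) {
  if (exon_length[1] < read_length)
    stop("minimum exon length (", exon_length[1],
         ") must be >= read_length (", read_length,
         ") so the exon effective length is positive")
  if (exon_length[2] < exon_length[1] || intron_length[2] < intron_length[1])
    stop("length ranges must satisfy min <= max")
  e_len <- sample(exon_length[1]:exon_length[2], 1)
  i1_len <- sample(intron_length[1]:intron_length[2], 1)
  i2_len <- sample(intron_length[1]:intron_length[2], 1)
  gene_start <- gene_padding
  up_flank_start <- gene_start
  up_intron_start <- up_flank_start + flank_length
  exon_start <- up_intron_start + i1_len
  exon_end <- exon_start + e_len
  down_intron_end <- exon_end + i2_len
  gene_end <- down_intron_end + flank_length
  chrom_len <- gene_end + gene_padding
  bases <- sample(names(base_probs), chrom_len, replace = TRUE,
                  prob = base_probs)
  trio <- exon_trio(
    event_id = event_id, chrom = event_id, strand = strand,
    up_intron = c(up_intron_start, exon_start),
    exon = c(exon_start, exon_end),
    down_intron = c(exon_end, down_intron_end),
    up_flank_exon_end = up_intron_start,
    down_flank_exon_start = down_intron_end,
    gene = c(gene_start, gene_end)
  )
  list(trio = trio, sequence = paste(bases, collapse = ""))
}

# all (start) placements of a junction read over donor->acceptor with
# anchor o: left anchor a in [o, L_r - o]
.junction_blocks <- function(donor, acceptor, left_anchor, read_length) {
  lapply(left_anchor, function(a) {
    cbind(start = c(donor - a, acceptor),
          end = c(donor, acceptor + (read_length - a)))
  })
}

#' Simulate reads for one event in one tissue
#'
#' Error-free, single-end, fixed-length reads. Inclusion-isoform evidence
#' (exon-body placements plus the two inclusion junctions) is generated
#' with weight `psi`, exclusion-junction evidence with weight `1 - psi`;
#' the number of reads per placement class is Poisson with mean
#' `depth x number of placements x weight`, placements uniform. Optional
#' intronic background reads (pre-mRNA / mis-splicing noise) are added at
#' `bg_rate x depth` per intronic placement so intron counters are
#' exercised.
#'
#' @param trio an [exon_trio()].
#' @param psi inclusion level in `[0, 1]` for this tissue.
#' @param depth expected reads per placement at weight 1.
#' @param read_length read length L_r (bp).
#' @param anchor junction anchor o (bp).
#' @param bg_rate intronic background rate relative to `depth`.
#' @return a [read_alignments()] data.frame.
#' @export
simulate_reads <- function(trio, psi, depth, read_length = 32, anchor = 8,
                           bg_rate = 0.02) {
  stopifnot(psi >= 0, psi <= 1, depth >= 0)
  l_r <- read_length
  o <- anchor
  e <- trio$exon
  n_body_pos <- (e[2] - e[1]) - l_r + 1
  n_junc_pos <- l_r + 1 - 2 * o
  stopifnot(n_body_pos >= 1, n_junc_pos >= 1)
  blocks <- list()
  ids <- character(0)
  add <- function(tag, blks) {
    if (!length(blks)) return()
    ids <<- c(ids, paste0(trio$event_id, ":", tag, ":",
                          seq_along(blks) + length(ids)))
    blocks <<- c(blocks, blks)
  }
  # exon body
  n <- stats::rpois(1, psi * depth * n_body_pos)
  if (n > 0) {
    starts <- e[1] + sample.int(n_body_pos, n, replace = TRUE) - 1
    add("body", lapply(starts, function(s) cbind(start = s, end = s + l_r)))
  }
  # inclusion junctions
  junctions <- list(
    ji_up = c(trio$up_flank_exon_end, e[1]),
    ji_down = c(e[2], trio$down_flank_exon_start)
  )
  for (tag in names(junctions)) {
    jc <- junctions[[tag]]
    n <- stats::rpois(1, psi * depth * n_junc_pos)
    if (n > 0) {
      anchors <- o + sample.int(n_junc_pos, n, replace = TRUE) - 1
      add(tag, .junction_blocks(jc[1], jc[2], anchors, l_r))
    }
  }
  # exclusion junction
  n <- stats::rpois(1, (1 - psi) * depth * n_junc_pos)
  if (n > 0) {
    anchors <- o + sample.int(n_junc_pos, n, replace = TRUE) - 1
    add("je", .junction_blocks(trio$up_flank_exon_end,
                               trio$down_flank_exon_start, anchors, l_r))
  }
  # intronic background
  for (region in c("up_intron", "down_intron")) {
    iv <- trio[[region]]
    n_pos <- (iv[2] - iv[1]) - l_r + 1
    if (n_pos < 1) next
    n <- stats::rpois(1, bg_rate * depth * n_pos)
    if (n > 0) {
      starts <- iv[1] + sample.int(n_pos, n, replace = TRUE) - 1
      add(paste0("bg_", region),
          lapply(starts, function(s) cbind(start = s, end = s + l_r)))
    }
  }
  read_alignments(ids, rep(trio$chrom, length(ids)), blocks)
}

#' Expected percent-spliced-in under the placement model
#'
#' Closed-form expectation of the P feature for a tissue sequenced at
#' inclusion level `psi`: expected inclusion evidence is
#' `psi x depth x (L_e - L_r + 1 + 2(L_r + 1 - 2o))` reads and expected
#' exclusion evidence `(1 - psi) x depth x (L_r + 1 - 2o)` reads; after
#' effective-length normalisation the lengths cancel and P reduces to
#' `psi`. Computed from the formulas (not returned as `psi` directly) so
#' it doubles as an algebraic cross-check of the normalisation chain.
#'
#' @param psi inclusion level in `[0, 1]`.
#' @param exon_length L_e (bp).
#' @param read_length L_r (bp).
#' @param anchor o (bp).
#' @param depth expected reads per placement (cancels for `depth > 0`).
#' @return expected P in `[0, 1]`.
#' @export
expected_p <- function(psi, exon_length, read_length, anchor, depth = 1) {
  eff_junc <- read_length + 1 - 2 * anchor
  eff_ni <- exon_length - read_length + 1 + 2 * eff_junc
  stopifnot(eff_junc >= 1, eff_ni >= 1, depth > 0)
  e_ni <- psi * depth * eff_ni
  e_ne <- (1 - psi) * depth * eff_junc
  norm_ni <- e_ni / eff_ni
  norm_ne <- e_ne / eff_junc
  if (norm_ni + norm_ne == 0) return(0)
  norm_ni / (norm_ni + norm_ne)
}

#' Simulate a complete two-tissue cassette-exon study
#'
#' Generates `n_es` skipped-exon events and `n_non_es` constitutive events,
#' each on its own chromosome, with reads for two tissues (tags `B` and
#' `S`). Defaults emulate a strongly tissue-differential design: skipped
#' exons are included at `psi_b = 0.3` in tissue B and `psi_s = 0.9` in
#' tissue S, while constitutive exons are fully included (`psi = 1`) in
#' both. Reads are 32 bp, error-free and single-end, with an 8 bp junction
#' anchor and a 2% intronic background.
#'
#' @param n_es,n_non_es event counts per class.
#' @param psi_es named vector `c(B = , S = )` of inclusion levels for ES
#'   events.
#' @param psi_non_es same for constitutive events (default fully included).
#' @param depth expected reads per placement.
#' @param read_length,anchor read length L_r and junction anchor o (bp).
#' @param seed integer seed; the whole study is reproducible from it.
#' @param ... passed to [simulate_event()] (length ranges, base
#'   composition, ...).
#' @return a list with `events` (event table), `labels` (factor, levels
#'   `ES`/`non-ES`), `genome` (named character vector), `reads` (list of
#'   two [read_alignments()], `B` and `S`), `meta` (list of two
#'   [sample_meta()]), and `psi` (per-event inclusion levels used, matrix).
#' @export
simulate_es_study <- function(n_es, n_non_es,
                              psi_es = c(B = 0.3, S = 0.9),
                              psi_non_es = c(B = 1, S = 1),
                              depth = 2, read_length = 32, anchor = 8,
                              seed = 1, ...) {
  set.seed(seed)
  n_total <- n_es + n_non_es
  labels <- factor(rep(c("ES", "non-ES"), c(n_es, n_non_es)),
                   levels = c("ES", "non-ES"))
  event_rows <- vector("list", n_total)
  genome <- character(n_total)
  reads_b <- vector("list", n_total)
  reads_s <- vector("list", n_total)
  psi_used <- matrix(NA_real_, n_total, 2, dimnames = list(NULL, c("B", "S")))
  for (i in seq_len(n_total)) {
    ev <- simulate_event(sprintf("ev%04d", i), read_length = read_length,
                         ...)
    psi <- if (labels[i] == "ES") psi_es else psi_non_es
    psi_used[i, ] <- psi[c("B", "S")]
    reads_b[[i]] <- simulate_reads(ev$trio, psi[["B"]], depth,
                                   read_length, anchor)
    reads_s[[i]] <- simulate_reads(ev$trio, psi[["S"]], depth,
                                   read_length, anchor)
    event_rows[[i]] <- as_event_row(ev$trio)
    genome[i] <- ev$sequence
  }
  events <- do.call(rbind, event_rows)
  names(genome) <- events$event_id
  rownames(psi_used) <- events$event_id
  bind_reads <- function(lst) {
    out <- do.call(rbind, lst)
    class(out) <- c("read_alignments", "data.frame")
    out
  }
  all_b <- bind_reads(reads_b)
  all_s <- bind_reads(reads_s)
  list(events = events, labels = labels, genome = genome,
       reads = list(B = all_b, S = all_s),
       meta = list(
         B = sample_meta("B", read_length, anchor, max(1, nrow(all_b))),
         S = sample_meta("S", read_length, anchor, max(1, nrow(all_s)))),
       psi = psi_used)
}

#' Write a simulated genome as FASTA
#'
#' @param genome named character vector of chromosome sequences.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}
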