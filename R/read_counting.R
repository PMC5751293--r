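#' Simplified spliced read alignments
#'
#' Reads are stored as a data.frame with one row per alignment record:
#' `read_id`, `chrom`, and a list-column `blocks` holding, per read, an
#' integer matrix with columns `start`, `end` (0-based half-open aligned
#' segments in increasing, non-overlapping order). Gaps between consecutive
#' blocks are splices. Every supplied record counts once; deduplication of
#' multi-mappers is the caller's (or the alignment adapter's) job.
#'
#' @param read_id character vector.
#' @param chrom character vector.
#' @param blocks list of 2-column matrices (start, end).
#' @return a data.frame of class `read_alignments`.
#' @export
read_alignments <- function(read_id, chrom, blocks) {
  if (length(chrom) == 1) chrom <- rep(chrom, length(read_id))
  stopifnot(length(read_id) == length(chrom),
            length(read_id) == length(blocks))
  blocks <- lapply(blocks, function(b) {
    b <- matrix(as.numeric(b), ncol = 2,
                dimnames = list(NULL, c("start", "end")))
    if (any(b[, 2] <= b[, 1]))
      stop("every alignment block must have end > start")
    if (nrow(b) > 1 && any(b[-1, 1] < b[-nrow(b), 2]))
      stop("alignment blocks must be non-overlapping and increasing")
    b
  })
  out <- data.frame(read_id = as.character(read_id),
                    chrom = as.character(chrom),
                    stringsAsFactors = FALSE)
  out$blocks <- blocks
  class(out) <- c("read_alignments", class(out))
  out
}

# first/last aligned coordinate per read and block count, vectorised
.read_span <- function(reads) {
  list(
    first = vapply(reads$blocks, function(b) b[1, 1], numeric(1)),
    last = vapply(reads$blocks, function(b) b[nrow(b), 2], numeric(1)),
    nblocks = vapply(reads$blocks, nrow, integer(1))
  )
}

#' Intersection-strict region read count
#'
#' Counts reads whose every aligned base lies inside `region`
#' (intersection-strict counting): a read overlapping a region boundary is
#' not counted. Splice gaps may span region internals; only aligned blocks
#' must be contained.
#'
#' @param reads a [read_alignments()] data.frame (pre-filtered to one
#'   chromosome).
#' @param region numeric `c(start, end)`, 0-based half-open.
#' @return integer count.
#' @export
count_region_reads <- function(reads, region) {
  stopifnot(length(region) == 2, region[2] > region[1])
  if (nrow(reads) == 0) return(0L)
  span <- .read_span(reads)
  sum(span$first >= region[1] & span$last <= region[2])
}

# logical vector: which reads are intersection-strict inside region
.reads_in_region <- function(reads, region) {
  if (nrow(reads) == 0) return(logical(0))
  span <- .read_span(reads)
  span$first >= region[1] & span$last <= region[2]
}

#' Anchored junction read count
#'
#' Counts reads supporting the exact splice junction `donor -> acceptor`:
#' the read must contain two consecutive aligned blocks, the first ending
#' exactly at `donor` and the second starting exactly at `acceptor`, with at
#' least `o` aligned bases in each of those two blocks (the anchors).
#' Near-miss splice coordinates are not counted; alignment slop is the
#' upstream aligner's responsibility.
#'
#' @param reads a [read_alignments()] data.frame.
#' @param donor,acceptor 0-based splice coordinates, `donor < acceptor`.
#' @param o minimum anchor length in bp on each side of the splice.
#' @return integer count.
#' @export
count_junction_reads <- function(reads, donor, acceptor, o) {
  stopifnot(donor < acceptor, o >= 1)
  if (nrow(reads) == 0) return(0L)
  sum(.junction_support(reads, donor, acceptor, o))
}

# logical vector over reads: supports the donor->acceptor splice with anchors
.junction_support <- function(reads, donor, acceptor, o) {
  vapply(reads$blocks, function(b) {
    n <- nrow(b)
    if (n < 2) return(FALSE)
    for (i in seq_len(n - 1)) {
      if (b[i, 2] == donor && b[i + 1, 1] == acceptor) {
        left_anchor <- b[i, 2] - b[i, 1]
        right_anchor <- b[i + 1, 2] - b[i + 1, 1]
        return(left_anchor >= o && right_anchor >= o)
      }
    }
    FALSE
  }, logical(1))
}

#' The six basic read counts of one event in one tissue
#'
#' Produces, from simplified alignments, the per-event count set:
#' * `n_exon`, `n_up_intron`, `n_down_intron`, `n_gene` — intersection-strict
#'   counts over the respective intervals;
#' * `n_ni` — reads supporting the inclusion isoform: reads fully inside the
#'   alternative exon plus anchored junction reads on either inclusion
#'   junction (upstream-flank end to exon start; exon end to downstream-flank
#'   start). A read supporting the exon body and/or both inclusion junctions
#'   still counts once.
#' * `n_ne` — anchored junction reads on the exclusion (skip) junction
#'   (upstream-flank end to downstream-flank start).
#'
#' @param reads a [read_alignments()] data.frame on `trio$chrom`.
#' @param trio an [exon_trio()].
#' @param o junction anchor length (bp).
#' @return named integer vector with elements
#'   `n_exon, n_up_intron, n_down_intron, n_ni, n_ne, n_gene`.
#' @export
count_set <- function(reads, trio, o = 8) {
  validate_exon_trio(trio)
  if (nrow(reads) > 0 && any(reads$chrom != trio$chrom))
    stop("reads contain chromosome(s) other than '", trio$chrom,
         "'; pre-filter to the event's chromosome")
  in_exon <- .reads_in_region(reads, trio$exon)
  junc_up <- if (nrow(reads)) {
    .junction_support(reads, trio$up_flank_exon_end, trio$exon[1], o)
  } else logical(0)
  junc_down <- if (nrow(reads)) {
    .junction_support(reads, trio$exon[2], trio$down_flank_exon_start, o)
  } else logical(0)
  junc_skip <- if (nrow(reads)) {
    .junction_support(reads, trio$up_flank_exon_end,
                      trio$down_flank_exon_start, o)
  } else logical(0)
  c(n_exon = sum(in_exon),
    n_up_intron = count_region_reads(reads, trio$up_intron),
    n_down_intron = count_region_reads(reads, trio$down_intron),
    n_ni = sum(in_exon | junc_up | junc_down),
    n_ne = sum(junc_skip),
    n_gene = count_region_reads(reads, trio$gene))
}

#' Per-tissue sample constants
#'
#' Constants that parameterise effective-length normalisation: the read
#' length, the junction anchor, and the total number of mapped reads in the
#' sample.
#'
#' @param tissue_tag short tag, conventionally `"B"` (brain) or `"S"`
#'   (skeletal muscle).
#' @param read_length read length L_r in bp.
#' @param anchor junction anchor o in bp; must satisfy `1 <= o <= L_r / 2`.
#' @param total_mapped total mapped reads T_num in the sample.
#' @return a named list of class `sample_meta`.
#' @export
sample_meta <- function(tissue_tag, read_length, anchor, total_mapped) {
  stopifnot(read_length >= 1, total_mapped >= 1)
  if (anchor < 1 || anchor > read_length / 2)
    stop("anchor must satisfy 1 <= o <= read_length/2 (got o = ", anchor,
         ", read_length = ", read_length, ")")
  structure(list(tissue_tag = as.character(tissue_tag),
                 read_length = read_length,
                 anchor = anchor,
                 total_mapped = total_mapped),
            class = "sample_meta")
}

#' Count all events of a study in one tissue
#'
#' @param reads a [read_alignments()] data.frame (whole tissue).
#' @param events event table (see [read_events()]).
#' @param o junction anchor length (bp).
#' @return data.frame with `event_id` and the six count columns.
#' @export
count_events <- function(reads, events, o = 8) {
  split_reads <- split(seq_len(nrow(reads)), reads$chrom)
  rows <- lapply(seq_len(nrow(events)), function(i) {
    trio <- as_exon_trio(events[i, , drop = FALSE])
    idx <- split_reads[[trio$chrom]]
    chrom_reads <- if (is.null(idx)) reads[0, ] else reads[idx, ]
    cbind(data.frame(event_id = trio$event_id, stringsAsFactors = FALSE),
          as.data.frame(as.list(count_set(chrom_reads, trio, o = o))))
  })
  do.call(rbind, rows)
}

#' Read a reads TSV
#'
#' The primary alignment exchange format: tab-separated with columns
#' `read_id`, `chrom`, `blocks`, where `blocks` is a comma-separated list of
#' `start-end` half-open segments, e.g. `"92-100,200-224"`.
#'
#' @param path TSV path.
#' @return a [read_alignments()] data.frame.
#' @export
read_reads_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c("character", "character",
                                          "character"))
  blocks <- lapply(strsplit(tab$blocks, ",", fixed = TRUE), function(parts) {
    coords <- do.call(rbind, strsplit(parts, "-", fixed = TRUE))
    matrix(as.numeric(coords), ncol = 2)
  })
  read_alignments(tab$read_id, tab$chrom, blocks)
}

#' Write a reads TSV
#'
#' @param reads a [read_alignments()] data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reads_tsv <- function(reads, path) {
  blocks <- vapply(reads$blocks, function(b) {
    paste(sprintf("%d-%d", as.integer(b[, 1]), as.integer(b[, 2])),
          collapse = ",")
  }, character(1))
  utils::write.table(
    data.frame(read_id = reads$read_id, chrom = reads$chrom, blocks = blocks,
               stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert SAM text records to simplified reads (adapter)
#'
#' Optional adapter for coordinate-sorted SAM text: parses POS and CIGAR into
#' aligned reference blocks. `M`, `=` and `X` consume reference into the
#' current block; `D` extends it (a deletion does not split a block); `N`
#' closes the current block (splice); `I`, `S`, `H`, `P` consume no
#' reference. Unmapped records (flag 0x4) are dropped; all other flags are
#' passed through.
#'
#' @param path SAM file path (text, with or without header lines).
#' @return a [read_alignments()] data.frame.
#' @export
read_sam_reads <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines))
    return(read_alignments(character(0), character(0), list()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(fields, function(f) {
    !bitwAnd(as.integer(f[2]), 4L)
  }, logical(1))
  fields <- fields[keep]
  blocks <- lapply(fields, function(f) {
    pos <- as.numeric(f[4]) - 1  # SAM POS is 1-based
    cigar <- f[6]
    ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
    lens <- as.numeric(sub("[MIDNSHP=X]", "", ops))
    kinds <- sub("\\d+", "", ops)
    starts <- numeric(0); ends <- numeric(0)
    cur_start <- pos; cur <- pos; open <- FALSE
    for (i in seq_along(kinds)) {
      k <- kinds[i]; l <- lens[i]
      if (k %in% c("M", "=", "X", "D")) {
        if (!open) { cur_start <- cur; open <- TRUE }
        cur <- cur + l
      } else if (k == "N") {
        if (open) { starts <- c(starts, cur_start); ends <- c(ends, cur) }
        cur <- cur + l
        open <- FALSE
      }
      # I, S, H, P: no reference consumed
    }
    if (open) { starts <- c(starts, cur_start); ends <- c(ends, cur) }
    cbind(start = starts, end = ends)
  })
  read_alignments(vapply(fields, `[`, character(1), 1),
                  vapply(fields, `[`, character(1), 3),
                  blocks)
}
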