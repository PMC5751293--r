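#' Structure (length) features of an event
#'
#' Lengths in bp of the upstream intron, the alternative exon and the
#' downstream intron. Lengths are strand-invariant.
#'
#' @param trio an [exon_trio()].
#' @return named numeric vector `c(len_up_intron, len_exon, len_down_intron)`.
#' @export
structure_features <- function(trio) {
  validate_exon_trio(trio)
  c(len_up_intron = trio$up_intron[2] - trio$up_intron[1],
    len_exon = trio$exon[2] - trio$exon[1],
    len_down_intron = trio$down_intron[2] - trio$down_intron[1])
}

#' Single-nucleotide counts of a sequence
#'
#' Counts A, C, G and T in a DNA string, case-insensitively. Ambiguity codes
#' (N, R, Y, ...) and any other characters contribute to no count, so the
#' four counts sum to the sequence length only for unambiguous sequence.
#'
#' @param sequence a character scalar (may be empty).
#' @return named integer vector `c(A = , C = , G = , T = )`.
#' @examples
#' nucleotide_counts("ACGT")   # one of each
#' nucleotide_counts("aaNCt")  # lowercase counted, N ignored
#' @export
nucleotide_counts <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (is.na(sequence) || nchar(sequence) == 0)
    return(c(A = 0L, C = 0L, G = 0L, T = 0L))
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  counts <- tabulate(match(chars, c("A", "C", "G", "T")), nbins = 4L)
  names(counts) <- c("A", "C", "G", "T")
  counts
}

# Extract the [start, end) slice of a chromosome (0-based half-open),
# reverse-complemented when rc is TRUE. genome is a named character vector
# or a Biostrings::DNAStringSet.
slice_genome <- function(genome, chrom, start, end, rc = FALSE) {
  if (inherits(genome, "DNAStringSet")) {
    if (!chrom %in% names(genome))
      stop("chromosome '", chrom, "' not found in genome")
    len <- length(genome[[chrom]])
    if (start < 0 || end > len)
      stop("interval [", start, ", ", end, ") out of bounds for '", chrom,
           "' (length ", len, ")")
    s <- Biostrings::subseq(genome[[chrom]], start + 1L, end)
    if (rc) s <- Biostrings::reverseComplement(s)
    return(as.character(s))
  }
  if (!chrom %in% names(genome))
    stop("chromosome '", chrom, "' not found in genome")
  len <- nchar(genome[[chrom]])
  if (start < 0 || end > len)
    stop("interval [", start, ", ", end, ") out of bounds for '", chrom,
         "' (length ", len, ")")
  s <- substr(genome[[chrom]], start + 1L, end)
  if (rc)
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

#' Sequence feature vector (structure + nucleotide composition) of an event
#'
#' Computes the 15 genome-sequence-derived features of one event: three
#' region lengths followed by A/C/G/T counts for the upstream intron, the
#' alternative exon and the downstream intron, in that fixed order.
#'
#' For minus-strand events the nucleotide counts are computed on the reverse
#' complement of each region slice so that composition is read in
#' transcriptional orientation; region slots keep their genomic identity
#' (the upstream-intron slot always refers to the genomically upstream
#' intron). Set `genomic_orientation = TRUE` to count the plus-strand
#' sequence regardless of strand, e.g. when replicating an analysis that did
#' not orient by strand. Lengths are unaffected by either choice.
#'
#' @param trio an [exon_trio()].
#' @param genome a named character vector or `Biostrings::DNAStringSet`
#'   keyed by chromosome name (see [read_genome()]).
#' @param genomic_orientation logical; if `TRUE`, never reverse-complement.
#' @return named numeric vector of length 15 in the order
#'   `len_up_intron, len_exon, len_down_intron`, then
#'   `A,C,G,T` for `up_intron`, `exon`, `down_intron`.
#' @export
sequence_feature_vector <- function(trio, genome, genomic_orientation = FALSE) {
  lens <- structure_features(trio)
  rc <- identical(trio$strand, "-") && !genomic_orientation
  regions <- list(up_intron = trio$up_intron,
                  exon = trio$exon,
                  down_intron = trio$down_intron)
  counts <- unlist(lapply(names(regions), function(region) {
    iv <- regions[[region]]
    cnt <- nucleotide_counts(
      slice_genome(genome, trio$chrom, iv[1], iv[2], rc = rc))
    names(cnt) <- paste0(tolower(names(cnt)), "_", region)
    cnt
  }))
  c(lens, counts)
}

#' Read a genome FASTA
#'
#' Thin wrapper over `Biostrings::readDNAStringSet` that keeps only the
#' first whitespace-delimited token of each FASTA header as the chromosome
#' name.
#'
#' @param path FASTA file path.
#' @return a `DNAStringSet` named by chromosome.
#' @export
read_genome <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Names of the 15 sequence features, in their fixed column order
#' @return character vector of length 15.
#' @export
sequence_feature_names <- function() {
  c("len_up_intron", "len_exon", "len_down_intron",
    as.vector(t(outer(c("up_intron", "exon", "down_intron"),
                      c("a", "c", "g", "t"),
                      function(r, b) paste0(b, "_", r)))))
}
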