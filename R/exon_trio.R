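#' Candidate cassette-exon event ("exon trio")
#'
#' An `exon_trio` describes one candidate skipped-exon event: the alternative
#' (cassette) exon together with its upstream and downstream introns, the
#' boundaries of the flanking constitutive exons, and the span of the host
#' gene. All coordinates are 0-based, half-open `[start, end)` on the genomic
#' (plus) strand, so every length is simply `end - start`. Regions are stored
#' in genomic order regardless of strand; the `strand` flag only affects how
#' sequence-derived features are read out.
#'
#' Structural invariants enforced by the constructor:
#' * `up_intron` ends where the exon starts; the exon ends where
#'   `down_intron` starts;
#' * the upstream flanking exon ends exactly at the start of `up_intron`
#'   and the downstream flanking exon starts exactly at the end of
#'   `down_intron`;
#' * the gene interval contains all three regions;
#' * every interval is non-empty.
#'
#' @param event_id character scalar identifying the event.
#' @param chrom chromosome (sequence) name.
#' @param strand `"+"` or `"-"`.
#' @param up_intron,exon,down_intron integer vectors of length 2,
#'   `c(start, end)`, 0-based half-open.
#' @param up_flank_exon_end 0-based coordinate where the upstream flanking
#'   exon ends (must equal `up_intron[1]`).
#' @param down_flank_exon_start 0-based coordinate where the downstream
#'   flanking exon starts (must equal `down_intron[2]`).
#' @param gene integer vector of length 2, gene span.
#' @return an object of class `exon_trio` (a named list).
#' @examples
#' trio <- exon_trio("ev1", "chr1", "+",
#'                   up_intron = c(200, 500), exon = c(500, 650),
#'                   down_intron = c(650, 900),
#'                   up_flank_exon_end = 200, down_flank_exon_start = 900,
#'                   gene = c(50, 1100))
#' structure_features(trio)
#' @export
exon_trio <- function(event_id, chrom, strand,
                      up_intron, exon, down_intron,
                      up_flank_exon_end, down_flank_exon_start,
                      gene) {
  trio <- list(
    event_id = as.character(event_id),
    chrom = as.character(chrom),
    strand = as.character(strand),
    up_intron = as.numeric(up_intron),
    exon = as.numeric(exon),
    down_intron = as.numeric(down_intron),
    up_flank_exon_end = as.numeric(up_flank_exon_end),
    down_flank_exon_start = as.numeric(down_flank_exon_start),
    gene = as.numeric(gene)
  )
  class(trio) <- "exon_trio"
  validate_exon_trio(trio)
  trio
}

#' Validate an exon_trio object
#'
#' Checks interval well-formedness and the adjacency/containment invariants
#' documented in [exon_trio()]. Called by the constructor; exported so that
#' readers of external annotation tables can re-validate.
#'
#' @param trio an `exon_trio`.
#' @return `trio`, invisibly, if valid; otherwise an error naming the
#'   offending region.
#' @export
validate_exon_trio <- function(trio) {
  stopifnot(inherits(trio, "exon_trio"))
  if (!trio$strand %in% c("+", "-"))
    stop("strand must be '+' or '-', got '", trio$strand, "'")
  for (region in c("up_intron", "exon", "down_intron", "gene")) {
    iv <- trio[[region]]
    if (length(iv) != 2 || anyNA(iv))
      stop("region '", region, "' must be c(start, end)")
    if (iv[2] <= iv[1])
      stop("malformed interval in region '", region,
           "': end (", iv[2], ") <= start (", iv[1], ")")
  }
  if (trio$up_intron[2] != trio$exon[1])
    stop("up_intron must end where exon starts (event ", trio$event_id, ")")
  if (trio$exon[2] != trio$down_intron[1])
    stop("exon must end where down_intron starts (event ", trio$event_id, ")")
  if (trio$up_flank_exon_end != trio$up_intron[1])
    stop("up_flank_exon_end must equal up_intron start (event ",
         trio$event_id, ")")
  if (trio$down_flank_exon_start != trio$down_intron[2])
    stop("down_flank_exon_start must equal down_intron end (event ",
         trio$event_id, ")")
  if (trio$gene[1] > trio$up_intron[1] || trio$gene[2] < trio$down_intron[2])
    stop("gene interval must contain the intron-exon-intron block (event ",
         trio$event_id, ")")
  invisible(trio)
}

#' @export
print.exon_trio <- function(x, ...) {
  cat("<exon_trio> ", x$event_id, "  ", x$chrom, " (", x$strand, ")\n",
      sep = "")
  cat(sprintf("  up_intron  [%d, %d)  (%d bp)\n",
              x$up_intron[1], x$up_intron[2], x$up_intron[2] - x$up_intron[1]))
  cat(sprintf("  exon       [%d, %d)  (%d bp)\n",
              x$exon[1], x$exon[2], x$exon[2] - x$exon[1]))
  cat(sprintf("  down_intron[%d, %d)  (%d bp)\n",
              x$down_intron[1], x$down_intron[2],
              x$down_intron[2] - x$down_intron[1]))
  cat(sprintf("  gene       [%d, %d)\n", x$gene[1], x$gene[2]))
  invisible(x)
}

event_table_columns <- c(
  "event_id", "chrom", "strand",
  "up_intron_start", "up_intron_end",
  "exon_start", "exon_end",
  "down_intron_start", "down_intron_end",
  "up_flank_exon_end", "down_flank_exon_start",
  "gene_start", "gene_end"
)

#' Convert one row of an event table to an exon_trio
#'
#' @param row a single-row data.frame with the columns written by
#'   [write_events()].
#' @return an `exon_trio`.
#' @export
as_exon_trio <- function(row) {
  missing_cols <- setdiff(event_table_columns, names(row))
  if (length(missing_cols))
    stop("event table row is missing columns: ",
         paste(missing_cols, collapse = ", "))
  exon_trio(
    event_id = row$event_id, chrom = row$chrom, strand = row$strand,
    up_intron = c(row$up_intron_start, row$up_intron_end),
    exon = c(row$exon_start, row$exon_end),
    down_intron = c(row$down_intron_start, row$down_intron_end),
    up_flank_exon_end = row$up_flank_exon_end,
    down_flank_exon_start = row$down_flank_exon_start,
    gene = c(row$gene_start, row$gene_end)
  )
}

#' Flatten an exon_trio to a one-row data.frame
#'
#' @param trio an `exon_trio`.
#' @return a one-row data.frame with the standard event-table columns.
#' @export
as_event_row <- function(trio) {
  validate_exon_trio(trio)
  data.frame(
    event_id = trio$event_id, chrom = trio$chrom, strand = trio$strand,
    up_intron_start = trio$up_intron[1], up_intron_end = trio$up_intron[2],
    exon_start = trio$exon[1], exon_end = trio$exon[2],
    down_intron_start = trio$down_intron[1],
    down_intron_end = trio$down_intron[2],
    up_flank_exon_end = trio$up_flank_exon_end,
    down_flank_exon_start = trio$down_flank_exon_start,
    gene_start = trio$gene[1], gene_end = trio$gene[2],
    stringsAsFactors = FALSE
  )
}

#' Read an event annotation table
#'
#' Reads a tab-separated event table with one row per candidate event.
#' Coordinates in the file are 0-based half-open by default; set
#' `one_based = TRUE` for annotation dialects whose starts are 1-based
#' inclusive (starts are then shifted down by one).
#'
#' @param path path to a TSV with the columns listed in [as_exon_trio()].
#' @param one_based logical; convert 1-based inclusive starts to the internal
#'   0-based half-open convention.
#' @return a data.frame of events; every row validates as an `exon_trio`.
#' @export
read_events <- function(path, one_based = FALSE) {
  events <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(event_table_columns, names(events))
  if (length(missing_cols))
    stop("event table ", path, " is missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (one_based) {
    start_cols <- c("up_intron_start", "exon_start", "down_intron_start",
                    "gene_start", "up_flank_exon_end")
    # up_flank_exon_end is an exclusive end in 0-based terms == 1-based
    # inclusive end, so it is left alone; only true starts shift.
    start_cols <- setdiff(start_cols, "up_flank_exon_end")
    for (cc in start_cols) events[[cc]] <- events[[cc]] - 1L
    events$down_flank_exon_start <- events$down_flank_exon_start - 1L
  }
  for (i in seq_len(nrow(events))) as_exon_trio(events[i, , drop = FALSE])
  events
}

#' Write an event annotation table
#'
#' @param events data.frame of events (e.g. from [simulate_es_study()]).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.table(events[, event_table_columns], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
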