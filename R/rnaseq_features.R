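#' Effective-length normalisation of the six basic counts
#'
#' Converts raw per-event counts into reads per effective position per
#' mapped read, scaled by 1e9. The effective length of a region is the
#' number of distinct read start positions compatible with it:
#' * exon body: `L_e - L_r + 1`;
#' * a single junction (up/down intron, exclusion): `L_r + 1 - 2o`;
#' * the inclusion isoform: `L_e - L_r + 1 + 2 * (L_r + 1 - 2o)`
#'   (exon body plus the two inclusion junctions);
#' * gene: `L_g - L_r + 1`.
#'
#' Each normalised value is `n * 1e9 / (effective_length * T_num)` with
#' `T_num` the sample's total mapped reads. The 1e9 constant is kept as is
#' (not the per-kilobase-per-million RPKM convention).
#'
#' @param cs a count set (named vector from [count_set()]).
#' @param meta a [sample_meta()].
#' @param trio the event's [exon_trio()] (provides exon and gene lengths).
#' @return named numeric vector
#'   `norm_exon, norm_up_intron, norm_down_intron, norm_ni, norm_ne,
#'   norm_gene`.
#' @export
normalize_counts <- function(cs, meta, trio) {
  validate_exon_trio(trio)
  l_e <- trio$exon[2] - trio$exon[1]
  l_g <- trio$gene[2] - trio$gene[1]
  l_r <- meta$read_length
  o <- meta$anchor
  eff_exon <- l_e - l_r + 1
  eff_junc <- l_r + 1 - 2 * o
  eff_ni <- eff_exon + 2 * eff_junc
  eff_gene <- l_g - l_r + 1
  if (eff_exon < 1)
    stop("non-positive effective exon length: L_e - L_r + 1 = ", eff_exon,
         " (exon shorter than read length)")
  if (eff_junc < 1)
    stop("non-positive effective junction length: L_r + 1 - 2o = ", eff_junc)
  if (eff_gene < 1)
    stop("non-positive effective gene length: L_g - L_r + 1 = ", eff_gene)
  scale <- 1e9 / meta$total_mapped
  c(norm_exon = unname(cs["n_exon"]) * scale / eff_exon,
    norm_up_intron = unname(cs["n_up_intron"]) * scale / eff_junc,
    norm_down_intron = unname(cs["n_down_intron"]) * scale / eff_junc,
    norm_ni = unname(cs["n_ni"]) * scale / eff_ni,
    norm_ne = unname(cs["n_ne"]) * scale / eff_junc,
    norm_gene = unname(cs["n_gene"]) * scale / eff_gene)
}

#' Percent-spliced-in feature (P)
#'
#' `P = NORM_ni / (NORM_ni + NORM_ne)`, the normalised inclusion fraction.
#' For an event with no junction evidence in either direction (both inputs
#' zero) P is defined as 0 rather than NaN; use the companion return value
#' of [rs_features()] if the no-evidence state must be distinguished.
#'
#' @param norm_ni,norm_ne non-negative normalised inclusion/exclusion
#'   counts.
#' @return a value in `[0, 1]`.
#' @export
p_feature <- function(norm_ni, norm_ne) {
  if (norm_ni < 0 || norm_ne < 0)
    stop("normalised counts must be non-negative")
  if (norm_ni + norm_ne == 0) return(0)
  norm_ni / (norm_ni + norm_ne)
}

#' Tissue divergence features
#'
#' Brain-minus-muscle differences of the six normalised counts and of P,
#' in the fixed order exon, up_intron, down_intron, ni, ne, gene, P.
#'
#' @param brain,muscle named numeric vectors from [normalize_counts()] with
#'   an additional `p` element.
#' @return named numeric vector
#'   `delta_exon, ..., delta_gene, delta_p` (7 values).
#' @export
divergence_features <- function(brain, muscle) {
  parts <- c("norm_exon", "norm_up_intron", "norm_down_intron",
             "norm_ni", "norm_ne", "norm_gene", "p")
  stopifnot(all(parts %in% names(brain)), all(parts %in% names(muscle)),
            all(is.finite(unlist(brain[parts]))),
            all(is.finite(unlist(muscle[parts]))))
  delta <- unlist(brain[parts]) - unlist(muscle[parts])
  names(delta) <- c("delta_exon", "delta_up_intron", "delta_down_intron",
                    "delta_ni", "delta_ne", "delta_gene", "delta_p")
  delta
}

.initial_names <- function() {
  base <- c("n_exon", "n_up_intron", "n_down_intron", "n_ni", "n_ne",
            "n_gene")
  c(paste0("s_", base), paste0("b_", base))
}

.equilibrium_names <- function() {
  parts <- c("exon", "up_intron", "down_intron", "ni", "ne", "gene")
  c(as.vector(vapply(parts, function(p) {
    c(paste0("s_norm_", p), paste0("b_norm_", p), paste0("delta_", p))
  }, character(3))), "s_p", "b_p", "delta_p")
}

#' Names of the 48 assembled features, in their fixed column order
#'
#' The order is: the 12 initial features (muscle then brain, each
#' exon, up_intron, down_intron, ni, ne, gene raw counts); the 21
#' equilibrium features (for each of exon, up_intron, down_intron, ni, ne,
#' gene: muscle normalised, brain normalised, divergence; then muscle P,
#' brain P, divergence of P); the 15 sequence features (three lengths, then
#' A/C/G/T per region). This order is persisted in feature-table headers so
#' that trained models are column-order-safe.
#'
#' @return character vector of length 48.
#' @export
rs_feature_names <- function() {
  c(.initial_names(), .equilibrium_names(), sequence_feature_names())
}

#' Column selectors for the five experimental feature sets
#'
#' @param set one of `"initial"` (12 raw counts), `"equilibrium"`
#'   (21 normalised/P/divergence), `"rnaseq"` (33 = initial + equilibrium),
#'   `"sequence"` (15 genome-derived), `"rs"` (all 48).
#' @return character vector of feature names (a subset of
#'   [rs_feature_names()]).
#' @export
feature_set_columns <- function(set = c("rs", "initial", "equilibrium",
                                        "rnaseq", "sequence")) {
  set <- match.arg(set)
  switch(set,
         initial = .initial_names(),
         equilibrium = .equilibrium_names(),
         rnaseq = c(.initial_names(), .equilibrium_names()),
         sequence = sequence_feature_names(),
         rs = rs_feature_names())
}

#' Assemble the 48-dimensional feature vector of one event
#'
#' Concatenates the two tissues' raw counts (initial features), the
#' equilibrium features (normalised counts, P, divergences) and the sequence
#' features into the fixed 48-column order of [rs_feature_names()].
#'
#' @param initial_b,initial_s named count vectors from [count_set()] for
#'   brain and muscle.
#' @param eq named numeric vector of the 21 equilibrium features (names as
#'   in [feature_set_columns]`("equilibrium")`).
#' @param seq_features named numeric vector of the 15 sequence features.
#' @return named numeric vector of length 48.
#' @export
assemble_rs <- function(initial_b, initial_s, eq, seq_features) {
  count_names <- c("n_exon", "n_up_intron", "n_down_intron", "n_ni", "n_ne",
                   "n_gene")
  if (!all(count_names %in% names(initial_b)) ||
      !all(count_names %in% names(initial_s)))
    stop("initial count sets must contain the six basic counts")
  if (!setequal(names(eq), .equilibrium_names()))
    stop("equilibrium block must contain exactly the 21 equilibrium features")
  if (!setequal(names(seq_features), sequence_feature_names()))
    stop("sequence block must contain exactly the 15 sequence features")
  initial <- c(stats::setNames(unname(initial_s[count_names]),
                               paste0("s_", count_names)),
               stats::setNames(unname(initial_b[count_names]),
                               paste0("b_", count_names)))
  out <- c(initial, eq[.equilibrium_names()],
           seq_features[sequence_feature_names()])
  if (anyNA(out)) stop("assembled feature vector contains missing values")
  stopifnot(length(out) == 48)
  out
}

#' Full feature extraction for one event
#'
#' Runs the whole per-event feature pipeline: normalises both tissues'
#' counts, computes P per tissue and the seven divergences, computes the
#' sequence features, and assembles the 48-vector.
#'
#' @param counts_b,counts_s named count vectors from [count_set()].
#' @param meta_b,meta_s [sample_meta()] for brain and muscle.
#' @param trio the event's [exon_trio()].
#' @param genome genome sequence source (see [sequence_feature_vector()]).
#' @param genomic_orientation passed to [sequence_feature_vector()].
#' @return a list with `features` (named 48-vector) and `no_junction_evidence`
#'   (logical: TRUE when neither tissue had inclusion or exclusion junction
#'   evidence, in which case both P values defaulted to 0).
#' @export
rs_features <- function(counts_b, counts_s, meta_b, meta_s, trio, genome,
                        genomic_orientation = FALSE) {
  norm_b <- normalize_counts(counts_b, meta_b, trio)
  norm_s <- normalize_counts(counts_s, meta_s, trio)
  p_b <- p_feature(norm_b["norm_ni"], norm_b["norm_ne"])
  p_s <- p_feature(norm_s["norm_ni"], norm_s["norm_ne"])
  no_evidence <-
    (norm_b["norm_ni"] + norm_b["norm_ne"] == 0) &&
    (norm_s["norm_ni"] + norm_s["norm_ne"] == 0)
  brain <- c(as.list(norm_b), p = unname(p_b))
  muscle <- c(as.list(norm_s), p = unname(p_s))
  delta <- divergence_features(brain, muscle)
  parts <- c("exon", "up_intron", "down_intron", "ni", "ne", "gene")
  eq <- stats::setNames(numeric(21), .equilibrium_names())
  for (p in parts) {
    eq[paste0("s_norm_", p)] <- norm_s[paste0("norm_", p)]
    eq[paste0("b_norm_", p)] <- norm_b[paste0("norm_", p)]
    eq[paste0("delta_", p)] <- delta[paste0("delta_", p)]
  }
  eq["s_p"] <- p_s
  eq["b_p"] <- p_b
  eq["delta_p"] <- delta["delta_p"]
  seq_features <- sequence_feature_vector(trio, genome,
                                          genomic_orientation)
  list(features = assemble_rs(counts_b, counts_s, eq, seq_features),
       no_junction_evidence = unname(no_evidence))
}

#' Build the feature matrix for a whole study
#'
#' Maps [rs_features()] over an event table given per-tissue reads (or
#' precomputed count tables) and returns the design matrix used for
#' training/prediction.
#'
#' @param events event table (see [read_events()]).
#' @param genome genome sequence source.
#' @param reads_b,reads_s per-tissue [read_alignments()]; ignored when
#'   `counts_b`/`counts_s` are supplied.
#' @param meta_b,meta_s [sample_meta()] per tissue.
#' @param counts_b,counts_s optional precomputed count data.frames from
#'   [count_events()] (columns `event_id` + six counts).
#' @param feature_set which column subset to return (see
#'   [feature_set_columns()]).
#' @param genomic_orientation passed to [sequence_feature_vector()].
#' @return a numeric matrix, one row per event (rownames = event ids),
#'   columns in the fixed documented order.
#' @export
build_feature_matrix <- function(events, genome,
                                 reads_b = NULL, reads_s = NULL,
                                 meta_b, meta_s,
                                 counts_b = NULL, counts_s = NULL,
                                 feature_set = "rs",
                                 genomic_orientation = FALSE) {
  if (is.null(counts_b)) {
    stopifnot(!is.null(reads_b))
    counts_b <- count_events(reads_b, events, o = meta_b$anchor)
  }
  if (is.null(counts_s)) {
    stopifnot(!is.null(reads_s))
    counts_s <- count_events(reads_s, events, o = meta_s$anchor)
  }
  rownames(counts_b) <- counts_b$event_id
  rownames(counts_s) <- counts_s$event_id
  count_names <- c("n_exon", "n_up_intron", "n_down_intron", "n_ni", "n_ne",
                   "n_gene")
  rows <- lapply(seq_len(nrow(events)), function(i) {
    trio <- as_exon_trio(events[i, , drop = FALSE])
    cb <- unlist(counts_b[trio$event_id, count_names])
    cs <- unlist(counts_s[trio$event_id, count_names])
    if (anyNA(cb) || anyNA(cs))
      stop("no counts for event '", trio$event_id, "' in one of the tissues")
    rs_features(cb, cs, meta_b, meta_s, trio, genome,
                genomic_orientation)$features
  })
  mat <- do.call(rbind, rows)
  rownames(mat) <- events$event_id
  mat[, feature_set_columns(feature_set), drop = FALSE]
}

#' Write / read a feature table
#'
#' Feature tables are TSVs with an `event_id` column, optionally a `label`
#' column, and the feature columns in their documented fixed order.
#'
#' @param features numeric matrix from [build_feature_matrix()].
#' @param path output TSV path.
#' @param labels optional character/factor vector aligned with the rows.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path, labels = NULL) {
  out <- data.frame(event_id = rownames(features), stringsAsFactors = FALSE)
  if (!is.null(labels)) out$label <- as.character(labels)
  out <- cbind(out, as.data.frame(features))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @return for `read_feature_table`: a list with `features` (matrix) and
#'   `labels` (character vector or NULL).
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  labels <- if ("label" %in% names(tab)) tab$label else NULL
  feature_cols <- setdiff(names(tab), c("event_id", "label"))
  mat <- as.matrix(tab[, feature_cols, drop = FALSE])
  rownames(mat) <- tab$event_id
  list(features = mat, labels = labels)
}
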