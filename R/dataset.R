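#' Consensus labels from three detector hit-lists
#'
#' An event hit by at least two of the three detectors is labelled `ES`;
#' an event hit by none is `non-ES`; an event hit by exactly one detector
#' is `unlabeled` (retained in tables but excluded from train/test export).
#'
#' @param hits logical matrix or data.frame with exactly three indicator
#'   columns (one per detector), one row per event.
#' @return factor with levels `ES`, `non-ES`, `unlabeled`.
#' @export
consensus_label <- function(hits) {
  hits <- as.matrix(hits)
  if (ncol(hits) != 3)
    stop("exactly three detector indicator columns are required, got ",
         ncol(hits))
  if (anyNA(hits)) stop("missing detector indicators")
  storage.mode(hits) <- "logical"
  n_hits <- rowSums(hits)
  factor(ifelse(n_hits >= 2, "ES",
                ifelse(n_hits == 0, "non-ES", "unlabeled")),
         levels = c("ES", "non-ES", "unlabeled"))
}

#' Read a detector hit-list
#'
#' Hit-lists are plain text, one event id per line.
#'
#' @param path file path.
#' @return character vector of event ids.
#' @export
read_hit_list <- function(path) {
  ids <- readLines(path)
  ids[nzchar(trimws(ids))]
}

#' Build the hit indicator matrix for a set of events
#'
#' @param event_ids character vector of all candidate event ids.
#' @param hit_lists list of three character vectors (event ids hit by each
#'   detector), e.g. from [read_hit_list()].
#' @return logical matrix, `length(event_ids)` rows x 3 columns.
#' @export
hit_matrix <- function(event_ids, hit_lists) {
  if (length(hit_lists) != 3)
    stop("three detector hit-lists are required")
  out <- vapply(hit_lists, function(hl) event_ids %in% hl,
                logical(length(event_ids)))
  out <- matrix(out, ncol = 3,
                dimnames = list(event_ids,
                                names(hit_lists) %||%
                                  paste0("detector", 1:3)))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stratified train/test split with exact test-class counts
#'
#' Draws exactly `n_test_pos` positive and `n_test_neg` negative instances
#' into the test set (seeded, without replacement); everything else goes to
#' the training set. Unlabeled instances are dropped with a message.
#'
#' @param labels factor/character labels per instance (`ES` / `non-ES`,
#'   possibly `unlabeled`).
#' @param n_test_pos,n_test_neg exact positive/negative test counts.
#' @param seed integer seed.
#' @param positive positive-class label.
#' @param negative negative-class label.
#' @return list with integer index vectors `train` and `test` (indices into
#'   `labels`).
#' @export
stratified_split <- function(labels, n_test_pos, n_test_neg, seed,
                             positive = "ES", negative = "non-ES") {
  labels <- as.character(labels)
  unlabeled <- !labels %in% c(positive, negative)
  if (any(unlabeled))
    message(sum(unlabeled), " unlabeled instance(s) excluded from the split")
  pos_idx <- which(labels == positive)
  neg_idx <- which(labels == negative)
  if (length(pos_idx) < n_test_pos)
    stop("only ", length(pos_idx), " positive instances; cannot place ",
         n_test_pos, " in the test set")
  if (length(neg_idx) < n_test_neg)
    stop("only ", length(neg_idx), " negative instances; cannot place ",
         n_test_neg, " in the test set")
  set.seed(seed)
  test_pos <- if (n_test_pos > 0) sort(sample(pos_idx, n_test_pos))
              else integer(0)
  test_neg <- if (n_test_neg > 0) sort(sample(neg_idx, n_test_neg))
              else integer(0)
  test <- sort(c(test_pos, test_neg))
  train <- sort(setdiff(c(pos_idx, neg_idx), test))
  list(train = train, test = test)
}

#' Independent-set remainder
#'
#' The number of catalogue events left over after the train and test sets
#' are removed; used to size an independent evaluation set.
#'
#' @param total total catalogued instances.
#' @param used_test,used_train instances consumed by the test and train
#'   sets.
#' @return `total - used_test - used_train`.
#' @export
holdout_remainder <- function(total, used_test, used_train) {
  remainder <- total - used_test - used_train
  if (remainder < 0)
    stop("test + train (", used_test + used_train,
         ") exceed the total (", total, ")")
  remainder
}
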