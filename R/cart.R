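# Deterministic unpruned CART (Gini) base learner.
#
# Kept in-package (rather than wrapping an existing tree package) so that
# split tie-breaking is fully specified, models serialise to plain JSON,
# and fits are bit-reproducible. Trees are grown to purity by default, as
# ensemble base learners usually are.
#
# Node table layout (parallel vectors, node 1 is the root):
#   feature   column index of the split, NA for leaves
#   threshold split point; rows with x <= threshold go left
#   left/right child node ids (NA for leaves)
#   prob      K-column matrix of leaf class proportions (rows for internal
#             nodes hold the node's own distribution, handy for inspection)

gini_impurity <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  1 - sum((counts / n)^2)
}

# Find the best (feature, threshold) split of rows `idx` by exhaustive scan.
# Ties broken toward the lowest feature index, then the lowest threshold.
best_split <- function(x, y_int, idx, n_classes, min_leaf) {
  n <- length(idx)
  parent_counts <- tabulate(y_int[idx], nbins = n_classes)
  parent_gini <- gini_impurity(parent_counts)
  best <- list(gain = 1e-12, feature = NA_integer_,
               threshold = NA_real_)
  for (j in seq_len(ncol(x))) {
    xj <- x[idx, j]
    ord <- order(xj, method = "radix")
    xs <- xj[ord]
    ys <- y_int[idx][ord]
    distinct <- which(xs[-n] < xs[-1])  # split after these positions
    if (!length(distinct)) next
    # cumulative class counts after each position
    cum <- apply(vapply(seq_len(n_classes), function(k) ys == k,
                        logical(n)), 2, cumsum)
    nl <- distinct
    nr <- n - nl
    ok <- nl >= min_leaf & nr >= min_leaf
    if (!any(ok)) next
    left_counts <- cum[distinct, , drop = FALSE]
    right_counts <- matrix(parent_counts, nrow = length(distinct),
                           ncol = n_classes, byrow = TRUE) - left_counts
    gini_l <- 1 - rowSums((left_counts / nl)^2)
    gini_r <- 1 - rowSums((right_counts / nr)^2)
    weighted <- (nl * gini_l + nr * gini_r) / n
    gain <- parent_gini - weighted
    gain[!ok] <- -Inf
    jbest <- which.max(gain)  # first max -> lowest threshold
    if (gain[jbest] > best$gain) {
      pos <- distinct[jbest]
      best <- list(gain = gain[jbest], feature = j,
                   threshold = (xs[pos] + xs[pos + 1]) / 2)
    }
  }
  best
}

# Fit an unpruned CART on matrix x and integer-coded labels.
fit_cart <- function(x, y, min_split = 2, min_leaf = 1, max_depth = 30L) {
  stopifnot(is.matrix(x), is.factor(y), nrow(x) == length(y))
  n_classes <- nlevels(y)
  y_int <- as.integer(y)
  nodes <- new.env(parent = emptyenv())
  nodes$feature <- integer(0)
  nodes$threshold <- numeric(0)
  nodes$left <- integer(0)
  nodes$right <- integer(0)
  nodes$prob <- NULL

  new_node <- function(idx) {
    counts <- tabulate(y_int[idx], nbins = n_classes)
    id <- length(nodes$feature) + 1L
    nodes$feature[id] <- NA_integer_
    nodes$threshold[id] <- NA_real_
    nodes$left[id] <- NA_integer_
    nodes$right[id] <- NA_integer_
    nodes$prob <- rbind(nodes$prob, counts / sum(counts))
    id
  }

  grow <- function(idx, depth) {
    id <- new_node(idx)
    counts <- tabulate(y_int[idx], nbins = n_classes)
    if (length(idx) < min_split || sum(counts > 0) < 2 ||
        depth >= max_depth)
      return(id)
    split <- best_split(x, y_int, idx, n_classes, min_leaf)
    if (is.na(split$feature)) return(id)
    go_left <- x[idx, split$feature] <= split$threshold
    nodes$feature[id] <- split$feature
    nodes$threshold[id] <- split$threshold
    nodes$left[id] <- grow(idx[go_left], depth + 1L)
    nodes$right[id] <- grow(idx[!go_left], depth + 1L)
    id
  }

  grow(seq_len(nrow(x)), 0L)
  structure(list(feature = nodes$feature, threshold = nodes$threshold,
                 left = nodes$left, right = nodes$right,
                 prob = nodes$prob, levels = levels(y)),
            class = "cart_tree")
}

# Per-row leaf class-probability matrix.
predict_cart <- function(tree, x) {
  stopifnot(is.matrix(x))
  out <- matrix(NA_real_, nrow(x), ncol(tree$prob))
  for (i in seq_len(nrow(x))) {
    id <- 1L
    while (!is.na(tree$feature[id])) {
      id <- if (x[i, tree$feature[id]] <= tree$threshold[id])
        tree$left[id] else tree$right[id]
    }
    out[i, ] <- tree$prob[id, ]
  }
  colnames(out) <- tree$levels
  out
}
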