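#' Random feature partition
#'
#' Splits the `D` feature indices into random disjoint subsets of size
#' `subset_size` (one remainder subset of smaller size is allowed when
#' `subset_size` does not divide `D`). Uses the current RNG state, so a
#' fixed seed reproduces the partition.
#'
#' @param n_features number of features D.
#' @param subset_size features per subset M (`1 <= M <= D`).
#' @return list of integer vectors, disjoint, jointly covering `1:D`.
#' @export
partition_features <- function(n_features, subset_size) {
  if (subset_size < 1 || subset_size > n_features)
    stop("subset_size must be between 1 and the number of features (",
         n_features, ")")
  perm <- sample.int(n_features)
  split(perm, ceiling(seq_along(perm) / subset_size))
}

#' Fit a block PCA rotation matrix
#'
#' For each feature subset, centres the selected columns, computes the
#' principal axes of their covariance (optionally on a row subsample), and
#' places the loading matrix as a diagonal block of a `D x D` rotation,
#' rearranged back to the original feature positions. All principal axes
#' are retained (axes of near-zero eigenvalue are still orthonormal), so
#' the assembled matrix is orthogonal. A subset whose columns are all
#' constant gets an identity block with a warning.
#'
#' Eigenvector signs are fixed so that each axis's largest-magnitude
#' loading is positive, making the rotation reproducible across platforms.
#'
#' @param x numeric training matrix (N x D).
#' @param subsets feature partition from [partition_features()].
#' @param sample_rows optional integer vector of rows to use for the PCA
#'   (the rotation is still applied to all rows).
#' @return an object of class `rotation_matrix`: list with `rotation`
#'   (D x D), `centers` (per-feature means used for the PCA) and `subsets`.
#' @export
fit_rotation <- function(x, subsets, sample_rows = NULL) {
  stopifnot(is.matrix(x), nrow(x) >= 2)
  d <- ncol(x)
  rot <- matrix(0, d, d)
  centers <- numeric(d)
  rows <- if (is.null(sample_rows)) seq_len(nrow(x)) else sample_rows
  for (idx in subsets) {
    xs <- x[rows, idx, drop = FALSE]
    mu <- colMeans(xs)
    centers[idx] <- mu
    xc <- sweep(xs, 2, mu)
    v <- crossprod(xc) / max(1, nrow(xc) - 1)
    if (all(abs(v) < 1e-12)) {
      warning("constant feature subset {", paste(idx, collapse = ","),
              "}: identity rotation block substituted")
      rot[idx, idx] <- diag(length(idx))
      next
    }
    ev <- eigen(v, symmetric = TRUE)
    vec <- ev$vectors
    for (k in seq_len(ncol(vec))) {  # deterministic sign convention
      m <- which.max(abs(vec[, k]))
      if (vec[m, k] < 0) vec[, k] <- -vec[, k]
    }
    rot[idx, idx] <- vec
  }
  structure(list(rotation = rot, centers = centers, subsets = subsets),
            class = "rotation_matrix")
}

#' Fit a Rotation Forest classifier
#'
#' Trains an ensemble of `n_trees` unpruned CART trees, each on a rotated
#' copy of the training data. Per tree, the feature set is randomly
#' partitioned into subsets of `subset_size` features, each subset is
#' rotated onto its principal axes (PCA over the training rows, optionally
#' over a per-subset class-and-bootstrap subsample), the per-subset loading
#' blocks are assembled into an orthogonal `D x D` matrix aligned with the
#' original feature positions, and the tree is fit on `x %*% rotation`.
#' Prediction averages the trees' leaf class distributions and takes the
#' class of maximum mean confidence.
#'
#' @param x numeric feature matrix (rows = instances); column names are
#'   recorded and enforced at prediction when present.
#' @param y class labels (factor or coercible); at least two classes.
#' @param n_trees ensemble size L.
#' @param subset_size features per rotation subset M.
#' @param seed integer seed; the fit is fully reproducible given
#'   `(seed, x, y, config)`.
#' @param class_sample_fraction probability of keeping each class in the
#'   per-subset PCA sample (1 = use every class; values below 1 give the
#'   classic per-subset class subsampling).
#' @param bootstrap draw a 75% bootstrap of the (class-filtered) rows for
#'   each subset's PCA.
#' @param min_split,min_leaf,max_depth base-tree growth limits; defaults
#'   grow to purity.
#' @param positive label of the positive class, used to break prediction
#'   ties (defaults to `"ES"` when present, otherwise the last level).
#'   Sensitivity to the positive class is favoured at exact ties.
#' @param identity_rotation if `TRUE`, skip PCA and use identity rotations
#'   (the ensemble then reduces to a committee of plain trees; intended for
#'   verification).
#' @return an object of class `rotation_forest`.
#' @seealso [predict.rotation_forest()], [write_rotation_forest()]
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(100, 0), 50), matrix(rnorm(100, 4), 50))
#' colnames(x) <- c("f1", "f2")
#' y <- factor(rep(c("non-ES", "ES"), each = 50))
#' fit <- rotation_forest(x, y, n_trees = 5, subset_size = 1, seed = 42)
#' table(predict(fit, x), y)
#' @export
rotation_forest <- function(x, y, n_trees = 10, subset_size = 3, seed = 1,
                            class_sample_fraction = 1, bootstrap = FALSE,
                            min_split = 2, min_leaf = 1, max_depth = 30L,
                            positive = NULL, identity_rotation = FALSE) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("x must be a numeric matrix")
  if (anyNA(x)) stop("x contains missing values")
  y <- as.factor(y)
  y <- droplevels(y)
  if (nlevels(y) < 2)
    stop("training labels contain a single class; need at least two")
  if (length(y) != nrow(x)) stop("x and y sizes differ")
  if (n_trees < 1) stop("n_trees must be >= 1")
  if (class_sample_fraction <= 0 || class_sample_fraction > 1)
    stop("class_sample_fraction must be in (0, 1]")
  if (is.null(positive))
    positive <- if ("ES" %in% levels(y)) "ES" else levels(y)[nlevels(y)]
  if (!positive %in% levels(y))
    stop("positive class '", positive, "' is not a label level")
  d <- ncol(x)
  config <- list(n_trees = n_trees, subset_size = subset_size, seed = seed,
                 class_sample_fraction = class_sample_fraction,
                 bootstrap = bootstrap, min_split = min_split,
                 min_leaf = min_leaf, max_depth = max_depth,
                 identity_rotation = identity_rotation)
  set.seed(seed)
  trees <- vector("list", n_trees)
  for (l in seq_len(n_trees)) {
    if (identity_rotation) {
      rotation <- structure(list(rotation = diag(d), centers = numeric(d),
                                 subsets = list(seq_len(d))),
                            class = "rotation_matrix")
    } else {
      subsets <- partition_features(d, subset_size)
      sample_rows <- NULL
      if (class_sample_fraction < 1 || bootstrap) {
        keep_classes <- levels(y)[stats::runif(nlevels(y)) <=
                                    class_sample_fraction]
        if (!length(keep_classes))
          keep_classes <- sample(levels(y), 1)
        rows <- which(y %in% keep_classes)
        if (bootstrap)
          rows <- sort(sample(rows, size = max(2, round(0.75 * length(rows))),
                              replace = TRUE))
        sample_rows <- rows
      }
      rotation <- fit_rotation(x, subsets, sample_rows)
    }
    rotated <- x %*% rotation$rotation
    trees[[l]] <- list(rotation = rotation,
                       tree = fit_cart(rotated, y, min_split = min_split,
                                       min_leaf = min_leaf,
                                       max_depth = max_depth))
  }
  structure(list(trees = trees, levels = levels(y), positive = positive,
                 feature_names = colnames(x), config = config,
                 n_train = nrow(x)),
            class = "rotation_forest")
}

# validate and align prediction input
.check_newdata <- function(object, newdata) {
  newdata <- as.matrix(newdata)
  d <- nrow(object$trees[[1]]$rotation$rotation)
  if (ncol(newdata) != d)
    stop("newdata has ", ncol(newdata), " columns; model expects ", d)
  if (!is.null(object$feature_names) && !is.null(colnames(newdata)) &&
      !identical(colnames(newdata), object$feature_names)) {
    if (!all(object$feature_names %in% colnames(newdata)))
      stop("newdata column names do not match the training features")
    newdata <- newdata[, object$feature_names, drop = FALSE]
  }
  newdata
}

#' Per-class ensemble confidence
#'
#' Rotates each instance by every tree's rotation matrix, reads off that
#' tree's leaf class distribution, and averages over trees. Rows sum to 1.
#'
#' @param model a [rotation_forest()] fit.
#' @param newdata numeric matrix with the model's feature columns.
#' @return numeric matrix, one row per instance, one column per class.
#' @export
predict_confidence <- function(model, newdata) {
  stopifnot(inherits(model, "rotation_forest"))
  newdata <- .check_newdata(model, newdata)
  conf <- 0
  for (tr in model$trees) {
    rotated <- newdata %*% tr$rotation$rotation
    conf <- conf + predict_cart(tr$tree, rotated)
  }
  conf <- conf / length(model$trees)
  colnames(conf) <- model$levels
  rownames(conf) <- rownames(newdata)
  conf
}

#' Predict classes or confidences from a Rotation Forest
#'
#' @param object a [rotation_forest()] fit.
#' @param newdata numeric matrix of instances.
#' @param type `"class"` for labels (maximum mean confidence, exact ties
#'   broken toward the positive class), `"prob"` for the confidence matrix.
#' @param ... unused.
#' @return factor of labels, or the confidence matrix.
#' @export
predict.rotation_forest <- function(object, newdata,
                                    type = c("class", "prob"), ...) {
  type <- match.arg(type)
  conf <- predict_confidence(object, newdata)
  if (type == "prob") return(conf)
  pos_col <- match(object$positive, object$levels)
  labels <- apply(conf, 1, function(row) {
    top <- which(row == max(row))
    if (pos_col %in% top) pos_col else top[1]
  })
  factor(object$levels[labels], levels = object$levels)
}

#' @export
print.rotation_forest <- function(x, ...) {
  cfg <- x$config
  cat("Rotation Forest classifier\n")
  cat("  trees:       ", cfg$n_trees, "\n")
  cat("  subset size: ", cfg$subset_size, "\n")
  cat("  features:    ",
      nrow(x$trees[[1]]$rotation$rotation), "\n")
  cat("  classes:     ", paste(x$levels, collapse = ", "),
      " (positive: ", x$positive, ")\n", sep = "")
  cat("  trained on:  ", x$n_train, "instances, seed", cfg$seed, "\n")
  invisible(x)
}

#' @export
summary.rotation_forest <- function(object, ...) {
  nodes <- vapply(object$trees,
                  function(tr) length(tr$tree$feature), integer(1))
  leaves <- vapply(object$trees,
                   function(tr) sum(is.na(tr$tree$feature)), integer(1))
  out <- list(config = object$config, levels = object$levels,
              positive = object$positive,
              nodes_per_tree = nodes, leaves_per_tree = leaves)
  class(out) <- "summary.rotation_forest"
  out
}

#' @export
print.summary.rotation_forest <- function(x, ...) {
  cat("Rotation Forest with", x$config$n_trees, "trees\n")
  cat("  nodes per tree: ", paste(x$nodes_per_tree, collapse = " "), "\n")
  cat("  leaves per tree:", paste(x$leaves_per_tree, collapse = " "), "\n")
  cat("  classes:", paste(x$levels, collapse = ", "),
      "| positive:", x$positive, "\n")
  invisible(x)
}

#' Serialize a Rotation Forest to versioned JSON
#'
#' Writes the full model (config, per-tree feature partitions, rotation
#' blocks, centring offsets and tree structures) as JSON with full numeric
#' precision, so that a reloaded model predicts identically and two fits
#' with the same seed serialise byte-identically.
#'
#' @param model a [rotation_forest()] fit.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rotation_forest <- function(model, path) {
  stopifnot(inherits(model, "rotation_forest"))
  payload <- list(
    format = "rotation_forest",
    version = 1L,
    config = model$config,
    levels = model$levels,
    positive = model$positive,
    feature_names = model$feature_names,
    n_train = model$n_train,
    trees = lapply(model$trees, function(tr) {
      list(subsets = lapply(tr$rotation$subsets, as.integer),
           centers = tr$rotation$centers,
           rotation = tr$rotation$rotation,
           tree = list(feature = tr$tree$feature,
                       threshold = tr$tree$threshold,
                       left = tr$tree$left, right = tr$tree$right,
                       prob = tr$tree$prob, levels = tr$tree$levels))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = FALSE)
  invisible(path)
}

#' @rdname write_rotation_forest
#' @return for `read_rotation_forest`: the reconstructed
#'   `rotation_forest` object.
#' @export
read_rotation_forest <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(payload$format, "rotation_forest"))
    stop("not a rotation_forest model file: ", path)
  num_vec <- function(lst) {  # JSON null -> NA; unboxed scalars allowed
    if (is.null(lst)) return(NA_real_)
    if (!is.list(lst)) return(as.numeric(lst))
    vapply(lst, function(v) if (is.null(v)) NA_real_ else as.numeric(v),
           numeric(1))
  }
  row_major <- function(rows) do.call(rbind, lapply(rows, num_vec))
  trees <- lapply(payload$trees, function(tr) {
    rotation <- structure(
      list(rotation = row_major(tr$rotation),
           centers = num_vec(tr$centers),
           subsets = lapply(tr$subsets, function(s) as.integer(num_vec(s)))),
      class = "rotation_matrix")
    tree <- structure(
      list(feature = as.integer(num_vec(tr$tree$feature)),
           threshold = num_vec(tr$tree$threshold),
           left = as.integer(num_vec(tr$tree$left)),
           right = as.integer(num_vec(tr$tree$right)),
           prob = row_major(tr$tree$prob),
           levels = vapply(tr$tree$levels, as.character, character(1))),
      class = "cart_tree")
    list(rotation = rotation, tree = tree)
  })
  config <- payload$config
  config$bootstrap <- isTRUE(config$bootstrap)
  config$identity_rotation <- isTRUE(config$identity_rotation)
  structure(list(trees = trees,
                 levels = vapply(payload$levels, as.character, character(1)),
                 positive = payload$positive,
                 feature_names = if (is.null(payload$feature_names)) NULL
                                 else vapply(payload$feature_names,
                                             as.character, character(1)),
                 config = config,
                 n_train = payload$n_train),
            class = "rotation_forest")
}
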