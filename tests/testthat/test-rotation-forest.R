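test_that("feature partitions are disjoint covers with a remainder rule", {
  set.seed(1)
  p48 <- partition_features(48, 3)
  expect_length(p48, 16)
  expect_true(all(lengths(p48) == 3))
  expect_setequal(unlist(p48), 1:48)

  p5 <- partition_features(5, 2)
  expect_setequal(lengths(p5), c(2, 2, 1))
  expect_setequal(unlist(p5), 1:5)

  set.seed(7); a <- partition_features(20, 4)
  set.seed(7); b <- partition_features(20, 4)
  expect_identical(a, b)
  expect_error(partition_features(5, 6), "between 1 and")
})

test_that("rotation matrices are orthogonal and invert cleanly", {
  set.seed(2)
  x <- matrix(rnorm(200 * 12), 200)
  x[, 3] <- 2 * x[, 1] + x[, 2]  # correlated columns included
  subsets <- partition_features(12, 3)
  rot <- fit_rotation(x, subsets)
  r <- rot$rotation
  expect_lt(max(abs(crossprod(r) - diag(12))), 1e-8)
  expect_equal(x %*% r %*% t(r), x, tolerance = 1e-8)
})

test_that("single-feature subsets give a signed permutation of identity", {
  set.seed(3)
  x <- matrix(rnorm(50 * 6), 50)
  rot <- fit_rotation(x, partition_features(6, 1))
  expect_equal(abs(rot$rotation), diag(6), tolerance = 1e-12)
})

test_that("uncorrelated unit-variance subsets rotate to near-identity", {
  # eigenvectors of a near-identity covariance are axis-aligned up to
  # sign/permutation; compare |R| column-wise against the eigen oracle
  set.seed(4)
  n <- 5000
  x <- matrix(rnorm(n * 4), n)
  rot <- fit_rotation(x, list(1:4))
  oracle <- eigen(stats::cov(x), symmetric = TRUE)$vectors
  expect_equal(abs(rot$rotation), abs(oracle), tolerance = 1e-8)
  # and the leading loading magnitude is near 1 for well-separated axes
  expect_lt(max(abs(crossprod(rot$rotation) - diag(4))), 1e-8)
})

test_that("constant subsets fall back to identity blocks with a warning", {
  set.seed(5)
  x <- cbind(matrix(rnorm(40), 20), 1, 2)
  expect_warning(rot <- fit_rotation(x, list(1:2, 3:4)),
                 "identity rotation block")
  expect_equal(rot$rotation[3:4, 3:4], diag(2))
})

test_that("identity-rotation ensembles reduce to a plain-tree committee", {
  # one informative feature, so any correct tree must split on it at the
  # midpoint of the single separating gap
  set.seed(6)
  x <- matrix(rnorm(50 * 4), 50)
  x[26:50, 2] <- x[26:50, 2] + 8
  colnames(x) <- paste0("f", 1:4)
  y <- factor(rep(c("non-ES", "ES"), each = 25), levels = c("ES", "non-ES"))
  blobs <- list(x = x, y = y)
  fit1 <- rotation_forest(blobs$x, blobs$y, n_trees = 1, subset_size = 4,
                          seed = 9, identity_rotation = TRUE)
  fit5 <- rotation_forest(blobs$x, blobs$y, n_trees = 5, subset_size = 4,
                          seed = 9, identity_rotation = TRUE)
  set.seed(10)
  grid <- matrix(rnorm(200 * 4), 200)
  grid[, 2] <- grid[, 2] + 4  # probe around the decision boundary
  colnames(grid) <- colnames(blobs$x)
  # all identity trees are the same plain tree; committees agree
  expect_equal(predict(fit1, grid), predict(fit5, grid))
  # and agree with an independently implemented unpruned CART (rpart)
  skip_if_not_installed("rpart")
  df <- data.frame(y = blobs$y, blobs$x)
  rp <- rpart::rpart(y ~ ., df, method = "class",
                     control = rpart::rpart.control(minsplit = 2, cp = 0,
                                                    xval = 0))
  rp_pred <- predict(rp, data.frame(grid), type = "class")
  expect_equal(as.character(predict(fit1, grid)),
               as.character(rp_pred))
})

test_that("training separates well-separated Gaussian blobs perfectly", {
  blobs <- make_blobs(n_per_class = 100, d = 10, sep = 10, seed = 11)
  fit <- rotation_forest(blobs$x, blobs$y, n_trees = 10, subset_size = 3,
                         seed = 12)
  expect_equal(mean(predict(fit, blobs$x) == blobs$y), 1)
})

test_that("fits are deterministic and serialise byte-identically", {
  blobs <- make_blobs(n_per_class = 30, d = 6, sep = 8, seed = 13)
  f1 <- tempfile(fileext = ".json")
  f2 <- tempfile(fileext = ".json")
  write_rotation_forest(
    rotation_forest(blobs$x, blobs$y, n_trees = 4, seed = 14), f1)
  write_rotation_forest(
    rotation_forest(blobs$x, blobs$y, n_trees = 4, seed = 14), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("JSON round trip restores an identically predicting model", {
  blobs <- make_blobs(n_per_class = 30, d = 6, sep = 4, seed = 15)
  fit <- rotation_forest(blobs$x, blobs$y, n_trees = 6, subset_size = 2,
                         seed = 16, class_sample_fraction = 0.9,
                         bootstrap = TRUE)
  path <- tempfile(fileext = ".json")
  write_rotation_forest(fit, path)
  back <- read_rotation_forest(path)
  set.seed(17)
  probe <- matrix(rnorm(300, mean = 4), ncol = 6)
  colnames(probe) <- colnames(blobs$x)
  expect_equal(predict_confidence(back, probe),
               predict_confidence(fit, probe))
  expect_identical(predict(back, probe), predict(fit, probe))
})

test_that("invalid training inputs are rejected", {
  blobs <- make_blobs(n_per_class = 10, d = 3, seed = 18)
  one_class <- factor(rep("ES", 20))
  expect_error(rotation_forest(blobs$x, one_class), "single class")
  x_na <- blobs$x
  x_na[1, 1] <- NA
  expect_error(rotation_forest(x_na, blobs$y), "missing values")
  fit <- rotation_forest(blobs$x, blobs$y, n_trees = 2, seed = 19)
  expect_error(predict(fit, blobs$x[, 1:2]), "columns")
})

test_that("confidence is the tree average, rows sum to 1, ties favour ES", {
  stub <- make_stub_forest(list(c(0.8, 0.2), c(0.4, 0.6)))
  x <- matrix(0, 3, 2)
  conf <- predict_confidence(stub, x)
  expect_equal(unname(conf[1, ]), c(0.6, 0.4))
  expect_equal(unname(rowSums(conf)), rep(1, 3))
  expect_equal(as.character(predict(stub, x)), rep("non-ES", 3))

  unanimous <- make_stub_forest(list(c(0, 1), c(0, 1)))
  expect_equal(unname(predict_confidence(unanimous, x)[1, ]), c(0, 1))

  tie <- make_stub_forest(list(c(0.5, 0.5)))
  expect_equal(as.character(predict(tie, x)), rep("ES", 3))
})

test_that("predicted labels are the argmax of the confidence matrix", {
  blobs <- make_blobs(n_per_class = 40, d = 5, sep = 3, seed = 20)
  fit <- rotation_forest(blobs$x, blobs$y, n_trees = 7, subset_size = 2,
                         seed = 21)
  set.seed(22)
  probe <- matrix(rnorm(50 * 5, mean = 1.5), 50)
  colnames(probe) <- colnames(blobs$x)
  conf <- predict_confidence(fit, probe)
  labels <- predict(fit, probe)
  for (i in seq_len(nrow(probe))) {
    top <- which(conf[i, ] == max(conf[i, ]))
    expect_true(match(as.character(labels[i]), colnames(conf)) %in% top)
  }
  expect_equal(unname(rowSums(conf)), rep(1, 50))
})

test_that("print and summary report the model shape", {
  blobs <- make_blobs(n_per_class = 15, d = 4, seed = 23)
  fit <- rotation_forest(blobs$x, blobs$y, n_trees = 3, seed = 24)
  expect_output(print(fit), "Rotation Forest")
  expect_output(print(summary(fit)), "nodes per tree")
})
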