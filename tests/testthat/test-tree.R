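# CART induction: split search, prediction, rendering, invariants.

test_that("constant targets give a single leaf", {
  X <- matrix(runif(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  tr <- fit_regression_tree(X, rep(0.37, 20), min_leaf = 2)
  expect_true(tr$root$leaf)
  expect_equal(predict(tr, X), rep(0.37, 20))
  # pure-class input for the classifier likewise
  tc <- fit_classification_tree(X, rep(1, 20), min_leaf = 2)
  expect_true(tc$root$leaf)
  expect_equal(tc$root$value, 1)
})

test_that("a step function is recovered with its threshold", {
  set.seed(50)
  n <- 2000
  X <- cbind(x1 = runif(n, 0, 6), x2 = runif(n, 0, 6))
  y <- as.numeric(X[, "x1"] > 3)
  tr <- fit_regression_tree(X, y, max_depth = 2, min_leaf = 20)
  expect_equal(tr$root$feature, 1)
  expect_lt(abs(tr$root$threshold - 3), 0.2)
  leaves <- sort(unique(predict(tr, X)))
  expect_lt(min(leaves), 0.05)
  expect_gt(max(leaves), 0.95)
  expect_identical(split_features(tr)$feature[1], "x1")
})

test_that("depth-1 splits equal exhaustive enumeration", {
  # hand-listed six points
  X <- cbind(a = c(1, 2, 3, 10, 11, 12), b = c(5, 1, 4, 2, 3, 6))
  y <- c(0.1, 0.2, 0.1, 0.8, 0.9, 0.85)
  tr <- fit_regression_tree(X, y, max_depth = 1, min_leaf = 1)
  oracle <- brute_best_split(X, y, min_leaf = 1, kind = "regression")
  expect_equal(tr$root$feature, oracle$feature)
  expect_equal(tr$root$threshold, oracle$threshold)
  expect_equal(tr$root$gain, oracle$gain)
  expect_equal(tr$root$left$value, mean(y[X[, 1] <= oracle$threshold]))

  # randomized small datasets, both criteria
  set.seed(51)
  for (rep in 1:60) {
    n <- sample(4:12, 1); d <- sample(1:2, 1)
    X <- matrix(sample(1:6, n * d, replace = TRUE), n, d,
                dimnames = list(NULL, paste0("f", 1:d)))
    for (kind in c("regression", "classification")) {
      y <- if (kind == "regression") round(runif(n), 2)
           else rbinom(n, 1, 0.5)
      fit <- if (kind == "regression") {
        fit_regression_tree(X, y, max_depth = 1, min_leaf = 1)
      } else {
        if (length(unique(y)) < 2) next
        fit_classification_tree(X, y, max_depth = 1, min_leaf = 1)
      }
      oracle <- brute_best_split(X, y, min_leaf = 1, kind = kind)
      if (is.null(oracle) || oracle$gain <= 1e-7) {
        expect_true(fit$root$leaf)
      } else {
        expect_equal(fit$root$feature, oracle$feature)
        expect_equal(fit$root$threshold, oracle$threshold)
        expect_equal(fit$root$gain, oracle$gain, tolerance = 1e-9)
      }
    }
  }
})

test_that("Gini computation matches hand arithmetic on a four-point toy", {
  X <- cbind(a = c(1, 2, 3, 4))
  y <- c(0, 0, 1, 1)
  tr <- fit_classification_tree(X, y, max_depth = 1, min_leaf = 1)
  # split at 2.5: children pure, parent impurity n*2p(1-p) = 4*2*.25 = 2
  expect_equal(tr$root$threshold, 2.5)
  expect_equal(tr$root$gain, 2)
  # and a linearly separable 1-d problem is solved at depth 1
  expect_equal(predict(tr, X), y)
})

test_that("routing follows thresholds, with 0.5 cutoffs on binary columns", {
  set.seed(52)
  n <- 400
  X <- cbind(bin = rbinom(n, 1, 0.5), cont = runif(n))
  y <- 0.2 + 0.6 * X[, "bin"]
  tr <- fit_regression_tree(X, y, max_depth = 1, min_leaf = 10)
  expect_equal(tr$root$feature, 1)
  expect_identical(tr$root$threshold, 0.5)  # midpoint of {0, 1}, exactly

  # manual trace through a hand-built two-level tree
  hand <- structure(list(
    root = list(leaf = FALSE, feature = 1L, threshold = 2, gain = 1,
                value = 0.5, n = 10,
                left = list(leaf = FALSE, feature = 2L, threshold = 0.5,
                            gain = 1, value = 0.3, n = 6,
                            left = list(leaf = TRUE, value = 0.1, n = 3),
                            right = list(leaf = TRUE, value = 0.6, n = 3)),
                right = list(leaf = TRUE, value = 0.9, n = 4)),
    kind = "regression", feature_names = c("a", "b"),
    hyperparams = list(max_depth = 2L, min_leaf = 1L, min_gain = 0),
    routing = "feature <= threshold goes left"), class = "dstree")
  pts <- rbind(c(a = 1, b = 0), c(a = 1, b = 1), c(a = 5, b = 0))
  expect_equal(predict(hand, pts), c(0.1, 0.6, 0.9))
  sf <- split_features(hand)
  expect_setequal(sf$feature, c("a", "b"))
  expect_equal(sf$times_used[sf$feature == "a"], 1L)
})

test_that("training predictions conserve the target mass", {
  set.seed(53)
  X <- matrix(rnorm(600), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- runif(200)
  tr <- fit_regression_tree(X, y, max_depth = 4, min_leaf = 5)
  expect_equal(sum(predict(tr, X)), sum(y))
  # per-leaf: prediction equals the mean of that leaf's training targets
  pred <- predict(tr, X)
  for (v in unique(pred)) {
    expect_equal(mean(y[pred == v]), v)
  }
})

test_that("training MSE is monotone non-increasing in depth", {
  set.seed(54)
  X <- matrix(rnorm(900), 300, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- plogis(X[, 1] + 0.5 * X[, 2] * X[, 3] + rnorm(300, sd = 0.3))
  mse <- vapply(0:5, function(dep) {
    tr <- fit_regression_tree(X, y, max_depth = dep, min_leaf = 5)
    mean((predict(tr, X) - y)^2)
  }, 0)
  expect_true(all(diff(mse) <= 1e-12))
})

test_that("renders agree with the tree structure", {
  set.seed(55)
  X <- cbind(a = runif(200), b = runif(200))
  y <- as.numeric(X[, "a"] > 0.4)
  tr <- fit_regression_tree(X, y, max_depth = 2, min_leaf = 10)
  nodes <- extree:::collect_nodes(tr$root)

  txt <- render_tree(tr, "text")
  expect_equal(length(strsplit(txt, "\n")[[1]]), length(nodes))

  dot <- render_tree(tr, "dot")
  expect_match(dot, "^digraph")
  n_int <- sum(!vapply(nodes, `[[`, TRUE, "leaf"))
  # one label per node plus one per edge ("yes"/"no")
  expect_equal(length(gregexpr("label=", dot)[[1]]),
               length(nodes) + 2L * n_int)
  expect_equal(length(gregexpr("->", dot)[[1]]), 2 * n_int)

  leaf <- fit_regression_tree(X, rep(0.5, 200), min_leaf = 10)
  expect_equal(length(strsplit(render_tree(leaf, "text"), "\n")[[1]]), 1)
  expect_equal(nrow(split_features(leaf)), 0)
})

test_that("trees round-trip through JSON byte-for-byte", {
  set.seed(56)
  X <- cbind(a = runif(300), b = runif(300))
  y <- plogis(3 * X[, "a"] - 1)
  tr <- fit_regression_tree(X, y, max_depth = 3, min_leaf = 10)
  js <- tree_to_json(tr)
  back <- tree_from_json(js)
  expect_equal(predict(back, X), predict(tr, X))
  expect_identical(tree_to_json(back), js)
})

test_that("degenerate inputs error clearly", {
  X <- cbind(a = 1:10)
  expect_error(fit_regression_tree(X, numeric(0)), "empty")
  expect_error(fit_regression_tree(X, c(rep(1, 9), NA)), "non-finite")
  expect_error(fit_classification_tree(X, rep(0.5, 10)), "binary")
})
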