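# CART-style binary-split trees: regression (variance-reduction splits,
# mean leaves) and classification (Gini splits, positive-fraction leaves).
# Candidate thresholds are midpoints between consecutive distinct sorted
# values, which yields exactly 0.5 on 0/1 columns. Tie-breaks: lowest
# feature index, then smallest threshold. Routing: feature <= threshold
# goes left.

# Best split of one feature by cumulative sums over the sorted order.
# Returns list(gain, threshold) on the node-impurity scale, or NULL.
best_split_feature <- function(x, y, min_leaf, kind) {
  n <- length(y)
  o <- order(x)
  xs <- x[o]; ys <- y[o]
  cs <- cumsum(ys)
  i <- seq_len(n - 1L)
  ok <- (xs[i] < xs[i + 1L]) & (i >= min_leaf) & (n - i >= min_leaf)
  if (!any(ok)) return(NULL)
  nl <- i; nr <- n - i
  sl <- cs[i]; sr <- cs[n] - sl
  if (kind == "regression") {
    cq <- cumsum(ys^2)
    ql <- cq[i]; qr <- cq[n] - ql
    sse_l <- pmax(ql - sl^2 / nl, 0)
    sse_r <- pmax(qr - sr^2 / nr, 0)
    tot <- max(cq[n] - cs[n]^2 / n, 0)
    crit <- tot - (sse_l + sse_r)
  } else {
    pl <- sl / nl; pr <- sr / nr
    child <- nl * 2 * pl * (1 - pl) + nr * 2 * pr * (1 - pr)
    p <- cs[n] / n
    crit <- n * 2 * p * (1 - p) - child
  }
  crit[!ok] <- -Inf
  # ties (to within accumulated rounding) break to the smallest threshold
  best <- which(crit >= max(crit) - 1e-9)[1L]
  list(gain = crit[best], threshold = (xs[best] + xs[best + 1L]) / 2)
}

grow_node <- function(X, y, depth, hp, kind) {
  n <- length(y)
  node <- list(value = mean(y), n = n)
  impurity <- if (kind == "regression") {
    sum((y - node$value)^2)
  } else {
    n * 2 * node$value * (1 - node$value)
  }
  if (depth >= hp$max_depth || n < 2 * hp$min_leaf || impurity <= 0) {
    node$leaf <- TRUE
    return(node)
  }
  best <- NULL; best_j <- 0L
  for (j in seq_len(ncol(X))) {
    cand <- best_split_feature(X[, j], y, hp$min_leaf, kind)
    if (!is.null(cand) &&
        (is.null(best) || cand$gain > best$gain + 1e-9)) {
      best <- cand; best_j <- j
    }
  }
  if (is.null(best) || best$gain <= hp$min_gain) {
    node$leaf <- TRUE
    return(node)
  }
  left <- X[, best_j] <= best$threshold
  node$leaf <- FALSE
  node$feature <- best_j
  node$threshold <- best$threshold
  node$gain <- best$gain
  node$left <- grow_node(X[left, , drop = FALSE], y[left], depth + 1L,
                         hp, kind)
  node$right <- grow_node(X[!left, , drop = FALSE], y[!left], depth + 1L,
                          hp, kind)
  node
}

dstree_fit <- function(X, y, kind, max_depth, min_leaf, min_gain) {
  X <- as_feature_matrix(X)
  y <- as.numeric(y)
  if (!length(y)) stop("empty target vector")
  if (any(!is.finite(y))) stop("non-finite target values")
  if (length(y) != nrow(X)) stop("X and y lengths differ")
  if (kind == "classification") y <- check_binary(y)
  hp <- list(max_depth = as.integer(max_depth),
             min_leaf = as.integer(min_leaf), min_gain = min_gain)
  root <- grow_node(X, y, 0L, hp, kind)
  structure(list(root = root, kind = kind,
                 feature_names = colnames(X), hyperparams = hp,
                 routing = "feature <= threshold goes left"),
            class = "dstree")
}

#' Fit a regression tree
#'
#' Greedy CART induction on a continuous target in `[0, 1]` (typically
#' black-box risk scores): at each node, the split minimising the weighted
#' child sum of squared deviations is chosen over all features and midpoint
#' thresholds; leaves predict the mean of their training targets. Growth
#' stops at `max_depth`, when a child would fall below `min_leaf` rows, or
#' when the best gain is at most `min_gain`.
#'
#' @param X Numeric feature matrix.
#' @param y Numeric target vector.
#' @param max_depth Maximum number of internal nodes on any root-to-leaf
#'   path (default 4 — extracted trees are meant to be read by humans).
#' @param min_leaf Minimum rows per leaf.
#' @param min_gain Minimum impurity decrease to accept a split.
#' @return An object of class `"dstree"`.
#' @seealso [fit_classification_tree()], [predict.dstree()],
#'   [split_features()], [render_tree()]
#' @export
fit_regression_tree <- function(X, y, max_depth = 4, min_leaf = 50,
                                min_gain = 1e-7) {
  dstree_fit(X, y, "regression", max_depth, min_leaf, min_gain)
}

#' Fit a classification tree
#'
#' As [fit_regression_tree()] but for a binary target with Gini-impurity
#' splits. Leaves store the positive fraction, so predictions still score
#' in `[0, 1]`.
#'
#' @inheritParams fit_regression_tree
#' @param y Binary 0/1 target vector.
#' @return An object of class `"dstree"`.
#' @export
fit_classification_tree <- function(X, y, max_depth = 4, min_leaf = 50,
                                    min_gain = 1e-7) {
  dstree_fit(X, y, "classification", max_depth, min_leaf, min_gain)
}

#' Predict from a fitted tree
#'
#' Routes each row down the tree (`feature <= threshold` goes left) and
#' returns the leaf value: mean target for regression trees, positive
#' fraction for classification trees. On 0/1 columns the learned midpoint
#' threshold is exactly 0.5.
#'
#' @param object A `"dstree"`.
#' @param newdata Numeric matrix or data frame of features.
#' @param ... Unused.
#' @return Numeric vector of predictions in the target's range.
#' @export
predict.dstree <- function(object, newdata, ...) {
  X <- as_feature_matrix(newdata, object$feature_names)
  out <- numeric(nrow(X))
  route <- function(node, idx) {
    if (node$leaf) {
      out[idx] <<- node$value
      return(invisible())
    }
    go_left <- X[idx, node$feature] <= node$threshold
    if (any(go_left)) route(node$left, idx[go_left])
    if (any(!go_left)) route(node$right, idx[!go_left])
  }
  if (nrow(X)) route(object$root, seq_len(nrow(X)))
  out
}

collect_nodes <- function(node, depth = 0L) {
  if (node$leaf) {
    return(list(list(leaf = TRUE, value = node$value, n = node$n,
                     depth = depth)))
  }
  c(list(list(leaf = FALSE, feature = node$feature,
              threshold = node$threshold, gain = node$gain,
              value = node$value, n = node$n, depth = depth)),
    collect_nodes(node$left, depth + 1L),
    collect_nodes(node$right, depth + 1L))
}

#' Features used by a fitted tree
#'
#' Aggregates the internal nodes: how often each feature splits and its
#' total impurity gain, ordered by total gain (ties by first pre-order
#' appearance). A single-leaf tree yields a zero-row table.
#'
#' @param tree A `"dstree"` or `"extree"`.
#' @return Data frame with columns `feature`, `times_used`, `total_gain`.
#' @export
split_features <- function(tree) {
  if (inherits(tree, "extree")) tree <- tree$tree
  stopifnot(inherits(tree, "dstree"))
  nodes <- collect_nodes(tree$root)
  internal <- Filter(function(nd) !nd$leaf, nodes)
  if (!length(internal)) {
    return(data.frame(feature = character(0), times_used = integer(0),
                      total_gain = numeric(0), stringsAsFactors = FALSE))
  }
  feats <- vapply(internal, function(nd) tree$feature_names[nd$feature], "")
  gains <- vapply(internal, function(nd) nd$gain, 0)
  first_seen <- tapply(seq_along(feats), feats, min)
  agg <- data.frame(feature = names(first_seen),
                    times_used = as.integer(table(feats)[names(first_seen)]),
                    total_gain = as.numeric(
                      tapply(gains, feats, sum)[names(first_seen)]),
                    stringsAsFactors = FALSE)
  agg <- agg[order(-agg$total_gain, first_seen[agg$feature]), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Render a tree as indented text or Graphviz DOT
#'
#' The DOT rendering shades each node by its mean target (risk), so darker
#' nodes mark subpopulations the model scores as likelier to be readmitted.
#'
#' @param tree A `"dstree"` or `"extree"`.
#' @param format `"text"` or `"dot"`.
#' @return A single string.
#' @export
render_tree <- function(tree, format = c("text", "dot")) {
  format <- match.arg(format)
  if (inherits(tree, "extree")) tree <- tree$tree
  stopifnot(inherits(tree, "dstree"))
  fn <- tree$feature_names
  if (format == "text") {
    lines <- character(0)
    walk <- function(node, indent) {
      pad <- strrep("  ", indent)
      if (node$leaf) {
        lines <<- c(lines, sprintf("%sleaf: value=%.4f (n=%d)", pad,
                                   node$value, node$n))
      } else {
        lines <<- c(lines, sprintf("%s%s <= %.4g (n=%d)", pad,
                                   fn[node$feature], node$threshold,
                                   node$n))
        walk(node$left, indent + 1L)
        walk(node$right, indent + 1L)
      }
    }
    walk(tree$root, 0L)
    return(paste(lines, collapse = "\n"))
  }
  # DOT: fill intensity proportional to node mean target
  counter <- 0L
  lines <- c("digraph tree {",
             "  node [shape=box, style=filled, fontname=\"Helvetica\"];")
  walk <- function(node) {
    counter <<- counter + 1L
    id <- sprintf("n%d", counter)
    shade <- max(0, min(1, node$value))
    fill <- grDevices::rgb(1, 1 - 0.8 * shade, 1 - 0.8 * shade)
    lab <- if (node$leaf) {
      sprintf("value %.3f\\nn=%d", node$value, node$n)
    } else {
      sprintf("%s <= %.4g\\nmean %.3f, n=%d", fn[node$feature],
              node$threshold, node$value, node$n)
    }
    lines <<- c(lines, sprintf("  %s [label=\"%s\", fillcolor=\"%s\"];",
                               id, lab, fill))
    if (!node$leaf) {
      lid <- walk(node$left)
      rid <- walk(node$right)
      lines <<- c(lines,
                  sprintf("  %s -> %s [label=\"yes\"];", id, lid),
                  sprintf("  %s -> %s [label=\"no\"];", id, rid))
    }
    id
  }
  walk(tree$root)
  lines <- c(lines, "}")
  paste(lines, collapse = "\n")
}

#' @export
print.dstree <- function(x, ...) {
  nodes <- collect_nodes(x$root)
  n_int <- sum(!vapply(nodes, `[[`, TRUE, "leaf"))
  cat(sprintf("%s tree: %d internal nodes, %d leaves, depth <= %d\n",
              if (x$kind == "regression") "Regression" else "Classification",
              n_int, length(nodes) - n_int, x$hyperparams$max_depth))
  cat(render_tree(x, "text"), "\n")
  invisible(x)
}

#' @param x A `"dstree"`.
#' @param ... Unused.
#' @rdname render_tree
#' @export
plot.dstree <- function(x, ...) {
  nodes <- collect_nodes(x$root)
  depth_max <- max(vapply(nodes, `[[`, 0L, "depth"))
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, 1), ylim = c(-depth_max - 0.5, 0.5))
  fn <- x$feature_names
  draw <- function(node, x0, x1, depth) {
    xc <- (x0 + x1) / 2
    lab <- if (node$leaf) sprintf("%.3f", node$value)
           else sprintf("%s<=%.3g", fn[node$feature], node$threshold)
    graphics::text(xc, -depth, lab, cex = 0.8)
    if (!node$leaf) {
      xm <- (x0 + x1) / 2
      graphics::segments(xm, -depth - 0.12, (x0 + xm) / 2, -depth - 0.88)
      graphics::segments(xm, -depth - 0.12, (xm + x1) / 2, -depth - 0.88)
      draw(node$left, x0, xm, depth + 1)
      draw(node$right, xm, x1, depth + 1)
    }
  }
  draw(x$root, 0, 1, 0)
  invisible(x)
}

#' Serialize a tree to/from JSON
#'
#' The JSON carries the recursive node records plus a conventions block
#' (routing rule, kind, hyperparameters) so a rendered tree is unambiguous.
#'
#' @param tree A `"dstree"`.
#' @param path File path; `NULL` returns the JSON string.
#' @export
tree_to_json <- function(tree, path = NULL) {
  if (inherits(tree, "extree")) tree <- tree$tree
  stopifnot(inherits(tree, "dstree"))
  strip <- function(node) {
    if (node$leaf) {
      list(leaf = TRUE, value = node$value, n = node$n)
    } else {
      list(leaf = FALSE, feature = node$feature,
           name = tree$feature_names[node$feature],
           threshold = node$threshold, gain = node$gain,
           value = node$value, n = node$n,
           left = strip(node$left), right = strip(node$right))
    }
  }
  obj <- list(kind = tree$kind, routing = tree$routing,
              hyperparams = tree$hyperparams,
              feature_names = tree$feature_names,
              root = strip(tree$root))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' @rdname tree_to_json
#' @export
tree_from_json <- function(path) {
  txt <- if (file.exists(path)) paste(readLines(path), collapse = "") else path
  obj <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  rebuild <- function(nd) {
    if (isTRUE(nd$leaf)) {
      list(leaf = TRUE, value = nd$value, n = nd$n)
    } else {
      list(leaf = FALSE, feature = nd$feature, threshold = nd$threshold,
           gain = nd$gain, value = nd$value, n = nd$n,
           left = rebuild(nd$left), right = rebuild(nd$right))
    }
  }
  structure(list(root = rebuild(obj$root), kind = obj$kind,
                 feature_names = unlist(obj$feature_names),
                 hyperparams = obj$hyperparams, routing = obj$routing),
            class = "dstree")
}
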