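#' Extract an interpretable surrogate tree from a black-box scorer
#'
#' The two-step distillation: draw `m` synthetic feature vectors from the
#' mixture model fitted to the training features, label each with the
#' black-box scorer, and fit a shallow tree to the pairs. In
#' `mode = "regression"` (the proposed method) the tree is trained directly
#' on the scorer's continuous risk scores, retaining the full information
#' in the black box's output. In `mode = "binary"` (the comparison arm) the
#' scores are first binarized at `threshold` — a score exactly at the
#' threshold maps to 1 — and a classification tree is fitted, losing the
#' gradation between confident and marginal predictions.
#'
#' Samples from the mixture are passed to the scorer unclipped (the scorer
#' contract is defined on the reals); a `clip` range per feature can be
#' supplied for scorers that reject out-of-support values.
#'
#' @param scorer A [risk_scorer()]; must share `feature_names` with the
#'   mixture, in the same order.
#' @param gmm A [fit_gmm()] result describing the feature distribution.
#' @param m Number of synthetic training pairs; default ten times the
#'   mixture's training size, capped at 100,000.
#' @param mode `"regression"` or `"binary"`.
#' @param threshold Binarization cutoff for `mode = "binary"` (default 0.5).
#' @param max_depth,min_leaf,min_gain Tree hyperparameters; see
#'   [fit_regression_tree()].
#' @param m_eval Size of the fresh held-out synthetic batch for the
#'   fidelity report.
#' @param clip Optional named list of `c(lo, hi)` ranges applied to sampled
#'   features before scoring.
#' @param seed Integer seed; fixes the synthetic draws, hence the tree.
#' @return An object of class `"extree"`: the fitted `tree`, the
#'   `fidelity` report (see [fidelity_report()]), and the configuration.
#' @examples
#' X <- cbind(x1 = runif(500), x2 = runif(500))
#' sc <- risk_scorer(function(Z) as.numeric(Z[, "x1"] > 0.5),
#'                   feature_names = colnames(X), label = "step")
#' g <- fit_gmm(X, K = 1)
#' et <- extract_tree(sc, g, m = 2000, min_leaf = 20, seed = 1)
#' et$tree$root$threshold  # close to 0.5
#' @export
extract_tree <- function(scorer, gmm, m = NULL,
                         mode = c("regression", "binary"),
                         threshold = 0.5, max_depth = 4, min_leaf = 50,
                         min_gain = 1e-7, m_eval = 5000, clip = NULL,
                         seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(scorer, "risk_scorer"), inherits(gmm, "diag_gmm"))
  if (!identical(scorer$feature_names, gmm$feature_names)) {
    stop("scorer and gmm disagree on feature names/order")
  }
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  if (is.null(m)) m <- min(10 * gmm$n, 100000)
  m <- as.integer(m)
  if (m < 1) stop("m must be >= 1")

  Xs <- sample_gmm(gmm, m, seed = sub_seed(seed, 1L))
  if (!is.null(clip)) Xs <- clip_features(Xs, clip)
  scores <- predict(scorer, Xs)
  tree <- if (mode == "regression") {
    fit_regression_tree(Xs, scores, max_depth = max_depth,
                        min_leaf = min_leaf, min_gain = min_gain)
  } else {
    fit_classification_tree(Xs, as.numeric(scores >= threshold),
                            max_depth = max_depth, min_leaf = min_leaf,
                            min_gain = min_gain)
  }
  fid <- fidelity_report(tree, scorer, gmm, m_eval = m_eval,
                         threshold = threshold, clip = clip,
                         seed = sub_seed(seed, 2L))
  structure(list(tree = tree, mode = mode, fidelity = fid, m = m,
                 threshold = threshold, seed = seed,
                 scorer_label = scorer$label,
                 feature_names = gmm$feature_names),
            class = "extree")
}

#' @rdname extract_tree
#' @param ... Passed to [extract_tree()].
#' @export
extract_regression_tree <- function(scorer, gmm, ...) {
  extract_tree(scorer, gmm, mode = "regression", ...)
}

#' @rdname extract_tree
#' @export
extract_decision_tree <- function(scorer, gmm, ...) {
  extract_tree(scorer, gmm, mode = "binary", ...)
}

clip_features <- function(X, clip) {
  for (nm in names(clip)) {
    j <- match(nm, colnames(X))
    if (is.na(j)) stop("clip range for unknown feature '", nm, "'")
    X[, j] <- pmin(pmax(X[, j], clip[[nm]][1]), clip[[nm]][2])
  }
  X
}

#' How faithfully does a surrogate tree mimic its scorer?
#'
#' On a fresh synthetic batch from the mixture, reports the squared
#' correlation between tree and scorer predictions (`r_squared`; 1 with a
#' `zero_variance` flag when either side is constant), the AUC of the tree's
#' scores against the scorer's binarized labels (`auc_agreement`; `NA` when
#' the binarized labels are single-class), and quantiles of the absolute
#' prediction difference.
#'
#' @param tree A `"dstree"` or `"extree"`.
#' @param scorer The [risk_scorer()] the tree was extracted from.
#' @param gmm The feature distribution to sample the evaluation batch from.
#' @param m_eval Evaluation batch size (>= 2).
#' @param threshold Binarization cutoff for the AUC-agreement labels.
#' @param clip Optional per-feature clip ranges (see [extract_tree()]).
#' @param seed Integer seed.
#' @return List with `r_squared`, `zero_variance`, `auc_agreement`,
#'   `abs_diff_quantiles` and `m_eval`.
#' @export
fidelity_report <- function(tree, scorer, gmm, m_eval = 5000,
                            threshold = 0.5, clip = NULL, seed = 1L) {
  if (inherits(tree, "extree")) tree <- tree$tree
  stopifnot(inherits(tree, "dstree"), inherits(scorer, "risk_scorer"))
  if (m_eval < 2) stop("m_eval must be >= 2")
  Xe <- sample_gmm(gmm, m_eval, seed = seed)
  if (!is.null(clip)) Xe <- clip_features(Xe, clip)
  s <- predict(scorer, Xe)
  t <- predict(tree, Xe)
  zero_var <- stats::var(s) < 1e-20 || stats::var(t) < 1e-20
  r2 <- if (zero_var) 1 else stats::cor(s, t)^2
  lab <- as.numeric(s >= threshold)
  auc <- if (length(unique(lab)) < 2) NA_real_ else auc_roc(lab, t)
  list(r_squared = r2, zero_variance = zero_var, auc_agreement = auc,
       abs_diff_quantiles = stats::quantile(abs(t - s),
                                            c(0.5, 0.9, 0.99, 1)),
       m_eval = as.integer(m_eval))
}

#' @export
print.extree <- function(x, ...) {
  cat(sprintf("Extracted %s tree ('%s' scorer, m = %d synthetic pairs)\n",
              if (x$mode == "regression") "regression" else "decision",
              x$scorer_label, x$m))
  cat(sprintf("  held-out fidelity: R^2 = %.4f, AUC agreement = %s\n",
              x$fidelity$r_squared,
              ifelse(is.na(x$fidelity$auc_agreement), "NA",
                     sprintf("%.4f", x$fidelity$auc_agreement))))
  print(x$tree)
  invisible(x)
}

#' @export
summary.extree <- function(object, ...) {
  sf <- split_features(object$tree)
  cat(sprintf("Extracted %s tree from scorer '%s'\n", object$mode,
              object$scorer_label))
  cat(sprintf("  synthetic pairs: %d (seed %d)\n", object$m, object$seed))
  cat(sprintf("  fidelity R^2: %.4f  AUC agreement: %s\n",
              object$fidelity$r_squared,
              ifelse(is.na(object$fidelity$auc_agreement), "NA",
                     sprintf("%.4f", object$fidelity$auc_agreement))))
  cat("  features used:\n")
  print(sf)
  invisible(sf)
}

#' @export
predict.extree <- function(object, newdata, ...) {
  predict(object$tree, newdata, ...)
}

#' @export
plot.extree <- function(x, ...) plot(x$tree, ...)
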