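#' Construct a risk scorer
#'
#' A risk scorer is the package's black-box contract: any fitted model that
#' maps a feature matrix (columns in a fixed, named order) to probabilities
#' in `[0, 1]`. Surrogate-tree extraction ([extract_tree()]) works with any
#' object honouring this contract; the reference logistic and feed-forward
#' scorers below are conforming examples, not the method itself.
#'
#' @param score_fun Function taking a numeric matrix with columns
#'   `feature_names` and returning a probability per row.
#' @param feature_names Character vector fixing the column order.
#' @param label Short display label.
#' @param meta Optional list of fitting metadata.
#' @return An object of class `"risk_scorer"`.
#' @export
risk_scorer <- function(score_fun, feature_names, label = "scorer",
                        meta = list()) {
  stopifnot(is.function(score_fun), is.character(feature_names))
  structure(list(score_fun = score_fun,
                 feature_names = feature_names,
                 label = label, meta = meta),
            class = "risk_scorer")
}

#' @param object A `"risk_scorer"`.
#' @param newdata Numeric matrix or data frame of features.
#' @param ... Unused.
#' @rdname risk_scorer
#' @export
predict.risk_scorer <- function(object, newdata, ...) {
  X <- as_feature_matrix(newdata, object$feature_names)
  p <- as.numeric(object$score_fun(X))
  if (length(p) != nrow(X)) stop("scorer returned wrong number of scores")
  if (anyNA(p) || any(p < -1e-9) || any(p > 1 + 1e-9)) {
    stop("scorer '", object$label, "' returned scores outside [0,1]")
  }
  pmin(pmax(p, 0), 1)
}

#' @export
print.risk_scorer <- function(x, ...) {
  cat("Risk scorer '", x$label, "' on ", length(x$feature_names),
      " features\n", sep = "")
  invisible(x)
}

#' Reference logistic-regression scorer
#'
#' @param X Numeric feature matrix.
#' @param y Binary outcome vector.
#' @param label Display label.
#' @return A `"risk_scorer"`.
#' @export
fit_logistic_scorer <- function(X, y, label = "logistic") {
  X <- as_feature_matrix(X)
  y <- check_binary(y)
  fit <- suppressWarnings(
    stats::glm.fit(cbind(`(Intercept)` = 1, X), y,
                   family = stats::binomial()))
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  fn <- colnames(X)
  risk_scorer(function(Xn) {
    as.numeric(stats::plogis(cbind(1, Xn) %*% beta))
  }, feature_names = fn, label = label,
  meta = list(coefficients = beta))
}

# ---- small feed-forward network (no neural-net package in this stack) ----

mlp_unpack <- function(theta, d, h) {
  n1 <- d * h
  list(W1 = matrix(theta[seq_len(n1)], d, h),
       b1 = theta[n1 + seq_len(h)],
       w2 = theta[n1 + h + seq_len(h)],
       b2 = theta[n1 + 2 * h + 1])
}

mlp_forward <- function(par, X) {
  Z <- tanh(sweep(X %*% par$W1, 2, par$b1, "+"))
  list(Z = Z, p = stats::plogis(as.numeric(Z %*% par$w2 + par$b2)))
}

#' Reference feed-forward network scorer
#'
#' A single-hidden-layer network (tanh units, logistic output) fitted by
#' BFGS on the penalised cross-entropy with analytic gradients. Inputs are
#' standardised internally (centre/scale live inside the scorer, so the
#' contract stays feature vector in original units -> probability). This is
#' a conforming example black box; extraction accepts any scorer.
#'
#' @param X Numeric feature matrix.
#' @param y Binary outcome vector.
#' @param hidden Hidden-layer width.
#' @param decay L2 penalty on the weights.
#' @param maxit BFGS iteration cap.
#' @param seed Seed for the random weight initialisation.
#' @param label Display label.
#' @return A `"risk_scorer"`.
#' @export
fit_mlp_scorer <- function(X, y, hidden = 4, decay = 0.03, maxit = 300,
                           seed = 1L, label = "mlp") {
  X <- as_feature_matrix(X)
  y <- check_binary(y)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  d <- ncol(Xs); h <- as.integer(hidden); n <- nrow(Xs)
  npar <- d * h + 2 * h + 1

  obj <- function(theta) {
    par <- mlp_unpack(theta, d, h)
    p <- mlp_forward(par, Xs)$p
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -mean(y * log(p) + (1 - y) * log(1 - p)) +
      decay * (sum(par$W1^2) + sum(par$w2^2)) / 2
  }
  grad <- function(theta) {
    par <- mlp_unpack(theta, d, h)
    fw <- mlp_forward(par, Xs)
    dlogit <- (fw$p - y) / n
    g_w2 <- as.numeric(crossprod(fw$Z, dlogit)) + decay * par$w2
    g_b2 <- sum(dlogit)
    dZ <- (dlogit %*% t(par$w2)) * (1 - fw$Z^2)
    g_W1 <- crossprod(Xs, dZ) + decay * par$W1
    g_b1 <- colSums(dZ)
    c(as.numeric(g_W1), g_b1, g_w2, g_b2)
  }
  theta0 <- with_seed(seed,
                      stats::runif(npar, -0.5, 0.5) / sqrt(d))
  opt <- stats::optim(theta0, obj, grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-8))
  par <- mlp_unpack(opt$par, d, h)
  fn <- colnames(X)
  risk_scorer(function(Xn) {
    Xn <- sweep(sweep(Xn, 2, ctr), 2, scl, "/")
    mlp_forward(par, Xn)$p
  }, feature_names = fn, label = label,
  meta = list(hidden = h, decay = decay, value = opt$value,
              convergence = opt$convergence, seed = seed))
}

#' Rebalance a binary training set
#'
#' `"up"` resamples the minority class with replacement until the class
#' counts are equal; `"down"` subsamples the majority class without
#' replacement. An already balanced input is returned unchanged.
#'
#' @param X Feature matrix.
#' @param y Binary outcome vector.
#' @param mode `"up"` or `"down"`.
#' @param seed Integer seed.
#' @return List with rebalanced `X`, `y` and the selected row `idx`.
#' @export
rebalance <- function(X, y, mode = c("up", "down"), seed = 1L) {
  mode <- match.arg(mode)
  X <- as_feature_matrix(X)
  y <- check_binary(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("rebalance needs both classes present")
  if (n1 == n0) return(list(X = X, y = y, idx = seq_along(y)))
  minority <- if (n1 < n0) 1 else 0
  idx_min <- which(y == minority); idx_maj <- which(y != minority)
  idx <- with_seed(seed, {
    if (mode == "up") {
      extra <- sample(idx_min, abs(n1 - n0), replace = TRUE)
      c(seq_along(y), extra)
    } else {
      keep_maj <- sample(idx_maj, length(idx_min), replace = FALSE)
      sort(c(idx_min, keep_maj))
    }
  })
  list(X = X[idx, , drop = FALSE], y = y[idx], idx = idx)
}

# Stratified fold assignment: within each class, shuffle then deal
# round-robin, so per-fold class counts differ by at most one row.
make_stratified_folds <- function(y, k, seed = 1L) {
  y <- check_binary(y)
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in c(0, 1)) {
      ix <- sample(which(y == cls))
      fold[ix] <- rep_len(seq_len(k), length(ix))
    }
  })
  fold
}

#' Tune a scorer by stratified k-fold cross-validation with rebalancing
#'
#' Splits the data into `k` label-stratified folds; for every parameter
#' setting in the grid, trains on k-1 folds (rebalanced) and evaluates the
#' chosen metric on the untouched held-out fold. Rebalancing is applied to
#' training folds only. Ties are broken by the first-listed grid entry.
#'
#' @param X Feature matrix.
#' @param y Binary outcome vector.
#' @param scorer_factory Function `(params, X, y, seed)` returning a
#'   `"risk_scorer"`.
#' @param param_grid Non-empty list of parameter lists.
#' @param k Number of folds (>= 2).
#' @param metric Function `(y, scores)` to maximise; default [auc_roc()].
#' @param rebalance_mode `"up"`, `"down"` or `"none"`.
#' @param seed Integer seed for folds, rebalancing, and scorer fits.
#' @return List with `best_params`, `best_index`, `mean_scores` and the
#'   `k x length(grid)` matrix of `fold_scores`.
#' @export
stratified_kfold_tune <- function(X, y, scorer_factory, param_grid,
                                  k = 5, metric = auc_roc,
                                  rebalance_mode = c("up", "down", "none"),
                                  seed = 1L) {
  rebalance_mode <- match.arg(rebalance_mode)
  if (!length(param_grid)) stop("empty parameter grid")
  X <- as_feature_matrix(X)
  y <- check_binary(y)
  if (k < 2) stop("k must be >= 2")
  fold <- make_stratified_folds(y, k, seed = sub_seed(seed, 1L))
  for (f in seq_len(k)) {
    if (sum(y[fold == f] == 1) == 0 || sum(y[fold == f] == 0) == 0) {
      stop("fold ", f, " lacks one of the classes; reduce k")
    }
  }
  scores <- matrix(NA_real_, k, length(param_grid))
  for (g in seq_along(param_grid)) {
    for (f in seq_len(k)) {
      tr <- fold != f
      Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
      if (rebalance_mode != "none") {
        rb <- rebalance(Xtr, ytr, rebalance_mode,
                        seed = sub_seed(seed, 100L + f))
        Xtr <- rb$X; ytr <- rb$y
      }
      sc <- scorer_factory(param_grid[[g]], Xtr, ytr,
                           seed = sub_seed(seed, 200L + f))
      scores[f, g] <- metric(y[!tr], predict(sc, X[!tr, , drop = FALSE]))
    }
  }
  means <- colMeans(scores)
  best <- which.max(means)  # which.max keeps the first of tied entries
  list(best_params = param_grid[[best]], best_index = best,
       mean_scores = means, fold_scores = scores, folds = fold)
}
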