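#' Fit a diagonal-covariance Gaussian mixture by EM
#'
#' Estimates the joint feature distribution `P` used to draw synthetic
#' inputs for surrogate-tree extraction: a K-component Gaussian mixture
#' with diagonal covariances, `p(x) = sum_i phi_i N(x; mu_i, diag(s_i))`,
#' fitted by expectation-maximisation. One-hot and binary columns are
#' treated as continuous coordinates (sampled values are not rounded; the
#' surrogate tree splits them at 0.5 via the midpoint rule).
#'
#' The E-step computes responsibilities with log-sum-exp stabilisation; the
#' M-step updates weights, means and variances in closed form. Per-column
#' variance floors (`var_floor` times the column variance) prevent
#' degenerate spikes on near-constant coordinates. The per-iteration
#' log-likelihood trace is recorded and is non-decreasing.
#'
#' @param X Numeric feature matrix (n x d), n > K.
#' @param K Number of mixture components.
#' @param init `"kmeans"` (k-means seeding of the means) or `"random"`
#'   (K rows drawn at random).
#' @param tol Absolute log-likelihood gain below which EM stops.
#' @param max_iter Iteration cap.
#' @param var_floor Variance floor as a fraction of each column's variance.
#' @param seed Integer seed for the initialisation.
#' @return An object of class `"diag_gmm"`: `weights` (length K), `means`
#'   and `vars` (K x d), `feature_names`, `loglik` (final), `loglik_trace`,
#'   `iterations`, `converged`, `n`, `seed`.
#' @examples
#' X <- cbind(a = rnorm(300), b = rnorm(300))
#' g <- fit_gmm(X, K = 1)
#' all.equal(g$means[1, ], colMeans(X))
#' @export
fit_gmm <- function(X, K, init = c("kmeans", "random"), tol = 1e-6,
                    max_iter = 500, var_floor = 1e-6, seed = 1L) {
  init <- match.arg(init)
  X <- as_feature_matrix(X)
  if (any(!is.finite(X))) stop("non-finite values in X")
  n <- nrow(X); d <- ncol(X)
  K <- as.integer(K)
  if (K < 1) stop("K must be >= 1")
  if (K >= n) stop("K must be smaller than the number of rows")
  if (tol <= 0) stop("tol must be positive")

  col_var <- apply(X, 2, stats::var) * (n - 1) / n
  floor_j <- pmax(var_floor * pmax(col_var, .Machine$double.eps), 1e-12)

  means <- with_seed(seed, {
    if (K == 1L) {
      matrix(colMeans(X), 1, d)
    } else if (init == "kmeans") {
      km <- tryCatch(
        stats::kmeans(X, centers = K, nstart = 3, iter.max = 50),
        error = function(e) NULL)
      if (is.null(km)) X[sample.int(n, K), , drop = FALSE] else km$centers
    } else {
      X[sample.int(n, K), , drop = FALSE]
    }
  })
  vars <- matrix(pmax(col_var, floor_j), K, d, byrow = TRUE)
  weights <- rep(1 / K, K)
  dimnames(means) <- dimnames(vars) <- list(NULL, colnames(X))

  trace <- numeric(0)
  prev_ll <- -Inf
  converged <- FALSE
  it <- 0L
  resp <- NULL
  while (it < max_iter) {
    it <- it + 1L
    # E-step: log N(x; mu_i, diag) per component, stabilised
    logp <- matrix(0, n, K)
    for (i in seq_len(K)) {
      lv <- log(vars[i, ])
      dev <- sweep(X, 2, means[i, ])
      logp[, i] <- log(weights[i]) -
        0.5 * (d * log(2 * pi) + sum(lv) +
                 rowSums(sweep(dev^2, 2, vars[i, ], "/")))
    }
    mx <- apply(logp, 1, max)
    lse <- mx + log(rowSums(exp(logp - mx)))
    ll <- sum(lse)
    trace <- c(trace, ll)
    resp <- exp(logp - lse)
    if (is.finite(prev_ll) && ll - prev_ll < tol) {
      converged <- TRUE
      break
    }
    prev_ll <- ll
    # M-step
    Nk <- colSums(resp)
    weights <- Nk / n
    for (i in seq_len(K)) {
      mu <- colSums(resp[, i] * X) / Nk[i]
      dev <- sweep(X, 2, mu)
      v <- colSums(resp[, i] * dev^2) / Nk[i]
      means[i, ] <- mu
      vars[i, ] <- pmax(v, floor_j)
    }
  }
  structure(list(weights = weights, means = means, vars = vars,
                 feature_names = colnames(X),
                 loglik = trace[length(trace)], loglik_trace = trace,
                 iterations = it, converged = converged,
                 n = n, K = K, var_floor = floor_j, seed = seed),
            class = "diag_gmm")
}

#' @export
print.diag_gmm <- function(x, ...) {
  cat(sprintf("Diagonal GMM: K=%d components, d=%d features, n=%d\n",
              x$K, ncol(x$means), x$n))
  cat(sprintf("  logLik %.2f after %d EM iterations (%s)\n", x$loglik,
              x$iterations,
              if (x$converged) "converged" else "iteration cap"))
  cat("  weights:", paste(sprintf("%.3f", x$weights), collapse = " "), "\n")
  invisible(x)
}

#' @export
logLik.diag_gmm <- function(object, ...) {
  val <- object$loglik
  attr(val, "df") <- (object$K - 1) + 2 * object$K * ncol(object$means)
  attr(val, "nobs") <- object$n
  class(val) <- "logLik"
  val
}

#' Mixture log-density
#'
#' Evaluates `log sum_i phi_i N(x; mu_i, diag(s_i))` with log-sum-exp
#' stabilisation.
#'
#' @param gmm A `"diag_gmm"`.
#' @param x A numeric vector of length d or an n x d matrix.
#' @return Numeric vector of log-densities.
#' @export
gmm_log_density <- function(gmm, x) {
  stopifnot(inherits(gmm, "diag_gmm"))
  d <- ncol(gmm$means)
  if (is.null(dim(x))) {
    if (length(x) != d) stop("x has length ", length(x), "; expected ", d)
    x <- matrix(x, 1, d)
  }
  if (ncol(x) != d) stop("x has ", ncol(x), " columns; expected ", d)
  K <- gmm$K
  logp <- matrix(0, nrow(x), K)
  for (i in seq_len(K)) {
    dev <- sweep(x, 2, gmm$means[i, ])
    logp[, i] <- log(gmm$weights[i]) -
      0.5 * (d * log(2 * pi) + sum(log(gmm$vars[i, ])) +
               rowSums(sweep(dev^2, 2, gmm$vars[i, ], "/")))
  }
  mx <- apply(logp, 1, max)
  mx + log(rowSums(exp(logp - mx)))
}

#' Sample synthetic feature vectors from a fitted mixture
#'
#' Draws each row by choosing a component with probability `phi_i`, then
#' independent normals per coordinate.
#'
#' @param gmm A `"diag_gmm"`.
#' @param m Number of rows to draw (>= 0).
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @return An `m x d` matrix with the mixture's feature names as columns.
#' @export
sample_gmm <- function(gmm, m, seed = NULL) {
  stopifnot(inherits(gmm, "diag_gmm"))
  if (m < 0) stop("m must be non-negative")
  d <- ncol(gmm$means)
  out <- with_seed(seed, {
    if (m == 0) {
      matrix(numeric(0), 0, d)
    } else {
      comp <- sample.int(gmm$K, m, replace = TRUE, prob = gmm$weights)
      z <- matrix(stats::rnorm(m * d), m, d)
      gmm$means[comp, , drop = FALSE] +
        z * sqrt(gmm$vars[comp, , drop = FALSE])
    }
  })
  dimnames(out) <- list(NULL, gmm$feature_names)
  out
}

#' @param object A `"diag_gmm"`.
#' @param nsim Number of rows to draw.
#' @param seed Integer seed.
#' @param ... Unused.
#' @rdname sample_gmm
#' @export
simulate.diag_gmm <- function(object, nsim = 1, seed = NULL, ...) {
  sample_gmm(object, nsim, seed = seed)
}

#' Choose the number of mixture components by BIC
#'
#' Fits every K in the grid with [fit_gmm()] and returns the K minimising
#' `BIC = -2 logLik + params log n`, with `params = (K - 1) + 2 K d`
#' (weights, means, diagonal variances). Ties go to the smallest K.
#'
#' @param X Numeric feature matrix.
#' @param K_grid Candidate component counts (all < n).
#' @param criterion Only `"BIC"` is implemented.
#' @param seed Seed passed to each fit.
#' @param ... Further arguments to [fit_gmm()].
#' @return The selected K, with attributes `bic` (per-grid values) and
#'   `fits`.
#' @export
select_K <- function(X, K_grid = 1:10, criterion = "BIC", seed = 1L, ...) {
  if (!length(K_grid)) stop("empty K grid")
  if (!identical(criterion, "BIC")) stop("only BIC selection is implemented")
  X <- as_feature_matrix(X)
  n <- nrow(X); d <- ncol(X)
  fits <- vector("list", length(K_grid))
  bic <- rep(NA_real_, length(K_grid))
  status <- character(length(K_grid))
  for (j in seq_along(K_grid)) {
    K <- K_grid[j]
    fits[[j]] <- tryCatch(fit_gmm(X, K, seed = seed, ...),
                          error = function(e) e)
    if (inherits(fits[[j]], "error")) {
      status[j] <- conditionMessage(fits[[j]])
    } else {
      pars <- (K - 1) + 2 * K * d
      bic[j] <- -2 * fits[[j]]$loglik + pars * log(n)
      status[j] <- "ok"
    }
  }
  if (all(is.na(bic))) {
    stop("no GMM fit succeeded: ",
         paste(sprintf("K=%d: %s", K_grid, status), collapse = "; "))
  }
  best <- which(bic == min(bic, na.rm = TRUE))[1]  # ties -> smallest K
  structure(K_grid[best], bic = bic, fits = fits)
}

#' Serialize a diagonal GMM to/from JSON
#'
#' @param gmm A `"diag_gmm"`.
#' @param path File path.
#' @export
gmm_to_json <- function(gmm, path) {
  stopifnot(inherits(gmm, "diag_gmm"))
  obj <- list(K = gmm$K, weights = gmm$weights,
              means = apply(gmm$means, 1, identity, simplify = FALSE),
              vars = apply(gmm$vars, 1, identity, simplify = FALSE),
              feature_names = gmm$feature_names,
              loglik = gmm$loglik, iterations = gmm$iterations,
              converged = gmm$converged, n = gmm$n, seed = gmm$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname gmm_to_json
#' @export
gmm_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  to_mat <- function(z, K) {
    if (is.matrix(z)) z else matrix(unlist(z), nrow = K, byrow = TRUE)
  }
  means <- to_mat(obj$means, obj$K)
  vars <- to_mat(obj$vars, obj$K)
  g <- list(weights = obj$weights, means = means, vars = vars,
            feature_names = obj$feature_names, loglik = obj$loglik,
            loglik_trace = obj$loglik, iterations = obj$iterations,
            converged = obj$converged, n = obj$n, K = obj$K,
            seed = obj$seed)
  class(g) <- "diag_gmm"
  g
}
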