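# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. seed = NULL means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Counter-based sub-seed so stream i is stable no matter how many other
# streams are drawn (kept < 2^31 - 1; never 0).
sub_seed <- function(seed, i) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(i) * 7919
  as.integer(s %% 2147483646) + 1L
}

stopifnot_scalar <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", what), call. = FALSE)
  }
  invisible(x)
}

as_feature_matrix <- function(X, feature_names = NULL) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X)) {
    stop("features must be a numeric matrix or data frame", call. = FALSE)
  }
  if (!is.null(feature_names)) {
    if (is.null(colnames(X))) {
      if (ncol(X) != length(feature_names)) {
        stop("feature matrix has ", ncol(X), " columns; expected ",
             length(feature_names), call. = FALSE)
      }
      colnames(X) <- feature_names
    } else if (!identical(colnames(X), feature_names)) {
      if (!all(feature_names %in% colnames(X))) {
        missing <- setdiff(feature_names, colnames(X))
        stop("missing feature columns: ", paste(missing, collapse = ", "),
             call. = FALSE)
      }
      X <- X[, feature_names, drop = FALSE]
    }
  }
  X
}

check_binary <- function(y, what = "y") {
  y <- as.numeric(y)
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    stop(sprintf("'%s' must be binary 0/1 with no missing values", what),
         call. = FALSE)
  }
  y
}
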