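#' Replicated 70-30 evaluation with conservative standard errors
#'
#' The study-level evaluation protocol: `R` replications, each drawing a
#' fresh label-stratified train/test split (train fraction `split`),
#' rebalancing the training portion, building the model there, and scoring
#' the untouched test portion with the full metric set. The summary reports
#' each metric's mean over replications, sample SD (denominator R - 1), and
#' the conservative adjusted SE `sd_adjustment_factor(R, 0.05) * SD`.
#'
#' Stratification is a deliberate refinement of plain random splitting: it
#' guarantees every test set contains positives, so AUC and average
#' precision are always defined.
#'
#' @param X Feature matrix.
#' @param y Binary outcome vector.
#' @param model_builder Function `(X_train, y_train, seed)` returning a
#'   [risk_scorer()].
#' @param R Number of replications (>= 2; default 50).
#' @param split Training fraction (default 0.70).
#' @param rebalance_mode `"up"`, `"down"` or `"none"`.
#' @param base_seed Replication r uses seed `base_seed + r` for its split,
#'   rebalancing and model fit.
#' @param threshold Decision cutoff for thresholded metrics.
#' @param alpha Tail probability for the SD adjustment (default 0.05).
#' @return An object of class `"replication_summary"`: `summary` (matrix,
#'   metrics x mean/sd/adj_se), `metrics` (R x 7 matrix of raw scores),
#'   `R`, `n_completed`, `split`, `adjustment_factor`, `seeds`.
#' @export
replicate_eval <- function(X, y, model_builder, R = 50, split = 0.70,
                           rebalance_mode = c("up", "down", "none"),
                           base_seed = 1L, threshold = 0.5, alpha = 0.05) {
  rebalance_mode <- match.arg(rebalance_mode)
  X <- as_feature_matrix(X)
  y <- check_binary(y)
  if (R < 2) stop("R must be >= 2")
  if (sum(y == 1) == 0 || sum(y == 0) == 0) stop("need both classes in y")
  metric_names <- c("acc", "auc", "auprc", "precision", "recall",
                    "f_value", "mcc")
  out <- matrix(NA_real_, R, length(metric_names),
                dimnames = list(NULL, metric_names))
  seeds <- base_seed + seq_len(R)
  failed <- 0L
  for (r in seq_len(R)) {
    res <- tryCatch({
      tr <- stratified_split(y, split, seed = seeds[r])
      Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
      if (rebalance_mode != "none") {
        rb <- rebalance(Xtr, ytr, rebalance_mode,
                        seed = sub_seed(seeds[r], 1L))
        Xtr <- rb$X; ytr <- rb$y
      }
      model <- model_builder(Xtr, ytr, seed = sub_seed(seeds[r], 2L))
      ms <- metric_set(y[!tr], predict(model, X[!tr, , drop = FALSE]),
                       threshold)
      unlist(ms[metric_names])
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- failed + 1L
      warning("replication ", r, " failed: ", conditionMessage(res))
    } else {
      out[r, ] <- res
    }
  }
  done <- stats::complete.cases(out)
  if (sum(done) < 2) stop("fewer than two replications completed")
  if (failed) {
    warning("summary computed over ", sum(done), " of ", R,
            " replications")
  }
  fac <- sd_adjustment_factor(R, alpha)
  mm <- out[done, , drop = FALSE]
  summ <- cbind(mean = colMeans(mm),
                sd = apply(mm, 2, stats::sd),
                adj_se = fac * apply(mm, 2, stats::sd))
  structure(list(summary = summ, metrics = out, R = R,
                 n_completed = sum(done), split = split,
                 adjustment_factor = fac, seeds = seeds,
                 rebalance_mode = rebalance_mode, alpha = alpha),
            class = "replication_summary")
}

# Label-stratified train/test split; test size = round((1 - split) n) with
# per-class proportions within one row of the full data's.
stratified_split <- function(y, split, seed) {
  n <- length(y)
  n_test <- round((1 - split) * n)
  with_seed(seed, {
    test <- logical(n)
    ix1 <- which(y == 1); ix0 <- which(y == 0)
    n_test1 <- round(n_test * length(ix1) / n)
    test[sample(ix1, n_test1)] <- TRUE
    test[sample(ix0, n_test - n_test1)] <- TRUE
    !test
  })
}

#' @export
print.replication_summary <- function(x, ...) {
  cat(sprintf("Replicated evaluation: %d/%d replications, %.0f-%.0f split, %s-sampling\n",
              x$n_completed, x$R, 100 * x$split, 100 * (1 - x$split),
              x$rebalance_mode))
  cat(sprintf("  SD adjustment factor (alpha=%.2f): %.4f\n", x$alpha,
              x$adjustment_factor))
  print(round(x$summary, 4))
  invisible(x)
}

#' Significance flags against a baseline model
#'
#' One-sided comparison per metric, following the convention that a
#' candidate "beats" the baseline when its mean exceeds the baseline mean
#' by more than twice (95% confidence, `"*"`) or three times (99%
#' confidence, `"**"`) the baseline's conservative adjusted SE. The
#' inequality is strict; candidates at or below the threshold, or below the
#' baseline, are `"ns"`.
#'
#' @param candidate,baseline `"replication_summary"` objects with equal `R`.
#' @return Named character vector of flags in `{"ns", "*", "**"}`.
#' @export
significance_flags <- function(candidate, baseline) {
  stopifnot(inherits(candidate, "replication_summary"),
            inherits(baseline, "replication_summary"))
  if (candidate$R != baseline$R) stop("candidate and baseline R differ")
  metrics <- rownames(baseline$summary)
  diff <- candidate$summary[metrics, "mean"] -
    baseline$summary[metrics, "mean"]
  se <- baseline$summary[metrics, "adj_se"]
  flags <- ifelse(diff > 3 * se, "**", ifelse(diff > 2 * se, "*", "ns"))
  stats::setNames(flags, metrics)
}
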