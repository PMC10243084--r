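# Model builders with the (X, y, seed) -> risk_scorer signature expected
# by replicate_eval(); these wire the full two-step pipeline into the
# replication harness (GMM refitted per replication on the training split
# only, so no test information leaks into extraction).

#' Ready-made model builders for the replication harness
#'
#' Each returns a function `(X_train, y_train, seed)` producing a
#' [risk_scorer()], the contract [replicate_eval()] expects.
#' `logistic_builder()` and `mlp_builder()` wrap the reference scorers;
#' `surrogate_builder()` runs the whole two-step extraction inside each
#' replication — train the black box, fit the mixture to the training
#' features, extract the tree — and returns the tree as the scorer under
#' evaluation.
#'
#' @param hidden,decay,maxit MLP settings (see [fit_mlp_scorer()]).
#' @param scorer_builder Builder for the black box being distilled.
#' @param mode `"regression"` or `"binary"` surrogate.
#' @param K Mixture components for the per-replication GMM fit.
#' @param m Synthetic pairs per extraction (`NULL` = default rule).
#' @param ... Tree hyperparameters passed to [extract_tree()].
#' @return A builder function.
#' @export
logistic_builder <- function() {
  function(X, y, seed) fit_logistic_scorer(X, y)
}

#' @rdname logistic_builder
#' @export
mlp_builder <- function(hidden = 4, decay = 0.03, maxit = 300) {
  function(X, y, seed) {
    fit_mlp_scorer(X, y, hidden = hidden, decay = decay, maxit = maxit,
                   seed = seed)
  }
}

#' @rdname logistic_builder
#' @export
surrogate_builder <- function(scorer_builder = mlp_builder(),
                              mode = c("regression", "binary"),
                              K = 3, m = NULL, ...) {
  mode <- match.arg(mode)
  dots <- list(...)
  function(X, y, seed) {
    blackbox <- scorer_builder(X, y, seed = sub_seed(seed, 1L))
    gmm <- fit_gmm(X, K = K, seed = sub_seed(seed, 2L))
    et <- do.call(extract_tree,
                  c(list(scorer = blackbox, gmm = gmm, m = m, mode = mode,
                         seed = sub_seed(seed, 3L)), dots))
    fn <- gmm$feature_names
    risk_scorer(function(Z) predict(et, Z), feature_names = fn,
                label = paste0("extracted-",
                               if (mode == "regression") "rt" else "dt"),
                meta = list(extree = et))
  }
}
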