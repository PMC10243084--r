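# Metrics, replication machinery, conservative SEs, significance flags.

test_that("confusion counts match hand tallies", {
  cm <- confusion(c(1, 0, 1, 0), c(0.9, 0.6, 0.4, 0.1))
  expect_equal(unclass(cm)[c("TP", "FP", "FN", "TN")],
               list(TP = 1L, FP = 1L, FN = 1L, TN = 1L),
               ignore_attr = TRUE)
  perfect <- confusion(c(1, 0), c(0.9, 0.1))
  expect_equal(perfect$FP + perfect$FN, 0)
  none <- confusion(c(1, 0), c(0, 0))
  expect_equal(none$TP + none$FP, 0)
  # scores exactly at the threshold predict positive
  at <- confusion(c(1, 0), c(0.5, 0.5))
  expect_equal(at$TP, 1L)
  expect_equal(at$FP, 1L)
  expect_error(confusion(c(1, 0), 0.5), "lengths")
})

test_that("AUC matches printed examples and handles ties", {
  expect_equal(auc_roc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(auc_roc(c(0, 1, 0, 1), rep(0.4, 4)), 0.5)
  expect_equal(auc_roc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8)), 0.75)
  expect_error(auc_roc(c(1, 1), c(0.1, 0.2)), "one class")
})

test_that("AUC and AUPRC equal brute-force constructions exhaustively", {
  # all labelings with both classes for n = 3..8, scores drawn from a
  # coarse grid so ties occur constantly
  set.seed(70)
  for (n in 3:8) {
    for (bits in 1:(2^n - 2)) {
      y <- as.integer(intToBits(bits)[1:n])
      s <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)
      expect_equal(auc_roc(y, s), brute_auc(y, s))
      if (sum(y) > 0) expect_equal(auprc(y, s), brute_auprc(y, s))
    }
  }
})

test_that("AUPRC matches step-curve hand examples", {
  expect_equal(auprc(c(1, 1, 0), c(0.9, 0.8, 0.1)), 1)
  expect_equal(auprc(c(1, 0, 1), c(0.9, 0.8, 0.7)), (1 + 2 / 3) / 2)
  # tied block: both rows enter together, precision at the block end
  expect_equal(auprc(c(1, 0), c(0.5, 0.5)), 0.5)
  expect_error(auprc(c(0, 0), c(0.1, 0.2)), "no positives")
})

test_that("random scorers approach the prevalence baseline AUPRC", {
  set.seed(71)
  n <- 5000
  y <- as.integer(runif(n) < 0.143)
  ap <- replicate(40, auprc(y, runif(n)))
  expect_lt(abs(mean(ap) - mean(y)), 0.01)
})

test_that("MCC matches hand arithmetic and zero conventions", {
  expect_equal(mcc(confusion(c(1, 0), c(1, 0))), 1)
  expect_equal(mcc(confusion(c(1, 0), c(1, 1))), 0)  # all predicted positive
  expect_equal(mcc(TP = 6, FP = 1, FN = 2, TN = 3), 16 / sqrt(1120))
})

test_that("metric_set is internally consistent", {
  set.seed(72)
  y <- rbinom(60, 1, 0.4)
  s <- runif(60)
  ms <- metric_set(y, s)
  expect_equal(ms$f_value,
               2 * ms$precision * ms$recall / (ms$precision + ms$recall))
  cm <- ms$confusion
  expect_equal(ms$acc, (cm$TP + cm$TN) / 60)
  expect_equal(cm$TP + cm$FP + cm$FN + cm$TN, 60)
  # all-negative predictions trigger the zero conventions
  ms0 <- metric_set(y, rep(0, 60))
  expect_equal(ms0$precision, 0)
  expect_equal(ms0$f_value, 0)
  expect_equal(ms0$mcc, 0)
})

test_that("chi-square SD adjustment gives the conservative multipliers", {
  expect_equal(round(sd_adjustment_factor(50, 0.05), 4), 1.2017)
  expect_equal(sd_adjustment_factor(10, 0.05),
               sqrt(9 / qchisq(0.05, 9)))
  expect_lt(sd_adjustment_factor(5000, 0.05), 1.02)
  # strictly decreasing in R
  f <- vapply(c(5, 10, 25, 50, 100, 500), sd_adjustment_factor, 0)
  expect_true(all(diff(f) < 0))
  expect_gt(sd_adjustment_factor(50, 0.05), 1)
  expect_error(sd_adjustment_factor(1), "R must")
  expect_error(sd_adjustment_factor(50, 1.2), "alpha")
})

test_that("replicated evaluation splits, rebalances and summarises", {
  set.seed(73)
  n <- 400
  X <- cbind(a = rnorm(n), b = rnorm(n))
  y <- rbinom(n, 1, plogis(-1.2 + 1.5 * X[, "a"]))
  if (sum(y) < 40) y[seq_len(40)] <- 1

  rs <- replicate_eval(X, y, logistic_builder(), R = 50, base_seed = 9)
  expect_equal(rs$n_completed, 50)
  # conservative SE is exactly the 1.2017 multiple of the sample SD
  expect_equal(rs$summary[, "adj_se"],
               sd_adjustment_factor(50, 0.05) * rs$summary[, "sd"])
  expect_equal(round(rs$adjustment_factor, 4), 1.2017)

  # determinism in the base seed
  rs2 <- replicate_eval(X, y, logistic_builder(), R = 50, base_seed = 9)
  expect_identical(rs$summary, rs2$summary)

  # stratified split arithmetic: test sizes and class balance
  tr <- extree:::stratified_split(y, 0.7, seed = 4)
  expect_equal(sum(!tr), round(0.3 * n))
  expect_lt(abs(sum(y[!tr] == 1) - 0.3 * sum(y == 1)), 1 + 1e-9)
})

test_that("failed replications are reported, not fatal", {
  set.seed(74)
  X <- cbind(a = rnorm(100), b = rnorm(100))
  y <- rbinom(100, 1, 0.3)
  flaky <- local({
    calls <- 0
    function(X, y, seed) {
      calls <<- calls + 1
      if (calls == 2) stop("synthetic failure")
      fit_logistic_scorer(X, y)
    }
  })
  ws <- testthat::capture_warnings(
    rs <- replicate_eval(X, y, flaky, R = 4, base_seed = 1))
  expect_match(ws, "failed", all = FALSE)
  expect_match(ws, "3 of 4", all = FALSE)
  expect_equal(rs$n_completed, 3)
})

test_that("significance flags follow the strict 2x / 3x rule", {
  mk <- function(auc_mean, auc_sd, R = 50) {
    fac <- sd_adjustment_factor(R, 0.05)
    summ <- matrix(c(auc_mean, auc_sd, fac * auc_sd), 1, 3,
                   dimnames = list("auc", c("mean", "sd", "adj_se")))
    structure(list(summary = summ, R = R), class = "replication_summary")
  }
  # base mean 0 keeps the boundary difference exactly representable
  base <- mk(0, 0.0088)
  thr <- 2 * base$summary["auc", "adj_se"]  # 0.0212 after rounding

  expect_equal(unname(significance_flags(mk(thr, 1e-4), base)),
               "ns")  # boundary is strict
  expect_equal(unname(significance_flags(mk(thr + 1e-6, 1e-4), base)),
               "*")
  expect_equal(unname(significance_flags(mk(1.5 * thr + 1e-6, 1e-4),
                                         base)), "**")
  expect_equal(unname(significance_flags(mk(-0.1, 1e-4), base)), "ns")
  expect_error(significance_flags(mk(0.7, 0.01, R = 20), base), "differ")

  # the printed AUC threshold: 2 x 1.2017 x 0.0088 rounds to 0.0212
  expect_equal(round(thr, 4), 0.0212)
})

test_that("report tables star models against the baseline", {
  mk <- function(auc_mean, auc_sd = 0.0088) {
    fac <- sd_adjustment_factor(50, 0.05)
    metrics <- c("acc", "auc", "auprc")
    summ <- matrix(rep(c(auc_mean, auc_sd, fac * auc_sd), each = 3), 3, 3,
                   dimnames = list(metrics, c("mean", "sd", "adj_se")))
    summ[, "mean"] <- auc_mean
    structure(list(summary = summ, R = 50),
              class = "replication_summary")
  }
  tab <- report_table(list(LR = mk(0.660), NN = mk(0.711)),
                      baseline = "LR")
  expect_equal(tab$model, c("LR", "NN"))
  expect_match(tab$auc[2], "\\*\\*$")  # 0.051 above, far beyond 3x
  expect_false(grepl("\\*", tab$auc[1]))
})
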