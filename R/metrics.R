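#' Confusion matrix at a score threshold
#'
#' A row is predicted positive when its score is at least `threshold`
#' (scores exactly at the cutoff count as positive).
#'
#' @param y Binary outcome vector.
#' @param scores Numeric scores in `[0, 1]`.
#' @param threshold Decision cutoff (default 0.5).
#' @return An object of class `"confusion_matrix"` with fields `TP`, `FP`,
#'   `FN`, `TN`.
#' @export
confusion <- function(y, scores, threshold = 0.5) {
  y <- check_binary(y)
  if (length(y) != length(scores)) stop("y and scores lengths differ")
  pred <- as.numeric(scores >= threshold)
  structure(list(TP = sum(pred == 1 & y == 1),
                 FP = sum(pred == 1 & y == 0),
                 FN = sum(pred == 0 & y == 1),
                 TN = sum(pred == 0 & y == 0)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2, 2,
              dimnames = list(c("pred+", "pred-"), c("obs+", "obs-")))
  print(m)
  invisible(x)
}

#' Area under the ROC curve (midrank estimator)
#'
#' Mann-Whitney form: `(sum of positive ranks - n1 (n1 + 1) / 2) / (n1 n0)`
#' with average ranks for ties, i.e. the probability that a random positive
#' outscores a random negative, counting ties as one half. Equals 0.5 for a
#' scorer guessing at random and 1 for perfect separation.
#'
#' @param y Binary outcome vector with both classes present.
#' @param scores Numeric scores.
#' @return AUC in `[0, 1]`.
#' @export
auc_roc <- function(y, scores) {
  y <- check_binary(y)
  if (length(y) != length(scores)) stop("y and scores lengths differ")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: only one class present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision: positives are visited in descending score
#' order and the precision at each positive's cut is averaged over all
#' positives; tied scores are processed as one block using the precision at
#' the block's end. For a no-skill scorer this converges to the positive
#' prevalence, the natural baseline on imbalanced outcomes.
#'
#' @param y Binary outcome vector with at least one positive.
#' @param scores Numeric scores.
#' @return Average precision in `[0, 1]`.
#' @export
auprc <- function(y, scores) {
  y <- check_binary(y)
  if (length(y) != length(scores)) stop("y and scores lengths differ")
  n1 <- sum(y == 1)
  if (n1 == 0) stop("AUPRC undefined: no positives")
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]; ss <- scores[o]
  # block ends: last index of each run of tied scores
  ends <- which(c(ss[-1] != ss[-length(ss)], TRUE))
  tp <- cumsum(ys)[ends]
  prec <- tp / ends
  pos_in_block <- diff(c(0, tp))
  sum(pos_in_block * prec) / n1
}

#' Matthews correlation coefficient
#'
#' `(TP TN - FP FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; returns 0 when
#' any denominator factor is zero (e.g. all-one-class predictions).
#'
#' @param cm A `"confusion_matrix"` from [confusion()]; alternatively give
#'   the four counts directly.
#' @param TP,FP,FN,TN Counts when `cm` is not supplied.
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(cm = NULL, TP = NULL, FP = NULL, FN = NULL, TN = NULL) {
  if (inherits(cm, "confusion_matrix")) {
    TP <- cm$TP; FP <- cm$FP; FN <- cm$FN; TN <- cm$TN
  } else if (is.null(TP)) {
    TP <- cm
  }
  denom <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  if (denom == 0) return(0)
  (TP * TN - FP * FN) / sqrt(denom)
}

#' Full metric set for a scored test set
#'
#' Accuracy, AUC, average precision, precision, recall, F-value (F1) and
#' MCC at the given threshold, with the zero conventions: precision is 0
#' when nothing is predicted positive, and F is 0 when precision + recall
#' is 0.
#'
#' @inheritParams confusion
#' @return Named list of class `"metric_set"`.
#' @export
metric_set <- function(y, scores, threshold = 0.5) {
  cm <- confusion(y, scores, threshold)
  n <- cm$TP + cm$FP + cm$FN + cm$TN
  precision <- if (cm$TP + cm$FP == 0) 0 else cm$TP / (cm$TP + cm$FP)
  recall <- if (cm$TP + cm$FN == 0) 0 else cm$TP / (cm$TP + cm$FN)
  f_value <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  structure(list(acc = (cm$TP + cm$TN) / n,
                 auc = auc_roc(y, scores),
                 auprc = auprc(y, scores),
                 precision = precision, recall = recall,
                 f_value = f_value, mcc = mcc(cm),
                 confusion = cm),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  v <- unlist(x[c("acc", "auc", "auprc", "precision", "recall",
                  "f_value", "mcc")])
  print(round(v, 4))
  invisible(x)
}

#' Conservative SD multiplier from the chi-square distribution
#'
#' The one-sided upper `1 - alpha` confidence limit on a normal population
#' standard deviation estimated from `R` replications is
#' `sqrt((R - 1) / chisq_quantile(alpha, R - 1))` times the sample SD. For
#' 50 replications at the 95% level the multiplier is 1.2017, which is the
#' factor applied to replication SDs to obtain deliberately conservative
#' standard errors.
#'
#' @param R Number of replications (>= 2).
#' @param alpha Lower-tail probability (default 0.05).
#' @return The multiplier (> 1, decreasing towards 1 as R grows).
#' @examples
#' round(sd_adjustment_factor(50), 4)  # 1.2017
#' @export
sd_adjustment_factor <- function(R, alpha = 0.05) {
  if (R < 2) stop("R must be >= 2")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  sqrt((R - 1) / stats::qchisq(alpha, df = R - 1))
}
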