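# Independent brute-force oracles used to pin expected values. These stay
# deliberately naive (double loops, exhaustive enumeration) and share no
# code with the implementation they check.

# AUC as the fraction of positive-negative pairs won, ties counting half.
brute_auc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Average precision from the precision-recall step curve, walking unique
# thresholds in descending order (tied scores enter together).
brute_auprc <- function(y, s) {
  th <- sort(unique(s), decreasing = TRUE)
  n1 <- sum(y == 1)
  ap <- 0; prev_rec <- 0
  for (t in th) {
    pred <- s >= t
    tp <- sum(pred & y == 1)
    prec <- tp / sum(pred)
    rec <- tp / n1
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

# Prior-visit count by double loop over all visit pairs.
brute_prior_visits <- function(admit, discharge, window = 180) {
  n <- length(admit)
  out <- integer(n)
  for (k in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j < k && admit[k] - discharge[j] >= 0 &&
          admit[k] - discharge[j] <= window) {
        out[k] <- out[k] + 1L
      }
    }
  }
  out
}

brute_labels <- function(admit, discharge, window) {
  n <- length(admit)
  out <- integer(n)
  for (k in seq_len(n)) {
    if (k < n && admit[k + 1] - discharge[k] <= window) out[k] <- 1L
  }
  out
}

# Exhaustive best depth-1 split: every feature, every midpoint threshold,
# impurity computed directly; ties resolved lowest feature index then
# smallest threshold (the package's stated convention).
brute_best_split <- function(X, y, min_leaf = 1, kind = "regression") {
  imp <- function(v) {
    if (!length(v)) return(0)
    if (kind == "regression") sum((v - mean(v))^2)
    else length(v) * 2 * mean(v) * (1 - mean(v))
  }
  best <- NULL
  for (j in seq_len(ncol(X))) {
    vals <- sort(unique(X[, j]))
    if (length(vals) < 2) next
    for (i in seq_len(length(vals) - 1)) {
      thr <- (vals[i] + vals[i + 1]) / 2
      left <- X[, j] <= thr
      if (sum(left) < min_leaf || sum(!left) < min_leaf) next
      gain <- imp(y) - imp(y[left]) - imp(y[!left])
      if (is.null(best) || gain > best$gain + 1e-9) {
        best <- list(feature = j, threshold = thr, gain = gain)
      }
    }
  }
  best
}

# Random visit history for one patient: sorted admits, short stays.
random_history <- function(n_visits, span = 700) {
  admit <- sort(sample.int(span, n_visits))
  los <- sample(0:10, n_visits, replace = TRUE)
  discharge <- admit + los
  # enforce non-overlap: next admit strictly after previous discharge
  for (k in seq_len(n_visits)[-1]) {
    if (admit[k] <= discharge[k - 1]) {
      admit[k] <- discharge[k - 1] + sample.int(40, 1)
      discharge[k] <- admit[k] + los[k]
    }
  }
  list(admit = admit, discharge = discharge)
}

# Comparable-scale mechanism for feature-recovery experiments: three true
# risk features (standard-normal marginals, coefficients 0.9/0.8/0.7)
# against five weak noise features, plus a length-of-stay column to drive
# the visit machinery. On this scale, coefficient magnitude is influence.
recovery_mechanism <- function() {
  specs <- replicate(8, list(type = "continuous", dist = "normal",
                             mean = 0, sd = 1), simplify = FALSE)
  names(specs) <- c(paste0("risk", 1:3), paste0("noise", 1:5))
  specs$los <- list(type = "continuous", dist = "lognormal",
                    meanlog = 1.2, sdlog = 0.8, round = TRUE)
  risk_mechanism(NA_real_,
                 c(risk1 = 0.9, risk2 = 0.8, risk3 = 0.7,
                   noise1 = 0.05, noise2 = 0.05, noise3 = 0.05,
                   noise4 = 0.05, noise5 = 0.05),
                 specs)
}

# Tiny admission table straight from vectors (one or more patients).
make_admissions <- function(patient_id, admit, discharge,
                            specialty = "medicine") {
  data.frame(patient_id = patient_id,
             visit_id = paste0(patient_id, "-", seq_along(admit)),
             admit_date = as.Date("2010-01-01") + admit,
             discharge_date = as.Date("2010-01-01") + discharge,
             specialty = specialty,
             stringsAsFactors = FALSE)
}
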