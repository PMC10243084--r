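#' Count prior visits within a look-back window
#'
#' For each visit of one patient, counts earlier visits whose discharge date
#' falls within `window_days` of the current admission date: visit `j` is
#' counted for visit `k` when `0 <= admit[k] - discharge[j] <= window_days`.
#' The 180-day boundary is inclusive. The count deliberately excludes the
#' current visit itself; `include_self = TRUE` restores the literal
#' self-counting sum (which always contributes 1) for comparability.
#'
#' @param admit,discharge Parallel `Date` (or numeric day) vectors for one
#'   patient, sorted ascending by admission date.
#' @param window_days Look-back window in days (default 180, i.e. six
#'   months).
#' @param include_self Count the index visit itself (adds 1 everywhere).
#' @return Integer vector of prior-visit counts, one per visit.
#' @examples
#' count_prior_visits(c(0, 100, 400), c(5, 103, 402))  # 0, 1, 0
#' @export
count_prior_visits <- function(admit, discharge, window_days = 180,
                               include_self = FALSE) {
  if (length(admit) != length(discharge)) {
    stop("'admit' and 'discharge' must have equal length")
  }
  a <- as.numeric(admit); d <- as.numeric(discharge)
  if (is.unsorted(a)) stop("visits must be sorted ascending by admit date")
  if (any(d < a)) stop("discharge before admission")
  n <- length(a)
  out <- integer(n)
  for (k in seq_len(n)) {
    if (k > 1L) {
      gaps <- a[k] - d[seq_len(k - 1L)]
      out[k] <- sum(gaps >= 0 & gaps <= window_days)
    }
  }
  if (include_self) out <- out + 1L
  out
}

#' Build readmission outcome labels for one patient
#'
#' Visit `k` is labelled 1 when a visit `k+1` exists and the gap from
#' discharge `k` to admission `k+1` is at most `window_days` (inclusive);
#' the final visit is always 0.
#'
#' @inheritParams count_prior_visits
#' @param window_days Outcome window in days, typically 30 or 90.
#' @return Binary integer vector, one entry per visit.
#' @export
build_labels <- function(admit, discharge, window_days) {
  if (length(admit) != length(discharge)) {
    stop("'admit' and 'discharge' must have equal length")
  }
  a <- as.numeric(admit); d <- as.numeric(discharge)
  if (is.unsorted(a)) stop("visits must be sorted ascending by admit date")
  n <- length(a)
  if (n == 0L) return(integer(0))
  gaps <- a[-1L] - d[-n]
  if (any(gaps < 0)) stop("overlapping stays: next admission before discharge")
  as.integer(c(gaps <= window_days, FALSE))
}

#' Filter an admission table by medical specialty
#'
#' Two cohort definitions: `"all"` keeps every specialty except pediatrics
#' and obstetrics/gynecology; `"main"` keeps only the four largest
#' specialties (medicine, surgery, orthopedics, cardiology).
#'
#' @param table Admission data frame with a specialty column.
#' @param mode `"all"` or `"main"`.
#' @param specialty_col Name of the specialty column.
#' @return The filtered table, with attributes `n_kept` and `n_dropped`.
#' @export
filter_specialties <- function(table, mode = c("all", "main"),
                               specialty_col = "specialty") {
  mode <- match.arg(mode)
  sp <- table[[specialty_col]]
  if (is.null(sp)) stop("table has no '", specialty_col, "' column")
  keep <- if (mode == "all") {
    !(sp %in% c("pediatrics", "obstetrics/gynecology"))
  } else {
    sp %in% c("medicine", "surgery", "orthopedics", "cardiology")
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_dropped") <- sum(!keep)
  message(sprintf("filter_specialties(mode=\"%s\"): kept %d, dropped %d rows",
                  mode, sum(keep), sum(!keep)))
  out
}

#' Assemble the labelled design matrix from an admission table
#'
#' Turns a raw admission table into the modelling dataset: per-patient
#' prior-visit counts are appended, 30/90-day readmission labels are
#' attached, categorical columns are one-hot encoded (full encoding, no
#' reference level dropped — trees are collinearity-insensitive), binary
#' columns coded 0/1, and continuous columns passed through unscaled.
#' Rows with missing values in any feature column are dropped and counted.
#' Visits admitted within a label window of the observation-range end are
#' flagged as censored (their 0 label may be truncation, not absence of
#' readmission).
#'
#' @param table Admission data frame with `patient_id`, `visit_id`,
#'   `admit_date`, `discharge_date` and feature columns.
#' @param feature_cols Character vector of feature columns; default every
#'   column except ids and dates.
#' @param label_windows Outcome windows in days (default `c(30, 90)`).
#' @param prior_window Look-back window for the prior-visit count.
#' @param range_end End of the observation window used for censoring flags;
#'   default the table's latest admission date.
#' @param drop_censored Drop visits censored for the *longest* label window
#'   instead of merely flagging them.
#' @return An object of class `"labeled_cohort"`: list with the numeric
#'   matrix `X`, labels `y30`/`y90` (named `y<window>` for other windows),
#'   `feature_names`, `row_keys` (patient/visit ids), per-window `censored`
#'   flags, recorded categorical `levels`, and `n_dropped_missing`.
#' @export
assemble_design_matrix <- function(table, feature_cols = NULL,
                                   label_windows = c(30, 90),
                                   prior_window = 180,
                                   range_end = NULL,
                                   drop_censored = FALSE) {
  required <- c("patient_id", "visit_id", "admit_date", "discharge_date")
  miss <- setdiff(required, names(table))
  if (length(miss)) stop("table lacks column(s): ", paste(miss, collapse = ", "))
  if (is.null(feature_cols)) {
    feature_cols <- setdiff(names(table), required)
  } else {
    absent <- setdiff(feature_cols, names(table))
    if (length(absent)) {
      stop("feature column(s) absent: ", paste(absent, collapse = ", "))
    }
  }
  tab <- table[order(table$patient_id, as.Date(table$admit_date)), ,
               drop = FALSE]
  rownames(tab) <- NULL
  admit <- as.numeric(as.Date(tab$admit_date))
  discharge <- as.numeric(as.Date(tab$discharge_date))
  pid <- as.character(tab$patient_id)

  # per-patient prior counts and labels
  idx_by_pat <- split(seq_along(pid), pid)
  vn <- integer(nrow(tab))
  labels <- matrix(0L, nrow(tab), length(label_windows))
  for (ix in idx_by_pat) {
    vn[ix] <- count_prior_visits(admit[ix], discharge[ix], prior_window)
    for (w in seq_along(label_windows)) {
      labels[ix, w] <- build_labels(admit[ix], discharge[ix],
                                    label_windows[w])
    }
  }
  if (is.null(range_end)) range_end <- max(admit)
  range_end <- as.numeric(as.Date(range_end))
  censored <- lapply(label_windows,
                     function(w) admit > range_end - w)
  names(censored) <- paste0("censored", label_windows)

  feats <- tab[, feature_cols, drop = FALSE]
  feats$visit_num <- vn
  complete <- stats::complete.cases(feats)
  n_dropped <- sum(!complete)
  if (n_dropped) {
    message(sprintf("assemble_design_matrix: dropped %d rows with missing features",
                    n_dropped))
  }
  keep <- complete
  if (drop_censored) keep <- keep & !censored[[length(label_windows)]]
  feats <- feats[keep, , drop = FALSE]
  labels <- labels[keep, , drop = FALSE]
  censored <- lapply(censored, function(z) z[keep])

  # encode: categoricals -> full one-hot with recorded level order
  cols <- list(); levels_map <- list()
  for (nm in names(feats)) {
    v <- feats[[nm]]
    if (is.numeric(v)) {
      cols[[nm]] <- as.numeric(v)
    } else {
      v <- as.character(v)
      lv <- sort(unique(v))
      levels_map[[nm]] <- lv
      for (l in lv) cols[[paste0(nm, "=", l)]] <- as.numeric(v == l)
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  if (any(!is.finite(X))) stop("non-finite value in encoded feature matrix")

  out <- list(X = X,
              feature_names = colnames(X),
              row_keys = data.frame(patient_id = pid[keep],
                                    visit_id = as.character(tab$visit_id)[keep],
                                    stringsAsFactors = FALSE),
              levels = levels_map,
              n_dropped_missing = n_dropped)
  for (w in seq_along(label_windows)) {
    out[[paste0("y", label_windows[w])]] <- labels[, w]
  }
  out <- c(out, censored)
  class(out) <- "labeled_cohort"
  out
}

#' @export
print.labeled_cohort <- function(x, ...) {
  cat("Labelled cohort: ", nrow(x$X), " visits x ", ncol(x$X),
      " encoded features\n", sep = "")
  for (nm in grep("^y[0-9]+$", names(x), value = TRUE)) {
    cat(sprintf("  %s prevalence: %.3f\n", nm, mean(x[[nm]])))
  }
  if (x$n_dropped_missing) {
    cat("  dropped for missingness:", x$n_dropped_missing, "\n")
  }
  invisible(x)
}

#' Serialize a labelled cohort as CSV + JSON sidecar
#'
#' The matrix (with labels appended) goes to `<prefix>.csv`; feature names,
#' categorical level orders and row keys go to `<prefix>.json`.
#'
#' @param x A `"labeled_cohort"`.
#' @param prefix Path prefix for the two files.
#' @export
write_labeled_cohort <- function(x, prefix) {
  stopifnot(inherits(x, "labeled_cohort"))
  ycols <- grep("^y[0-9]+$", names(x), value = TRUE)
  df <- as.data.frame(x$X, check.names = FALSE)
  for (nm in ycols) df[[nm]] <- x[[nm]]
  utils::write.csv(df, paste0(prefix, ".csv"), row.names = FALSE)
  side <- list(feature_names = x$feature_names, levels = x$levels,
               row_keys = x$row_keys, label_cols = ycols,
               n_dropped_missing = x$n_dropped_missing)
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_labeled_cohort
#' @export
read_labeled_cohort <- function(prefix) {
  df <- utils::read.csv(paste0(prefix, ".csv"), check.names = FALSE)
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  ycols <- side$label_cols
  X <- as.matrix(df[, setdiff(names(df), ycols), drop = FALSE])
  out <- list(X = X, feature_names = side$feature_names,
              row_keys = as.data.frame(side$row_keys),
              levels = as.list(side$levels),
              n_dropped_missing = side$n_dropped_missing)
  for (nm in ycols) out[[nm]] <- as.integer(df[[nm]])
  class(out) <- "labeled_cohort"
  out
}
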