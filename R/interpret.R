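#' Cross-model feature-overlap table
#'
#' Compares which features the extracted trees (and any other tree models)
#' actually split on. A feature is "influential" for a model when it
#' appears as a split with total gain above `min_gain`. Rows are the union
#' of influential features across models, ordered by how many models use
#' the feature (descending), then alphabetically. Features used by every
#' model are the consensus risk factors worth clinical review.
#'
#' @param trees Named list of `"dstree"`/`"extree"` objects; names label
#'   the columns.
#' @param min_gain Minimum total gain for a feature to count as
#'   influential (default 0: any split counts).
#' @return An object of class `"feature_overlap"`: a data frame of 0/1
#'   indicators with a `feature` column, and attribute `gains` holding the
#'   per-(feature, model) total gains.
#' @export
feature_overlap <- function(trees, min_gain = 0) {
  if (!length(trees)) stop("need at least one fitted tree")
  if (is.null(names(trees)) || any(!nzchar(names(trees)))) {
    names(trees) <- paste0("model", seq_along(trees))
  }
  sf <- lapply(trees, split_features)
  sf <- lapply(sf, function(d) d[d$total_gain > min_gain | min_gain == 0, ,
                                 drop = FALSE])
  feats <- sort(unique(unlist(lapply(sf, `[[`, "feature"))))
  if (!length(feats)) {
    df <- data.frame(feature = character(0))
    for (nm in names(trees)) df[[nm]] <- integer(0)
    return(structure(df,
                     gains = matrix(numeric(0), 0, length(trees),
                                    dimnames = list(NULL, names(trees))),
                     class = c("feature_overlap", "data.frame")))
  }
  ind <- sapply(sf, function(d) as.integer(feats %in% d$feature))
  ind <- matrix(ind, nrow = length(feats),
                dimnames = list(feats, names(trees)))
  gains <- sapply(sf, function(d) {
    g <- stats::setNames(d$total_gain, d$feature)
    out <- rep(NA_real_, length(feats))
    out[match(names(g), feats)] <- g
    out
  })
  gains <- matrix(gains, nrow = length(feats),
                  dimnames = list(feats, names(trees)))
  ord <- order(-rowSums(ind), feats)
  df <- data.frame(feature = feats[ord], ind[ord, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(df, gains = gains[ord, , drop = FALSE],
            class = c("feature_overlap", "data.frame"))
}

#' @export
print.feature_overlap <- function(x, ...) {
  cat("Feature overlap across models (1 = used as a split):\n")
  print.data.frame(x)
  invisible(x)
}

#' Write a feature-overlap table as CSV or Markdown
#'
#' @param x A `"feature_overlap"`.
#' @param path File path.
#' @param format `"csv"` or `"markdown"` (checkmark-style table).
#' @export
write_feature_overlap <- function(x, path, format = c("csv", "markdown")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "feature_overlap"))
  if (format == "csv") {
    utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  } else {
    models <- setdiff(names(x), "feature")
    header <- paste0("| feature | ", paste(models, collapse = " | "), " |")
    sep <- paste0("|", strrep(" --- |", length(models) + 1))
    rows <- apply(as.data.frame(x), 1, function(r) {
      marks <- ifelse(r[models] == "1" | r[models] == 1, "x", "")
      paste0("| ", r[["feature"]], " | ",
             paste(marks, collapse = " | "), " |")
    })
    writeLines(c(header, sep, rows), path)
  }
  invisible(path)
}

#' Results-table assembly with significance stars
#'
#' Collects replicated summaries into one table of mean scores per model
#' and metric, starring models that significantly beat the named baseline
#' (see [significance_flags()]).
#'
#' @param summaries Named list of `"replication_summary"` objects.
#' @param baseline Name of the baseline entry (default the first).
#' @param metrics Which metrics to tabulate.
#' @return Data frame with one row per model; starred entries are
#'   formatted as e.g. `"0.699**"`.
#' @export
report_table <- function(summaries, baseline = names(summaries)[1],
                         metrics = c("acc", "auc", "auprc")) {
  stopifnot(length(summaries) >= 1, baseline %in% names(summaries))
  base <- summaries[[baseline]]
  rows <- lapply(names(summaries), function(nm) {
    s <- summaries[[nm]]
    flags <- if (nm == baseline) {
      stats::setNames(rep("ns", nrow(s$summary)), rownames(s$summary))
    } else {
      significance_flags(s, base)
    }
    vals <- vapply(metrics, function(m) {
      star <- switch(flags[[m]], "ns" = "", "*" = "*", "**" = "**")
      sprintf("%.3f%s", s$summary[m, "mean"], star)
    }, "")
    c(model = nm, vals)
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}
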