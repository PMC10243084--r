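#' Ground-truth readmission risk mechanism
#'
#' Defines the data-generating process behind [generate_cohort()]: marginal
#' distributions for every admission-level feature plus a logistic risk model
#' on the log-odds scale. The risk function gives each visit's probability of
#' a subsequent admission within 30 days, so distillation fidelity and
#' feature-recovery claims can be checked against a known truth.
#'
#' @param intercept Log-odds intercept. `NA` means "calibrate at generation
#'   time against the cohort's target 30-day prevalence" (see
#'   [calibrate_intercept()]).
#' @param coefficients Named numeric vector of log-odds coefficients. Every
#'   name must refer to a feature in `feature_specs` (the emergent
#'   `visit_num` prior-visit count included); categorical features cannot
#'   carry coefficients directly.
#' @param feature_specs Named list of marginal feature descriptions. Each
#'   element is a list with a `type` field:
#'   * `"continuous"` — `dist` one of `"normal"` (`mean`, `sd`, optional
#'     `min`/`max` truncation bounds) or `"lognormal"` (`meanlog`, `sdlog`);
#'     optional `round = TRUE` rounds to whole units.
#'   * `"binary"` — success probability `p`.
#'   * `"categorical"` — `levels`, a named probability vector summing to 1.
#'   * `"emergent"` — computed from the visit history rather than drawn
#'     (only `visit_num`); `pilot` gives a Poisson `lambda` used as a
#'     stand-in marginal during intercept calibration.
#' @param interarrival_scale Mean (days) of the exponential tail gap for
#'   visits not readmitted within 90 days. Larger values space visit chains
#'   further apart, so fewer follow-ups fall inside the observation window
#'   and the realized readmission prevalence drops.
#' @return An object of class `"risk_mechanism"`.
#' @seealso [default_mechanism()], [generate_cohort()], [true_risk()]
#' @export
risk_mechanism <- function(intercept, coefficients, feature_specs,
                           interarrival_scale = 240) {
  if (!is.numeric(interarrival_scale) || interarrival_scale <= 0) {
    stop("'interarrival_scale' must be a positive number of days")
  }
  coefficients <- unlist(coefficients)
  if (length(coefficients) && is.null(names(coefficients))) {
    stop("'coefficients' must be named by feature")
  }
  unknown <- setdiff(names(coefficients), names(feature_specs))
  if (length(unknown)) {
    stop("coefficient(s) reference unknown feature(s): ",
         paste(unknown, collapse = ", "))
  }
  for (nm in names(feature_specs)) {
    sp <- feature_specs[[nm]]
    if (is.null(sp$type)) stop("feature spec '", nm, "' lacks a type")
    if (identical(sp$type, "binary")) {
      if (sp$p < 0 || sp$p > 1) stop("binary p for '", nm, "' outside [0,1]")
    }
    if (identical(sp$type, "categorical")) {
      pr <- unlist(sp$levels)
      if (any(pr < 0) || abs(sum(pr) - 1) > 1e-8) {
        stop("categorical level probabilities for '", nm,
             "' must be in [0,1] and sum to 1")
      }
      if (nm %in% names(coefficients)) {
        stop("categorical feature '", nm, "' cannot carry a coefficient")
      }
    }
  }
  structure(
    list(intercept = intercept,
         coefficients = coefficients,
         feature_specs = feature_specs,
         interarrival_scale = interarrival_scale),
    class = "risk_mechanism")
}

#' Default synthetic readmission mechanism
#'
#' The feature roster mirrors the administrative variables of a typical
#' hospital-admission dataset: age, Charlson and van Walraven comorbidity
#' scores, length of stay, emergency-department admission flag,
#' nursing-home discharge flag, insurance class, surgery and ICU flags,
#' transfer count, secondary-diagnosis count, medical specialty, and the
#' emergent count of prior visits in the last six months. Coefficients put
#' most signal on comorbidity, prior utilisation and admission source,
#' matching the risk factors the readmission literature flags as reliable.
#'
#' @param interarrival_scale Passed through to [risk_mechanism()].
#' @return A `"risk_mechanism"` with an uncalibrated (`NA`) intercept.
#' @export
default_mechanism <- function(interarrival_scale = 240) {
  specs <- list(
    age = list(type = "continuous", dist = "normal", mean = 62, sd = 18,
               min = 18, max = 100, round = TRUE),
    charlson = list(type = "continuous", dist = "pois", lambda = 1.5),
    van_walraven = list(type = "continuous", dist = "normal", mean = 4,
                        sd = 6, round = TRUE),
    los = list(type = "continuous", dist = "lognormal", meanlog = 1.2,
               sdlog = 0.8, round = TRUE),
    visit_num = list(type = "emergent", pilot = list(dist = "pois",
                                                     lambda = 0.3)),
    admit_ed = list(type = "binary", p = 0.55),
    nursing_home = list(type = "binary", p = 0.08),
    insurance_public = list(type = "binary", p = 0.60),
    surgery = list(type = "binary", p = 0.35),
    icu = list(type = "binary", p = 0.08),
    transfers = list(type = "continuous", dist = "pois", lambda = 0.2),
    second_diag_count = list(type = "continuous", dist = "pois", lambda = 2),
    specialty = list(type = "categorical", levels = c(
      medicine = 0.30, surgery = 0.24, orthopedics = 0.12, cardiology = 0.11,
      pediatrics = 0.05, `obstetrics/gynecology` = 0.05, others = 0.13))
  )
  coefs <- c(age = 0.012, charlson = 0.25, van_walraven = 0.05,
             los = 0.03, visit_num = 0.45, admit_ed = 0.50,
             nursing_home = 0.40, insurance_public = 0.20,
             surgery = -0.20, second_diag_count = 0.08)
  risk_mechanism(intercept = NA_real_, coefficients = coefs,
                 feature_specs = specs,
                 interarrival_scale = interarrival_scale)
}

#' Shallow-truth mechanism for distillation-fidelity experiments
#'
#' Same feature roster as [default_mechanism()] but with the risk signal
#' concentrated in three canonical readmission factors — emergency
#' admission (0.8), Charlson score (0.6) and prior-visit count (0.6), all
#' other coefficients zero. With a truth this shallow, a depth-4 surrogate
#' tree can track the black box closely, which is the regime in which
#' extracted-tree and black-box accuracy are expected to be comparable.
#'
#' @inheritParams default_mechanism
#' @return A `"risk_mechanism"` with an uncalibrated (`NA`) intercept.
#' @export
shallow_mechanism <- function(interarrival_scale = 240) {
  m <- default_mechanism(interarrival_scale)
  m$coefficients <- c(charlson = 0.6, visit_num = 0.6, admit_ed = 0.8)
  m
}

# Vectorized draw of n feature rows from the mechanism's marginals,
# returned as a named list of vectors (cheaper than a data.frame in the
# per-patient generation loop). Emergent features use their pilot marginal
# when pilot = TRUE, otherwise they are omitted (the generator computes
# them from the visit history).
draw_features_list <- function(specs, n, pilot = FALSE) {
  out <- list()
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    v <- switch(sp$type,
      continuous = {
        x <- switch(sp$dist,
          normal = stats::rnorm(n, sp$mean, sp$sd),
          lognormal = stats::rlnorm(n, sp$meanlog, sp$sdlog),
          pois = stats::rpois(n, sp$lambda),
          stop("unknown continuous dist '", sp$dist, "'"))
        if (!is.null(sp$min)) x <- pmax(x, sp$min)
        if (!is.null(sp$max)) x <- pmin(x, sp$max)
        if (isTRUE(sp$round)) x <- round(x)
        as.numeric(x)
      },
      binary = as.numeric(stats::runif(n) < sp$p),
      categorical = {
        pr <- unlist(sp$levels)
        names(pr)[1L + findInterval(stats::runif(n), cumsum(pr),
                                    rightmost.closed = TRUE)]
      },
      emergent = {
        if (!pilot) NULL else as.numeric(stats::rpois(n, sp$pilot$lambda))
      },
      stop("unknown feature type '", sp$type, "'"))
    if (!is.null(v)) out[[nm]] <- v
  }
  out
}

draw_features <- function(specs, n, pilot = FALSE) {
  as.data.frame(draw_features_list(specs, n, pilot), check.names = FALSE,
                stringsAsFactors = FALSE)
}

#' Ground-truth readmission probability
#'
#' Evaluates the mechanism's logistic risk function: the probability that a
#' visit with the given features is followed by another admission within 30
#' days, `plogis(intercept + sum(coefficients * features))`.
#'
#' @param mechanism A [risk_mechanism()].
#' @param features A data frame (one row per visit) or a named vector/list
#'   supplying every feature named in the mechanism's coefficients.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
true_risk <- function(mechanism, features) {
  stopifnot(inherits(mechanism, "risk_mechanism"))
  if (is.na(mechanism$intercept)) {
    stop("mechanism intercept is NA; calibrate it first ",
         "(see calibrate_intercept)")
  }
  if (!is.data.frame(features)) {
    features <- as.data.frame(as.list(features), check.names = FALSE)
  }
  eta <- rep(mechanism$intercept, nrow(features))
  for (nm in names(mechanism$coefficients)) {
    if (is.null(features[[nm]])) {
      stop("feature '", nm, "' required by the mechanism is missing")
    }
    eta <- eta + mechanism$coefficients[[nm]] * as.numeric(features[[nm]])
  }
  stats::plogis(eta)
}

#' Calibrate the mechanism intercept against a target prevalence
#'
#' Solves (by bisection) for the intercept at which the mean ground-truth
#' risk over a pilot sample of feature draws equals the target 30-day
#' readmission prevalence. Emergent features (the prior-visit count) use
#' their pilot marginal.
#'
#' @param mechanism A [risk_mechanism()].
#' @param target Target mean risk in (0, 1).
#' @param n_pilot Pilot sample size.
#' @param seed Integer seed for the pilot draw.
#' @return The mechanism with its intercept replaced by the solution.
#' @export
calibrate_intercept <- function(mechanism, target, n_pilot = 10000,
                                seed = 1L) {
  stopifnot(inherits(mechanism, "risk_mechanism"))
  if (target <= 0 || target >= 1) stop("'target' must lie in (0,1)")
  pilot <- with_seed(seed, draw_features(mechanism$feature_specs, n_pilot,
                                         pilot = TRUE))
  eta0 <- rep(0, n_pilot)
  for (nm in names(mechanism$coefficients)) {
    eta0 <- eta0 + mechanism$coefficients[[nm]] * as.numeric(pilot[[nm]])
  }
  f <- function(b) mean(stats::plogis(b + eta0)) - target
  lo <- -30; hi <- 30
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < 1e-10) break
  }
  mechanism$intercept <- (lo + hi) / 2
  mechanism
}

#' Realized readmission prevalence of a generated cohort
#'
#' Mean outcome label among visits admitted early enough for the outcome
#' window to be fully observed (visits admitted within `window` days of
#' `range_end` are excluded as censored).
#'
#' @param cohort Admission table (see [generate_cohort()]).
#' @param window Outcome window in days.
#' @param range_end End of the observation window; default the table's
#'   latest admission date.
#' @return The realized prevalence (a proportion).
#' @export
realized_prevalence <- function(cohort, window, range_end = NULL) {
  admit <- as.numeric(as.Date(cohort$admit_date))
  dis <- as.numeric(as.Date(cohort$discharge_date))
  if (is.null(range_end)) range_end <- max(admit)
  range_end <- as.numeric(as.Date(range_end))
  lab <- cen <- logical(0)
  for (ix in split(seq_along(admit), cohort$patient_id)) {
    o <- ix[order(admit[ix])]
    lab <- c(lab, build_labels(admit[o], dis[o], window) == 1L)
    cen <- c(cen, admit[o] > range_end - window)
  }
  mean(lab[!cen])
}

# Full mechanism calibration for a cohort configuration. The pilot-draw
# bisection of calibrate_intercept() ignores two endogenous effects:
# high-risk patients contribute more visits, and later visits carry larger
# prior-visit counts, so the realized per-visit prevalence overshoots the
# pilot target. A couple of stochastic-approximation corrections against
# small internally generated cohorts remove the bias: each round shifts
# the intercept by logit(target) - logit(realized).
calibrate_mechanism <- function(mechanism, config, n_iters = 2,
                                n_check = 4000) {
  mechanism <- calibrate_intercept(mechanism, config$target_prevalence_30,
                                   seed = sub_seed(config$seed, 0L))
  check_cfg <- config
  check_cfg$n_patients <- min(config$n_patients, as.integer(n_check))
  p30 <- config$target_prevalence_30; p90 <- config$target_prevalence_90
  for (it in seq_len(n_iters)) {
    check_cfg$seed <- sub_seed(config$seed, 900000L + it)
    tab <- generate_core(check_cfg, mechanism)
    r30 <- realized_prevalence(tab, 30, config$date_range[2])
    r30 <- min(max(r30, 1e-4), 1 - 1e-4)
    mechanism$intercept <- mechanism$intercept +
      stats::qlogis(p30) - stats::qlogis(r30)
    # same correction for the 31-90 day arm (mass between the windows)
    r90 <- realized_prevalence(tab, 90, config$date_range[2])
    q_cur <- if (is.null(mechanism$q90)) (p90 - p30) / (1 - p30)
             else mechanism$q90
    mechanism$q90 <- min(max(q_cur * (p90 - p30) / max(r90 - r30, 1e-4),
                             0), 1)
  }
  mechanism
}

#' Synthetic cohort configuration
#'
#' @param n_patients Number of patients to simulate (positive integer).
#' @param max_visits_per_patient Hard cap on a patient's visit chain.
#' @param date_range Length-2 `Date` vector; must span at least 365 days so
#'   90-day outcomes are observable.
#' @param seed Master integer seed; each patient draws from a counter-based
#'   sub-stream so adding patients never perturbs earlier patients.
#' @param target_prevalence_30,target_prevalence_90 Target per-visit 30- and
#'   90-day readmission prevalences (defaults 14.3% and 24.4%, the rates a
#'   large administrative readmission cohort typically shows).
#' @return An object of class `"cohort_config"`.
#' @export
cohort_config <- function(n_patients = 5000, max_visits_per_patient = 30,
                          date_range = as.Date(c("2010-01-01", "2011-12-31")),
                          seed = 1L,
                          target_prevalence_30 = 0.143,
                          target_prevalence_90 = 0.244) {
  n_patients <- as.integer(n_patients)
  if (is.na(n_patients) || n_patients <= 0) {
    stop("'n_patients' must be a positive integer")
  }
  if (max_visits_per_patient < 1) stop("'max_visits_per_patient' must be >= 1")
  date_range <- as.Date(date_range)
  if (length(date_range) != 2 || anyNA(date_range)) {
    stop("'date_range' must be two valid dates")
  }
  if (as.numeric(diff(date_range)) < 365) {
    stop("'date_range' must span at least 365 days")
  }
  p30 <- target_prevalence_30; p90 <- target_prevalence_90
  if (!(p30 > 0 && p30 <= p90 && p90 < 1)) {
    stop("need 0 < target_prevalence_30 <= target_prevalence_90 < 1")
  }
  structure(list(n_patients = n_patients,
                 max_visits_per_patient = as.integer(max_visits_per_patient),
                 date_range = date_range, seed = as.integer(seed),
                 target_prevalence_30 = p30, target_prevalence_90 = p90),
            class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("Cohort configuration: %d patients, %s to %s, seed %d\n",
              x$n_patients, format(x$date_range[1]),
              format(x$date_range[2]), x$seed))
  cat(sprintf("  target prevalence: %.3f (30-day), %.3f (90-day); <= %d visits/patient\n",
              x$target_prevalence_30, x$target_prevalence_90,
              x$max_visits_per_patient))
  invisible(x)
}

#' Generate a synthetic hospital-admission cohort
#'
#' Simulates per-patient visit chains under the mechanism's risk function.
#' For each visit, features are drawn from the mechanism's marginals, the
#' ground-truth 30-day readmission probability is evaluated (including the
#' realized prior-visit count), and the gap to the next admission is drawn
#' as: with probability `true_risk`, uniform on 1..30 days; otherwise with a
#' secondary probability calibrated to the 90-day target, uniform on 31..90
#' days; otherwise `91 + Exponential(interarrival_scale)` days. Chains stop
#' when the next admission would fall beyond the date range or the visit cap
#' is reached. Admission month and day-of-week are derived from the
#' admission date and emitted as categorical feature columns.
#'
#' @param config A [cohort_config()].
#' @param mechanism A [risk_mechanism()]; default [default_mechanism()].
#' @param calibrate Recalibrate the intercept against
#'   `config$target_prevalence_30` (always done when the intercept is `NA`).
#' @return A data frame with columns `patient_id`, `visit_id`, `admit_date`,
#'   `discharge_date` and the feature columns, sorted by patient and
#'   admission date. The calibrated mechanism is attached as attribute
#'   `"mechanism"`.
#' @examples
#' cfg <- cohort_config(n_patients = 200, seed = 7)
#' coh <- generate_cohort(cfg)
#' head(coh)
#' @export
generate_cohort <- function(config, mechanism = default_mechanism(),
                            calibrate = TRUE) {
  stopifnot(inherits(config, "cohort_config"),
            inherits(mechanism, "risk_mechanism"))
  if (calibrate || is.na(mechanism$intercept)) {
    mechanism <- calibrate_mechanism(mechanism, config)
  }
  generate_core(config, mechanism)
}

generate_core <- function(config, mechanism) {
  p30 <- config$target_prevalence_30
  q90 <- if (!is.null(mechanism$q90)) mechanism$q90
         else (config$target_prevalence_90 - p30) / (1 - p30)
  start <- config$date_range[1]; end <- config$date_range[2]
  span <- as.numeric(end - start)
  specs <- mechanism$feature_specs
  coefs <- mechanism$coefficients
  kmax <- config$max_visits_per_patient
  scale_tail <- mechanism$interarrival_scale

  chunk <- 8L
  np <- config$n_patients
  # flat accumulators (visit chains are short; grow in blocks)
  cap <- np * 3L
  acc <- new.env(parent = emptyenv())
  acc$pid <- integer(cap); acc$vno <- integer(cap)
  acc$admit <- numeric(cap); acc$dis <- numeric(cap)
  feat_names <- names(draw_features_list(specs, 1L, pilot = FALSE))
  for (nm in feat_names) {
    acc[[nm]] <- vector(if (nm == "specialty" ||
                            specs[[nm]]$type == "categorical")
                        "character" else "numeric", cap)
  }
  pos <- 0L
  ensure <- function(need) {
    if (need <= cap) return(invisible())
    newcap <- max(need, 2L * cap)
    for (nm in ls(acc)) {
      length(acc[[nm]]) <- newcap
    }
    cap <<- newcap
  }
  start_num <- as.numeric(start); end_num <- as.numeric(end)

  for (i in seq_len(np)) {
    set.seed(sub_seed(config$seed, i))
    feats <- draw_features_list(specs, chunk, pilot = FALSE)
    u_read <- stats::runif(chunk)
    u_late <- stats::runif(chunk)
    gap30 <- sample.int(30, chunk, replace = TRUE)
    gap90 <- 30L + sample.int(60, chunk, replace = TRUE)
    gap_tail <- 91 + round(stats::rexp(chunk, 1 / scale_tail))
    n_drawn <- chunk
    admit <- start_num + floor(stats::runif(1) * (span + 1))
    dis_hist <- numeric(0)
    k <- 0L
    repeat {
      k <- k + 1L
      if (k > n_drawn) {  # extend this patient's pre-drawn block
        more <- draw_features_list(specs, chunk, pilot = FALSE)
        for (nm in feat_names) feats[[nm]] <- c(feats[[nm]], more[[nm]])
        u_read <- c(u_read, stats::runif(chunk))
        u_late <- c(u_late, stats::runif(chunk))
        gap30 <- c(gap30, sample.int(30, chunk, replace = TRUE))
        gap90 <- c(gap90, 30L + sample.int(60, chunk, replace = TRUE))
        gap_tail <- c(gap_tail, 91 + round(stats::rexp(chunk,
                                                       1 / scale_tail)))
        n_drawn <- n_drawn + chunk
      }
      discharge <- admit + max(0, feats$los[k])
      vn <- if (length(dis_hist)) sum(admit - dis_hist <= 180) else 0L
      eta <- mechanism$intercept
      for (nm in names(coefs)) {
        val <- if (nm == "visit_num") vn else feats[[nm]][k]
        eta <- eta + coefs[[nm]] * val
      }
      risk <- stats::plogis(eta)
      gap <- if (u_read[k] < risk) gap30[k]
             else if (u_late[k] < q90) gap90[k]
             else gap_tail[k]
      pos <- pos + 1L
      ensure(pos)
      acc$pid[pos] <- i; acc$vno[pos] <- k
      acc$admit[pos] <- admit; acc$dis[pos] <- discharge
      for (nm in feat_names) acc[[nm]][pos] <- feats[[nm]][k]
      dis_hist <- c(dis_hist, discharge)
      next_admit <- discharge + gap
      if (k >= kmax || next_admit > end_num) break
      admit <- next_admit
    }
  }
  ix <- seq_len(pos)
  out <- data.frame(
    patient_id = sprintf("P%06d", acc$pid[ix]),
    visit_id = sprintf("P%06d-%d", acc$pid[ix], acc$vno[ix]),
    admit_date = as.Date(acc$admit[ix], origin = as.Date("1970-01-01")),
    discharge_date = as.Date(acc$dis[ix], origin = as.Date("1970-01-01")),
    stringsAsFactors = FALSE)
  for (nm in feat_names) out[[nm]] <- acc[[nm]][ix]
  lt <- as.POSIXlt(out$admit_date)
  out$admit_month <- month.abb[lt$mon + 1L]
  out$admit_dow <- c("Sun", "Mon", "Tue", "Wed", "Thu", "Fri",
                     "Sat")[lt$wday + 1L]
  out <- out[order(out$patient_id, out$admit_date), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "mechanism") <- mechanism
  attr(out, "config") <- config
  out
}

#' @export
print.risk_mechanism <- function(x, ...) {
  cat("Ground-truth risk mechanism\n")
  cat("  intercept:", format(x$intercept, digits = 4), "\n")
  cat("  coefficients:", length(x$coefficients), "features\n")
  top <- sort(abs(x$coefficients), decreasing = TRUE)
  cat("  largest |coef|:",
      paste(sprintf("%s=%.3g", names(top)[seq_len(min(5, length(top)))],
                    x$coefficients[names(top)[seq_len(min(5, length(top)))]]),
            collapse = ", "), "\n")
  cat("  interarrival tail scale:", x$interarrival_scale, "days\n")
  invisible(x)
}

#' Read/write mechanisms and cohort configurations as YAML
#'
#' @param x A `"risk_mechanism"` or `"cohort_config"`.
#' @param path File path.
#' @return `read_mechanism()`/`read_cohort_config()` return the
#'   reconstructed object; the writers return `path` invisibly.
#' @export
write_mechanism <- function(x, path) {
  stopifnot(inherits(x, "risk_mechanism"))
  obj <- unclass(x)
  obj$coefficients <- as.list(obj$coefficients)
  # yaml drops names on atomic vectors; maps need explicit lists
  obj$feature_specs <- lapply(obj$feature_specs, function(sp) {
    if (!is.null(sp$levels)) sp$levels <- as.list(sp$levels)
    sp
  })
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_mechanism
#' @export
read_mechanism <- function(path) {
  obj <- yaml::read_yaml(path)
  specs <- lapply(obj$feature_specs, function(sp) {
    if (!is.null(sp$levels)) sp$levels <- unlist(sp$levels)
    sp
  })
  risk_mechanism(intercept = if (is.null(obj$intercept)) NA_real_
                             else obj$intercept,
                 coefficients = unlist(obj$coefficients),
                 feature_specs = specs,
                 interarrival_scale = obj$interarrival_scale)
}

#' @rdname write_mechanism
#' @export
write_cohort_config <- function(x, path) {
  stopifnot(inherits(x, "cohort_config"))
  obj <- unclass(x)
  obj$date_range <- format(obj$date_range)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_mechanism
#' @export
read_cohort_config <- function(path) {
  obj <- yaml::read_yaml(path)
  cohort_config(n_patients = obj$n_patients,
                max_visits_per_patient = obj$max_visits_per_patient,
                date_range = as.Date(unlist(obj$date_range)),
                seed = obj$seed,
                target_prevalence_30 = obj$target_prevalence_30,
                target_prevalence_90 = obj$target_prevalence_90)
}

#' Read/write admission tables as CSV
#'
#' The CSV carries a `#`-prefixed provenance header (tool version and, when
#' available, the generating seed) followed by a standard header row;
#' dates are ISO-8601.
#'
#' @param cohort Admission table as returned by [generate_cohort()].
#' @param path File path.
#' @export
write_cohort <- function(cohort, path) {
  cfg <- attr(cohort, "config")
  prov <- sprintf("# extree cohort v%s rows=%d%s",
                  as.character(utils::packageVersion("extree")),
                  nrow(cohort),
                  if (is.null(cfg)) "" else sprintf(" seed=%d", cfg$seed))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(prov, con)
  utils::write.csv(cohort, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  for (col in c("admit_date", "discharge_date")) {
    if (!is.null(out[[col]])) out[[col]] <- as.Date(out[[col]])
  }
  out
}
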