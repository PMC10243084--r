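# Synthetic cohort generator: ground-truth risk, calibration, determinism.

test_that("true_risk evaluates the logistic risk function", {
  specs <- list(a = list(type = "continuous", dist = "normal",
                         mean = 0, sd = 1))
  m0 <- risk_mechanism(0, c(a = 0), specs)
  expect_equal(true_risk(m0, c(a = 7)), 0.5)

  m1 <- risk_mechanism(-2, c(a = 1), specs)
  expect_equal(true_risk(m1, c(a = 2)), 0.5)

  # qlogis(0.143) = -1.7898; at the printed precision -1.79 the risk is
  # 0.143 to three decimals
  m2 <- risk_mechanism(-1.79, c(a = 0), specs)
  expect_equal(true_risk(m2, c(a = 0)), 0.143, tolerance = 0.001)

  expect_error(true_risk(m1, c(b = 1)), "'a'")
})

test_that("mechanism validation catches bad inputs", {
  specs <- list(a = list(type = "binary", p = 0.5),
                g = list(type = "categorical",
                         levels = c(x = 0.4, y = 0.6)))
  expect_error(risk_mechanism(0, c(zzz = 1), specs), "unknown feature")
  expect_error(risk_mechanism(0, c(a = 1),
                              list(a = list(type = "binary", p = 1.3))),
               "outside")
  expect_error(risk_mechanism(0, c(g = 1), specs), "categorical")
  expect_error(cohort_config(n_patients = 0), "positive")
  expect_error(cohort_config(date_range = as.Date(c("2010-01-01",
                                                    "2010-06-01"))),
               "365")
})

test_that("zero-coefficient mechanism hits the calibrated prevalence", {
  specs <- list(a = list(type = "continuous", dist = "normal",
                         mean = 0, sd = 1),
                los = list(type = "continuous", dist = "lognormal",
                           meanlog = 1.2, sdlog = 0.8, round = TRUE))
  mech <- risk_mechanism(NA_real_, c(a = 0), specs)
  cfg <- cohort_config(n_patients = 5000, seed = 42,
                       target_prevalence_30 = 0.2,
                       target_prevalence_90 = 0.3)
  coh <- generate_cohort(cfg, mech)
  p30 <- realized_prevalence(coh, 30, cfg$date_range[2])
  # tolerance: 3 x combined SE of the realized binomial mean and the
  # calibration check-cohort noise (~0.005 each at these sizes)
  expect_lt(abs(p30 - 0.2), 0.02)
})

test_that("default cohort matches the 14.3% / 24.4% prevalence targets", {
  cfg <- cohort_config(n_patients = 5000, seed = 7)
  coh <- generate_cohort(cfg)
  p30 <- realized_prevalence(coh, 30, cfg$date_range[2])
  p90 <- realized_prevalence(coh, 90, cfg$date_range[2])
  expect_lt(abs(p30 - 0.143), 0.015)
  expect_lt(abs(p90 - 0.244), 0.020)
  # labels are consistent: a 30-day readmission is also a 90-day one
  ld <- assemble_design_matrix(coh, range_end = cfg$date_range[2])
  expect_true(all(ld$y30 <= ld$y90))
})

test_that("generation is deterministic in the seed", {
  cfg <- cohort_config(n_patients = 150, seed = 3)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  attr(c1, "mechanism") <- attr(c2, "mechanism") <- NULL
  attr(c1, "config") <- attr(c2, "config") <- NULL
  expect_identical(c1, c2)
  c3 <- generate_cohort(cohort_config(n_patients = 150, seed = 4))
  expect_false(identical(c1$admit_date, c3$admit_date))
})

test_that("adding patients never perturbs earlier patients' draws", {
  small <- generate_cohort(cohort_config(n_patients = 50, seed = 9),
                           calibrate = FALSE,
                           mechanism = local({
                             m <- default_mechanism()
                             m$intercept <- -2
                             m
                           }))
  big <- generate_cohort(cohort_config(n_patients = 80, seed = 9),
                         calibrate = FALSE,
                         mechanism = local({
                           m <- default_mechanism()
                           m$intercept <- -2
                           m
                         }))
  expect_identical(small$visit_id,
                   big$visit_id[big$patient_id %in% small$patient_id])
  expect_identical(small$age,
                   big$age[big$patient_id %in% small$patient_id])
})

test_that("larger interarrival scale lowers realized prevalence", {
  mech <- default_mechanism()
  mech$intercept <- -4  # fixed, so only the spacing differs
  p <- vapply(c(120, 600), function(s) {
    m <- mech; m$interarrival_scale <- s
    cfg <- cohort_config(n_patients = 3000, seed = 5)
    realized_prevalence(generate_cohort(cfg, m, calibrate = FALSE), 30,
                        cfg$date_range[2])
  }, 0)
  expect_gt(p[1], p[2])
})

test_that("true risk discriminates realized labels as designed", {
  specs <- list(charlson = list(type = "continuous", dist = "pois",
                                lambda = 1.5),
                los = list(type = "continuous", dist = "lognormal",
                           meanlog = 1.2, sdlog = 0.8, round = TRUE))
  cfg <- cohort_config(n_patients = 4000, seed = 8)

  # flat mechanism: the risk score carries no information, AUC ~ 0.5
  flat <- generate_cohort(cfg, risk_mechanism(NA_real_, c(charlson = 0),
                                              specs))
  ld <- assemble_design_matrix(flat, range_end = cfg$date_range[2])
  keep <- !ld$censored30
  r <- true_risk(attr(flat, "mechanism"),
                 as.data.frame(ld$X[keep, , drop = FALSE],
                               check.names = FALSE))
  expect_lt(abs(auc_roc(ld$y30[keep], r) - 0.5), 0.03)

  # strong single coefficient: the oracle risk separates labels well
  strong <- generate_cohort(cfg, risk_mechanism(NA_real_,
                                                c(charlson = 1.5), specs))
  ld2 <- assemble_design_matrix(strong, range_end = cfg$date_range[2])
  keep2 <- !ld2$censored30
  r2 <- true_risk(attr(strong, "mechanism"),
                  as.data.frame(ld2$X[keep2, , drop = FALSE],
                                check.names = FALSE))
  expect_gt(auc_roc(ld2$y30[keep2], r2), 0.75)
})

test_that("mechanism and config round-trip through YAML", {
  dir <- withr::local_tempdir()
  mech <- default_mechanism()
  mech$intercept <- -3.21
  f <- file.path(dir, "mech.yaml")
  write_mechanism(mech, f)
  back <- read_mechanism(f)
  expect_equal(back$intercept, mech$intercept)
  expect_equal(back$coefficients, mech$coefficients)
  expect_equal(back$feature_specs$specialty$levels,
               mech$feature_specs$specialty$levels)

  cfg <- cohort_config(n_patients = 123, seed = 9)
  g <- file.path(dir, "cfg.yaml")
  write_cohort_config(cfg, g)
  expect_equal(read_cohort_config(g), cfg)
})

test_that("cohort CSV round-trips with provenance header", {
  dir <- withr::local_tempdir()
  coh <- generate_cohort(cohort_config(n_patients = 40, seed = 2))
  f <- file.path(dir, "cohort.csv")
  write_cohort(coh, f)
  expect_match(readLines(f, n = 1), "^# extree cohort")
  back <- read_cohort(f)
  expect_equal(back$admit_date, coh$admit_date)
  expect_equal(back$age, coh$age)
  expect_equal(back$specialty, coh$specialty)
})
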