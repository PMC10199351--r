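test_that("covariate sets are nested and standardized exactly", {
  coh <- small_cohort(n = 400, seed = 14)
  sets <- default_covariate_sets()
  expect_true(all(sets$basic %in% sets$augmented))
  expect_true(all(sets$augmented %in% sets$full))
  d_full <- select_covariate_set(coh, "full")
  expect_equal(ncol(d_full$X), 58)
  d_basic <- select_covariate_set(coh, "basic")
  expect_true(all(colnames(d_basic$X) %in% colnames(d_full$X)))
  expect_lt(max(abs(colMeans(d_full$X))), 1e-12)
  expect_lt(max(abs(apply(d_full$X, 2, sd) - 1)), 1e-12)
  expect_error(select_covariate_set(coh, "nope"), "unknown covariate set")
  coh$age <- 1
  expect_error(select_covariate_set(coh, "full"), "age")
})

test_that("a null treatment effect yields near-zero interaction terms", {
  tr0 <- truth_parameters(effect_params = list(theta = 0))
  coh <- small_cohort(n = 6000, seed = 15, truth = tr0)
  fit <- fit_modified_model(coh, "full", "primary", fixed_penalty(), seed = 3)
  se <- sqrt(diag(fit$gvcov))
  # gamma0 (constant effect) and gamma1 (slope) both within ~2 SEs of 0
  expect_lt(abs(fit$gamma[["const"]]), 2.5 * se[grep("const", names(se))])
  expect_lt(abs(fit$gamma[["eta"]] * fit$calibration_slope),
            2.5 * se[grep("g_eta", names(se))])
})

test_that("estimated risk difference vanishes as the risk score collapses", {
  coh <- small_cohort(n = 2500, seed = 16)
  fit <- fit_modified_model(coh, "basic", "primary", fixed_penalty(),
                            seed = 3)
  etas <- seq(-4, -16, by = -1)  # below the observed score range
  rd <- risk_from_score(fit, etas, "intensive", 4.13) -
    risk_from_score(fit, etas, "standard", 4.13)
  expect_lt(abs(rd[length(rd)]), 1e-4)
  expect_true(all(diff(abs(rd)) <= 1e-12))
})

test_that("lowest-percentile subjects carry a negligible estimated difference", {
  coh <- simulate_cohort(cohort_config(seed = 57))  # full study size
  fit <- fit_modified_model(coh, "full", "primary", fixed_penalty(),
                            seed = 3)
  pr <- riskmag:::predict_cohort(fit, coh, 4.13)
  low <- pr$eta <= quantile(pr$eta, 0.01)
  expect_lt(max(abs(pr$rd[low])), 0.005)
})

test_that("risk predictions obey their limits on a hand-built fit", {
  fit <- toy_fit(g0 = -0.2, g1 = 0, h_rate = 0.05)
  # before the first baseline step, risk is 0
  expect_equal(risk_from_score(fit, 0, "standard", 0.005), 0)
  # risk score -> -inf: both arms -> 0
  expect_lt(risk_from_score(fit, -30, "intensive", 4.13), 1e-12)
  # monotone in eta for fixed arm
  r <- risk_from_score(fit, seq(-3, 3, 0.5), "standard", 4.13)
  expect_true(all(diff(r) > 0))
  # beyond follow-up: error
  expect_error(risk_from_score(fit, 0, "standard", 7), "exceeds")
  # g identically 0: no difference anywhere
  null_fit <- toy_fit(g0 = 0, g1 = 0)
  x <- data.frame(x = c(-1, 0, 2))
  expect_equal(estimated_risk_difference(null_fit, x, 4.13), rep(0, 3))
})

test_that("a benefit of -0.027 converts to 27 events prevented per 1000", {
  expect_equal(events_prevented_per_1000(-0.027), 27)
  expect_equal(events_prevented_per_1000(c(0, 0.01)), c(0, -10))
})

test_that("model-free average risk matches Kaplan-Meier on one arm", {
  # homogeneous data (no covariate signal): the fitted baseline reproduces
  # the marginal standard-arm risk
  tr <- flat_truth(rate = 0.055, theta = log(0.85))
  coh <- simulate_cohort(cohort_config(n_subjects = 10000, seed = 18), tr,
                         list(outcome_definition("primary", "amci")))
  fit <- suppressWarnings(
    fit_modified_model(coh, "basic", "primary",
                       penalty_spec(alpha = 1, lambda = 5), seed = 3))
  std <- coh$arm == "standard"
  km <- km_risk_at(kaplan_meier(coh$time_primary[std],
                                coh$event_primary[std]), 4.13)
  expect_lt(abs(risk_from_score(fit, 0, "standard", 4.13) - km$risk), 0.01)
})

test_that("fits serialize to text and predict identically after reload", {
  coh <- small_cohort(n = 1200, seed = 19)
  fit <- fit_modified_model(coh, "basic", "primary", fixed_penalty(),
                            seed = 3)
  path <- tempfile(fileext = ".json")
  write_fit(fit, path)
  fit2 <- read_fit(path)
  nd <- as.data.frame(coh)[1:50, ]
  expect_equal(absolute_risk(fit2, nd, "intensive", 4.13),
               absolute_risk(fit, nd, "intensive", 4.13), tolerance = 1e-12)
  expect_equal(estimated_risk_difference(fit2, nd, 4.13),
               estimated_risk_difference(fit, nd, 4.13), tolerance = 1e-12)
})

test_that("refusing degenerate inputs: missing outcome, one arm, few events", {
  coh <- small_cohort(n = 300, seed = 20)
  expect_error(fit_modified_model(coh, "basic", "nonexistent"),
               "outcome not found")
  one_arm <- coh[coh$arm == "standard", ]
  attr(one_arm, "covariate_names") <- attr(coh, "covariate_names")
  expect_error(fit_modified_model(one_arm, "basic", "primary"),
               "both treatment arms")
  few <- coh
  few$event_primary[-(1:5)] <- 0
  expect_error(fit_modified_model(few, "basic", "primary"),
               "at least 30 events")
})
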