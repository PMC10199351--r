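test_that("covariate marginals match their specifications", {
  cfg <- cohort_config(n_subjects = 1e5, seed = 1)
  g <- generate_covariates(cfg)
  x <- g$covariates
  expect_equal(mean(x[, "female"]), 0.351, tolerance = 0.01 / 0.351)
  expect_lt(abs(mean(x[, "female"]) - 0.351), 0.01)
  expect_lt(abs(mean(x[, "age"]) - 67.9), 0.1)
  expect_lt(abs(sd(x[, "age"]) - 9.3), 0.1)
  expect_lt(abs(mean(x[, "medicare"]) - 0.551), 0.01)
  # independence under the identity copula
  expect_lt(abs(cor(x[, "female"], x[, "black"])), 3 / sqrt(nrow(x)))
})

test_that("covariate generation is deterministic given the seed", {
  cfg <- cohort_config(n_subjects = 500, seed = 9)
  g1 <- generate_covariates(cfg)
  g2 <- generate_covariates(cfg)
  expect_identical(g1$covariates, g2$covariates)
  expect_identical(g1$arm, g2$arm)
  g3 <- generate_covariates(cohort_config(n_subjects = 500, seed = 10))
  expect_false(identical(g1$covariates, g3$covariates))
})

test_that("arm assignment is randomized independently of covariates", {
  cfg <- cohort_config(n_subjects = 20000, seed = 3)
  g <- generate_covariates(cfg)
  z <- g$arm == "intensive"
  p_bin <- chisq.test(table(g$covariates[, "female"], z))$p.value
  p_con <- t.test(g$covariates[, "age"] ~ z)$p.value
  expect_gt(p_bin, 1e-3)
  expect_gt(p_con, 1e-3)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_subjects = 1), "at least 2")
  specs <- default_covariate_specs()
  bad_cor <- diag(nrow(specs)); bad_cor[1, 2] <- 0.9  # asymmetric
  expect_error(cohort_config(correlation = bad_cor), "symmetric")
  npsd <- diag(nrow(specs))
  npsd[1, 2] <- npsd[2, 1] <- 1.5  # eigenvalue < 0
  expect_error(cohort_config(correlation = npsd), "positive semi-definite")
  specs$prevalence[specs$name == "female"] <- 1.2
  expect_error(cohort_config(covariate_specs = specs), "prevalence")
})

test_that("outcomes follow the closed-form risk with no heterogeneity", {
  # beta = 0, theta = 0, single component: 4.13-year risk = 1 - exp(-4.13 l)
  tr <- flat_truth(rate = 0.05)
  cfg <- cohort_config(n_subjects = 50000, seed = 5)
  g <- generate_covariates(cfg)
  coh <- generate_outcomes(g$covariates, g$arm, tr,
                           list(outcome_definition("primary", "amci")),
                           seed = 6)
  expect_true(all(coh$truth_eta == 0))
  km <- km_risk_at(kaplan_meier(coh$time_primary, coh$event_primary), 4.13)
  expect_lt(abs(km$risk - (1 - exp(-0.05 * 4.13))), 0.005)
})

test_that("composites over more components fail earlier and more often", {
  coh <- small_cohort(n = 4000, seed = 8)
  expect_true(all(coh$time_cognitive_or_death <= coh$time_primary + 1e-12))
  expect_gte(mean(coh$event_cognitive_or_death), mean(coh$event_primary))
  # event times agree with the wider composite whenever the narrow one fires
  fired <- coh$event_primary == 1
  expect_true(all(coh$time_cognitive_or_death[fired] <=
                    coh$time_primary[fired]))
})

test_that("a constant generative hazard ratio is recovered by Cox regression", {
  cfg <- cohort_config(n_subjects = 40000, seed = 13)
  coh <- simulate_cohort(cfg)  # default truth: constant HR 0.85
  z <- as.numeric(coh$arm == "intensive")
  f <- survival::coxph(survival::Surv(coh$time_primary, coh$event_primary) ~
                         z + offset(coh$truth_eta))
  expect_lt(abs(exp(coef(f)) - 0.85), 0.03)
})

test_that("primary-outcome event fractions emulate the trial's printed counts", {
  cfg <- cohort_config(n_subjects = 40000, seed = 17)
  coh <- simulate_cohort(cfg)
  int <- coh$arm == "intensive"
  expect_lt(abs(mean(coh$event_primary[int]) - 765 / 3989), 0.015)
  expect_lt(abs(mean(coh$event_primary[!int]) - 828 / 3929), 0.015)
})

test_that("eligibility filter tallies exclusions per reason", {
  # no flagged subjects: nothing removed
  coh <- small_cohort(n = 300, seed = 2)
  f0 <- apply_eligibility_filter(coh)
  expect_equal(f0$n_analytic, 300)
  expect_equal(f0$n_no_followup + f0$n_missing_covariates, 0)

  # one missing covariate among complete others: exactly that subject removed
  coh2 <- coh
  coh2$age[7] <- NA
  f1 <- apply_eligibility_filter(coh2)
  expect_equal(f1$n_missing_covariates, 1)
  expect_false(7 %in% f1$cohort$id)
  expect_equal(f1$n_analytic, 299)
})

test_that("no-follow-up exclusion fraction matches the emulated flow", {
  # 9631 randomized with 6.7% lacking follow-up assessments
  cfg <- cohort_config(n_subjects = 9631, no_followup_rate = 643 / 9631,
                       seed = 4)
  coh <- simulate_cohort(cfg)
  filt <- apply_eligibility_filter(coh)
  expect_equal(filt$n_no_followup, 9631 - sum(coh$has_followup))
  expect_lt(abs(filt$pct_excluded - 6.7), 1.0)
  # the exact printed instance: 643 of 9631 is 6.7%
  coh$has_followup <- rep(1L, 9631)
  coh$has_followup[seq_len(643)] <- 0L
  filt2 <- apply_eligibility_filter(coh)
  expect_equal(filt2$n_no_followup, 643)
  expect_equal(round(filt2$pct_excluded, 1), 6.7)
})

test_that("risk oracles obey limits and closed forms", {
  tr <- flat_truth(rate = 0.05)
  # risk tends to 0 with the horizon
  expect_equal(oracle_absolute_risk(tr, 0, "standard", 0), 0)
  expect_lt(oracle_absolute_risk(tr, 0, "standard", 1e-9), 1e-8)
  # closed form at total hazard 0.05/y, t = 4.13
  expect_equal(oracle_absolute_risk(tr, 0, "standard", 4.13),
               1 - exp(-0.2065))
  # nondecreasing in t
  ts <- seq(0.1, 10, by = 0.1)
  expect_true(all(diff(oracle_absolute_risk(tr, 0.3, "standard", ts)) >= 0))
})

test_that("oracle risk difference obeys the survival-power identity and limits", {
  # theta = 0: no difference anywhere
  tr0 <- flat_truth(rate = 0.05, theta = 0)
  expect_equal(oracle_risk_difference(tr0, c(-2, 0, 2), 4.13), rep(0, 3))
  # constant HR: RD = (1 - (1 - r)^h) - r
  th <- log(0.85)
  tr <- flat_truth(rate = 0.05, theta = th)
  r_std <- oracle_absolute_risk(tr, 0.7, "standard", 4.13)
  expect_equal(oracle_risk_difference(tr, 0.7, 4.13),
               (1 - (1 - r_std)^exp(th)) - r_std)
  # zero-risk limit
  expect_lt(abs(oracle_risk_difference(tr, -10, 4.13)), 1e-3)
})

test_that("empirical Kaplan-Meier risk agrees with the oracle at large n", {
  tr <- truth_parameters()
  cfg <- cohort_config(n_subjects = 1e5, seed = 23)
  coh <- simulate_cohort(cfg)
  std <- coh$arm == "standard"
  km <- km_risk_at(kaplan_meier(coh$time_primary[std],
                                coh$event_primary[std]), 4.13)
  oracle <- mean(oracle_absolute_risk(tr, coh$truth_eta[std], "standard",
                                      4.13))
  expect_lt(abs(km$risk - oracle), 3 * sqrt(km$variance) + 0.003)
})
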