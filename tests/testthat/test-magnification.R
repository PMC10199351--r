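test_that("direct-magnification reference obeys its identities", {
  grid <- seq(0, 0.95, by = 0.05)
  # unit hazard ratio: no difference anywhere
  expect_equal(direct_magnification_reference(1, grid), rep(0, length(grid)))
  # passes through the origin
  expect_equal(direct_magnification_reference(0.85, 0), 0)
  # small-risk limit: RD / r -> h - 1
  r <- 1e-6
  expect_equal(direct_magnification_reference(0.85, r) / r, 0.85 - 1,
               tolerance = 1e-4)
  # closed form at h = 0.85, r = 0.2
  expect_equal(direct_magnification_reference(0.85, 0.2),
               (1 - 0.8^0.85) - 0.2)
  # negative on (0,1) iff protective, with an interior maximum of |RD|
  rd <- direct_magnification_reference(0.85, grid)
  expect_true(all(rd[grid > 0] < 0))
  expect_true(which.min(rd) > 1 && which.min(rd) < length(grid))
  expect_true(all(direct_magnification_reference(1.2, grid[-1]) > 0))
  expect_error(direct_magnification_reference(0.85, 1), "\\[0, 1\\)")
  expect_error(direct_magnification_reference(0, grid), "> 0")
})

test_that("the reference matches a two-arm exponential simulation", {
  h <- 0.85; r <- 0.2; tstar <- 1
  lam_std <- -log(1 - r) / tstar
  set.seed(43)
  n <- 1e5
  risk_std <- mean(rexp(n, lam_std) <= tstar)
  risk_int <- mean(rexp(n, h * lam_std) <= tstar)
  expect_lt(abs((risk_int - risk_std) -
                  direct_magnification_reference(h, r)), 0.005)
})

test_that("tertile table bookkeeping is exact", {
  coh <- small_cohort(n = 2400, seed = 44)
  fit <- fit_modified_model(coh, "basic", "primary", fixed_penalty(),
                            seed = 3)
  tb <- tertile_benefit_table(fit, coh, 4.13)
  expect_equal(nrow(tb), 3)
  expect_equal(tb$tertile, c("High", "Medium", "Low"))
  expect_equal(sum(tb$n_intensive), sum(coh$arm == "intensive"))
  expect_equal(sum(tb$n_standard), sum(coh$arm == "standard"))
  # tertile sizes differ by <= 1
  sizes <- tb$n_intensive + tb$n_standard
  expect_lte(diff(range(sizes)), 1)
  # columns satisfy the report arithmetic identities
  expect_equal(tb$pct_intensive,
               round(100 * tb$events_intensive / tb$n_intensive, 1))
  expect_equal(tb$estimated_minus_observed,
               tb$estimated_rd_median - tb$observed_rd)
  # high-benefit tertile holds the most negative estimated differences
  expect_lt(tb$rd_max[1], tb$rd_min[3] + 1e-12)
})

test_that("a null-effect fit yields a flat curve with a band covering zero", {
  fit <- toy_fit(g0 = 0, g1 = 0, h_rate = 0.06)
  set.seed(45)
  n <- 800
  x <- rnorm(n)
  d <- sim_exp(n, rate = 0.06, lp = x, seed = 46)
  coh <- data.frame(id = 1:n,
                    arm = factor(sample(c("standard", "intensive"), n, TRUE),
                                 levels = c("standard", "intensive")),
                    has_followup = 1, time_primary = d$time,
                    event_primary = d$event, x = x)
  attr(coh, "covariate_names") <- "x"
  class(coh) <- c("cohort", "data.frame")
  mc <- magnification_curve(fit, coh, 4, n_boot = 30, seed = 5)
  expect_true(all(abs(mc$curve$estimated_rd) < 1e-12, na.rm = TRUE))
  expect_true(all(mc$curve$lower <= 0 & mc$curve$upper >= 0, na.rm = TRUE))
  # same seed, same replicate count: identical band
  mc2 <- magnification_curve(fit, coh, 4, n_boot = 30, seed = 5)
  expect_identical(mc$curve, mc2$curve)
})

test_that("under constant-HR truth the curve tracks the reference in band", {
  coh <- small_cohort(n = 6000, seed = 47)
  fit <- fit_modified_model(coh, "full", "primary", fixed_penalty(),
                            seed = 3)
  mc <- magnification_curve(fit, coh, 4.13, n_boot = 60, seed = 9)
  # compare where the data live: central 80% of baseline risk
  qs <- quantile(mc$histogram, c(0.1, 0.9))
  sel <- mc$curve$baseline_risk >= qs[1] & mc$curve$baseline_risk <= qs[2] &
    !is.na(mc$curve$estimated_rd)
  inside <- mc$reference$rd[sel] >= mc$curve$lower[sel] - 0.01 &
    mc$reference$rd[sel] <= mc$curve$upper[sel] + 0.01
  expect_gt(mean(inside), 0.8)
})

test_that("the linearity test is exact under exactly-zero spline terms", {
  fit <- toy_fit()
  fit$interaction_basis <- "spline"
  fit$gamma <- c(const = -0.2, eta = 0.1, spline1 = 0)
  fit$knots <- c(-1, 0, 1)
  out <- linearity_test(fit)
  expect_equal(out$chi2, 0)
  expect_equal(out$p, 1)
  fit$interaction_basis <- "linear"
  fit$gamma <- c(const = -0.2, eta = 0.1, spline1 = NA_real_)
  expect_error(linearity_test(fit), "nothing to test")
})

test_that("linearity p-values are well calibrated under linear truth", {
  # scaled type-I experiment: linear-in-eta effect, spline term tested
  tr <- truth_parameters(effect_kind = "linear_in_risk",
                         effect_params = list(intercept = log(0.85),
                                              slope = -0.2))
  rej <- 0; nrep <- 40
  for (r in seq_len(nrep)) {
    coh <- small_cohort(n = 2000, seed = 500 + r, truth = tr)
    fit <- fit_modified_model(coh, "basic", "primary", fixed_penalty(),
                              seed = 3)
    p <- linearity_test(fit)$p
    rej <- rej + (p < 0.05)
  }
  expect_lte(rej / nrep, 0.15)
})

test_that("hybrid subgroup interactions never change the analytic sample", {
  coh <- small_cohort(n = 2000, seed = 48)
  hy <- hybrid_effect_model(coh, "basic", "primary", fixed_penalty(),
                            seed = 3)
  expect_equal(hy$n, nrow(coh))
  expect_equal(hy$n_events, sum(coh$event_primary))
  expect_equal(hy$base_fit$n, hy$hybrid_fit$n)
  expect_equal(hy$base_fit$n_events, hy$hybrid_fit$n_events)
  expect_length(hy$subgroup_coefficients, 5)
  expect_true(is.finite(hy$c_difference))
})

test_that("single-level subgroups are dropped with a warning", {
  coh <- small_cohort(n = 1500, seed = 49)
  coh$baseline_mci <- 0  # degenerate subgroup
  expect_warning(
    hy <- hybrid_effect_model(coh, "basic", "primary", fixed_penalty(),
                              seed = 3),
    "single-level")
  expect_false("baseline_mci" %in% names(hy$subgroup_coefficients))
})
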