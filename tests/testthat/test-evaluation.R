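test_that("concordance matches brute-force pair enumeration", {
  brute_c <- function(scores, time, event) {
    num <- den <- 0
    n <- length(time)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (time[i] < time[j] && event[i] == 1) {
          den <- den + 1
          if (scores[i] > scores[j]) num <- num + 1
          else if (scores[i] == scores[j]) num <- num + 0.5
        }
      }
    }
    num / den
  }
  # 4 subjects, all events: 6 comparable pairs, enumerable by hand
  sc <- c(3, 1, 4, 2); tm <- c(1, 2, 3, 4); ev <- rep(1, 4)
  expect_equal(harrell_c(sc, tm, ev), brute_c(sc, tm, ev))
  # larger case with censoring and score ties
  set.seed(26)
  n <- 120
  sc2 <- sample(1:8, n, replace = TRUE)
  d <- sim_exp(n, rate = 0.2, lp = 0.3 * sc2, seed = 27)
  expect_equal(harrell_c(sc2, d$time, d$event),
               brute_c(sc2, d$time, d$event))
})

test_that("perfect ranking gives C = 1; monotone transforms leave C fixed", {
  set.seed(28)
  tt <- sort(rexp(50, 0.1))
  expect_equal(harrell_c(-tt, tt, rep(1, 50)), 1)
  d <- sim_cox_data(n = 100, p = 1, beta = 0.8, seed = 29)
  s <- drop(d$X)
  c1 <- harrell_c(s, d$time, d$event)
  expect_equal(harrell_c(exp(3 * s), d$time, d$event), c1)
  expect_equal(harrell_c(rank(s), d$time, d$event), c1)
})

test_that("decile grouping partitions the cohort with near-equal sizes", {
  set.seed(30)
  risks <- runif(1037)
  d <- sim_exp(1037, rate = 0.1, seed = 31)
  rep_ <- decile_calibration(risks, d$time, d$event, 4)
  expect_equal(sum(rep_$groups$n), 1037)
  expect_lte(diff(range(rep_$groups$n)), 1)
  expect_true(all(diff(rep_$groups$mean_estimated) > 0))
  # assignment covers every subject exactly once
  expect_equal(sort(unique(rep_$assignment)), 1:10)
  expect_equal(tabulate(rep_$assignment), rep_$groups$n)
})

test_that("homogeneous risk is calibrated within Greenwood error", {
  # constant true risk 0.2 at t*; estimated risk set to the same constant
  lam <- -log(1 - 0.2) / 4
  d <- sim_exp(20000, rate = lam, seed = 32)
  rep_ <- decile_calibration(rep(0.2, 20000), d$time, d$event, 4)
  dev <- abs(rep_$groups$observed - rep_$groups$mean_estimated)
  expect_true(all(dev <= 3 * sqrt(rep_$groups$greenwood_var)))
  expect_lt(rep_$mae, 0.02)
})

test_that("the calibration chi-square is zero when observed equals estimated", {
  d <- sim_exp(4000, rate = 0.08, seed = 33)
  set.seed(34)
  est <- runif(4000, 0.1, 0.5)
  rep_ <- decile_calibration(est, d$time, d$event, 4)
  # force exact agreement group by group, then the statistic must vanish
  for (g in 1:10) {
    rep_$data$estimated[rep_$assignment == g] <- rep_$groups$observed[g]
  }
  out <- gnd_test(rep_)
  expect_equal(out$gnd_chi2, 0, tolerance = 1e-12)
  expect_equal(out$gnd_p, 1)
  expect_equal(out$gnd_df, nrow(out$gnd_groups) - 1)
})

test_that("low-event groups are merged before testing, never left under 5", {
  set.seed(35)
  n <- 600
  # strong risk gradient: bottom deciles have almost no events by t*
  x <- sort(rnorm(n))
  d <- sim_exp(n, rate = 0.02, lp = 2 * x, seed = 36)
  est <- 1 - exp(-0.02 * exp(2 * x) * 4)
  out <- gnd_test(decile_calibration(est, d$time, d$event, 4))
  expect_true(all(out$gnd_groups$events >= 5))
  expect_equal(out$gnd_df, nrow(out$gnd_groups) - 1)
  expect_lt(nrow(out$gnd_groups), 10)
})

test_that("gross miscalibration is detected", {
  d <- sim_exp(8000, rate = 0.06, seed = 37)
  true_risk <- 1 - exp(-0.06 * 4)
  est <- rep(true_risk, 8000) + 0.10  # shifted by +0.10 in every decile
  set.seed(38)
  est <- est + runif(8000, -0.01, 0.01)  # break ties for grouping
  out <- gnd_test(decile_calibration(est, d$time, d$event, 4))
  expect_lt(out$gnd_p, 0.05)
})

test_that("standardized hazard ratios are scale-invariant and recover truth", {
  set.seed(39)
  n <- 10000
  x <- rnorm(n, sd = 2.5)
  b <- 0.3
  d <- sim_exp(n, rate = 0.05, lp = b * x, seed = 40)
  h1 <- standardized_univariate_hr(x, d$time, d$event)
  h2 <- standardized_univariate_hr(x * 37.2, d$time, d$event)
  expect_equal(h1$hr, h2$hr, tolerance = 1e-10)
  # HR per 1 SD ~ exp(b * sd(x))
  expect_lt(abs(h1$hr - exp(b * sd(x))), 0.08)
  expect_error(standardized_univariate_hr(rep(1, 50), d$time[1:50],
                                          d$event[1:50]), "zero variance")
})

test_that("a covariate unrelated to outcome has HR near 1 with covering CI", {
  set.seed(41)
  d <- sim_exp(10000, rate = 0.05, seed = 42)
  h <- standardized_univariate_hr(rnorm(10000), d$time, d$event)
  expect_gt(h$hr, 0.95)
  expect_lt(h$hr, 1.05)
  expect_true(h$ci[1] < 1 && h$ci[2] > 1)
})
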