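#' Tertile-of-estimated-benefit validation table
#'
#' Splits the cohort into tertiles of the model-estimated between-arm risk
#' difference (most negative = highest estimated benefit) and compares, per
#' tertile, the median estimated risk difference with the observed
#' Kaplan-Meier risk difference at `t_star` and its confidence interval.
#'
#' @param fit A `modified_cox_fit`.
#' @param cohort The analysis cohort.
#' @param t_star Horizon in years.
#' @return A `tertile_benefit_table` data frame, one row per tertile (High,
#'   Medium, Low benefit): estimated-RD range, n and events (with
#'   percentages) per arm, median estimated RD, observed RD with 95% CI, and
#'   estimated minus observed.
#' @export
tertile_benefit_table <- function(fit, cohort, t_star) {
  pr <- predict_cohort(fit, cohort, t_star)
  grp <- risk_groups(pr$rd, 3)  # 1 = most negative RD = highest benefit
  tm <- cohort[[paste0("time_", fit$outcome)]]
  ev <- cohort[[paste0("event_", fit$outcome)]]
  label <- c("High", "Medium", "Low")
  rows <- lapply(1:3, function(g) {
    sel <- grp == g
    int <- sel & cohort$arm == "intensive"
    std <- sel & cohort$arm == "standard"
    if (!sum(int) || !sum(std))
      stop("tertile ", label[g], " lacks one treatment arm")
    obs <- km_group_risk_difference(tm[sel], ev[sel], cohort$arm[sel], t_star)
    est <- stats::median(pr$rd[sel])
    data.frame(tertile = label[g],
               rd_min = min(pr$rd[sel]), rd_max = max(pr$rd[sel]),
               n_intensive = sum(int), n_standard = sum(std),
               events_intensive = sum(ev[int]),
               events_standard = sum(ev[std]),
               pct_intensive = round(100 * sum(ev[int]) / sum(int), 1),
               pct_standard = round(100 * sum(ev[std]) / sum(std), 1),
               estimated_rd_median = est,
               observed_rd = obs$rd,
               observed_ci_low = obs$ci[1], observed_ci_high = obs$ci[2],
               estimated_minus_observed = est - obs$rd)
  })
  structure(do.call(rbind, rows),
            class = c("tertile_benefit_table", "data.frame"))
}

#' @export
print.tertile_benefit_table <- function(x, ...) {
  cat("Observed and estimated risk differences by tertile of estimated benefit\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-6s (%.4f to %.4f): n %d/%d, events %d (%.1f%%) / %d (%.1f%%)\n",
                x$tertile[i], x$rd_min[i], x$rd_max[i],
                x$n_intensive[i], x$n_standard[i],
                x$events_intensive[i], x$pct_intensive[i],
                x$events_standard[i], x$pct_standard[i]))
    cat(sprintf("         estimated (median) %.3f, observed %.3f (%.3f to %.3f), est - obs %.3f\n",
                x$estimated_rd_median[i], x$observed_rd[i],
                x$observed_ci_low[i], x$observed_ci_high[i],
                x$estimated_minus_observed[i]))
  }
  invisible(x)
}

#' Risk-difference reference under direct risk magnification
#'
#' Under a constant treatment hazard ratio `h`, a standard-arm risk `r`
#' transforms to `1 - (1 - r)^h` in the treated arm (the survival-power
#' identity of proportional hazards), giving the reference risk difference
#' `RD(r) = (1 - (1 - r)^h) - r`. The curve passes through (0, 0) with slope
#' `h - 1` at the origin, the small-risk limit in which the absolute risk
#' reduction is directly proportional to baseline risk.
#'
#' @param overall_hr Overall treatment hazard ratio (> 0), e.g. from a
#'   treatment-main-effect-only Cox model.
#' @param grid Baseline (standard-arm) risks in \[0, 1).
#' @return Reference risk differences along `grid`.
#' @export
direct_magnification_reference <- function(overall_hr, grid) {
  if (overall_hr <= 0) stop("overall_hr must be > 0")
  if (any(grid < 0 | grid >= 1)) stop("baseline risks must lie in [0, 1)")
  (1 - (1 - grid)^overall_hr) - grid
}

#' Risk-magnification curve with bootstrap band
#'
#' Summarizes how the model-estimated absolute risk difference varies with
#' estimated baseline (standard-arm) risk: a Gaussian-kernel local mean of
#' subject-level (baseline risk, risk difference) pairs over a grid, a
#' percentile bootstrap band from resampling subjects, a constant-hazard-
#' ratio reference curve anchored at the overall treatment hazard ratio, and
#' an overlay of observed Kaplan-Meier risk differences within quartiles of
#' estimated risk difference.
#'
#' @param fit A `modified_cox_fit`.
#' @param cohort The analysis cohort.
#' @param t_star Horizon in years.
#' @param grid Baseline-risk grid (default: 50 points spanning the 1st-99th
#'   percentiles of estimated baseline risk).
#' @param n_boot Bootstrap replicates for the band (default 200).
#' @param seed Seed for the bootstrap.
#' @param bandwidth Kernel bandwidth (default 0.25 x SD of baseline risk).
#' @param conf_level Band level (default 0.95).
#' @return A `magnification_curve` object: `curve` (grid, estimated RD,
#'   band), `reference` (constant-HR RD), `overall_hr`, `quartiles`
#'   (observed RD with CI within quartiles of estimated RD), `linearity_p`
#'   (when the fit carries spline interaction terms), `histogram` data.
#' @export
magnification_curve <- function(fit, cohort, t_star, grid = NULL,
                                n_boot = 200, seed = 1L, bandwidth = NULL,
                                conf_level = 0.95) {
  stopifnot(n_boot >= 1)
  pr <- predict_cohort(fit, cohort, t_star)
  r0 <- pr$risk_standard
  rd <- pr$rd
  if (is.null(grid))
    grid <- seq(stats::quantile(r0, 0.01), stats::quantile(r0, 0.99),
                length.out = 50)
  if (is.null(bandwidth)) bandwidth <- 0.25 * stats::sd(r0)
  ksmooth_mean <- function(x, y) {
    vapply(grid, function(g) {
      k <- stats::dnorm((x - g) / bandwidth)
      near <- abs(x - g) <= 2 * bandwidth
      if (!any(near)) return(NA_real_)  # empty neighborhood: flagged absent
      sum(k * y) / sum(k)
    }, 0)
  }
  est <- ksmooth_mean(r0, rd)
  set.seed(seed)
  n <- length(rd)
  boot <- matrix(NA_real_, n_boot, length(grid))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    boot[b, ] <- ksmooth_mean(r0[idx], rd[idx])
  }
  a <- (1 - conf_level) / 2
  lower <- apply(boot, 2, stats::quantile, probs = a, na.rm = TRUE)
  upper <- apply(boot, 2, stats::quantile, probs = 1 - a, na.rm = TRUE)
  lower <- pmin(lower, est, na.rm = FALSE)
  upper <- pmax(upper, est, na.rm = FALSE)
  tm <- cohort[[paste0("time_", fit$outcome)]]
  ev <- cohort[[paste0("event_", fit$outcome)]]
  ohr <- exp(unname(stats::coef(survival::coxph(
    survival::Surv(tm, ev) ~ I(as.numeric(cohort$arm == "intensive")),
    ties = "efron"))))
  qgrp <- risk_groups(rd, 4)
  quart <- do.call(rbind, lapply(1:4, function(g) {
    sel <- qgrp == g
    obs <- km_group_risk_difference(tm[sel], ev[sel], cohort$arm[sel], t_star)
    data.frame(quartile = g, mean_baseline_risk = mean(r0[sel]),
               mean_estimated_rd = mean(rd[sel]), observed_rd = obs$rd,
               ci_low = obs$ci[1], ci_high = obs$ci[2])
  }))
  lin_p <- if (fit$interaction_basis == "spline" && !is.null(fit$gvcov))
    tryCatch(linearity_test(fit)$p, error = function(e) NA_real_)
  else NA_real_
  structure(list(curve = data.frame(baseline_risk = grid, estimated_rd = est,
                                    lower = lower, upper = upper),
                 reference = data.frame(
                   baseline_risk = grid,
                   rd = direct_magnification_reference(ohr, grid)),
                 overall_hr = ohr, quartiles = quart,
                 linearity_p = lin_p, bandwidth = bandwidth,
                 n_boot = n_boot, t_star = t_star,
                 histogram = r0),
            class = "magnification_curve")
}

#' @export
print.magnification_curve <- function(x, ...) {
  cat("Risk-magnification curve at t* =", x$t_star, "years\n")
  cat("  overall treatment HR:", signif(x$overall_hr, 3),
      "  bootstrap replicates:", x$n_boot, "\n")
  if (!is.na(x$linearity_p))
    cat(sprintf("  linearity P = %.3g\n", x$linearity_p))
  cat("  estimated RD range on grid:",
      paste(signif(range(x$curve$estimated_rd, na.rm = TRUE), 3),
            collapse = " to "), "\n")
  invisible(x)
}

#' Wald test of linearity of the treatment-interaction function
#'
#' Joint Wald chi-square test that all nonlinear (spline) coefficients of
#' `g(eta)` are zero; degrees of freedom equal the number of spline terms. A
#' large P value is consistent with the absolute benefit varying linearly in
#' the risk score on the log-hazard scale.
#'
#' @param fit A `modified_cox_fit` with spline interaction terms.
#' @return A list with `chi2`, `df`, `p`.
#' @export
linearity_test <- function(fit) {
  if (fit$interaction_basis != "spline" || is.na(fit$gamma["spline1"]))
    stop("nothing to test: fit has no spline interaction terms")
  g <- fit$gamma[["spline1"]]
  if (g == 0 || is.null(fit$gvcov))
    return(list(chi2 = 0, df = 1L, p = 1))
  vi <- grep("spline", colnames(fit$gvcov))
  if (!length(vi)) vi <- 3
  v <- fit$gvcov[vi[1], vi[1]]
  chi2 <- g^2 / v
  list(chi2 = chi2, df = 1L,
       p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

#' Hybrid risk-plus-effect model with prespecified subgroup interactions
#'
#' Refits the modified model adding treatment interactions with prespecified
#' subgroups -- by default age >= 75 years, female sex, Black race, baseline
#' MCI and baseline CVD -- and compares discrimination (Harrell's C on the
#' full linear predictor) between the risk-only and hybrid models.
#'
#' @param cohort The analysis cohort.
#' @param covariate_set Covariate-set name.
#' @param outcome Outcome name.
#' @param penalty A [penalty_spec()].
#' @param subgroups Named list mapping subgroup labels to functions of the
#'   cohort returning 0/1 indicators; `NULL` uses the defaults above.
#' @param ... Passed to [fit_modified_model()].
#' @return A list with `base_fit`, `hybrid_fit`, `c_base`, `c_hybrid`,
#'   `c_difference`, `subgroup_coefficients`.
#' @export
hybrid_effect_model <- function(cohort, covariate_set = "full",
                                outcome = "primary",
                                penalty = penalty_spec(),
                                subgroups = NULL, ...) {
  if (is.null(subgroups)) {
    subgroups <- list(
      age_ge_75 = function(d) as.numeric(d$age >= 75),
      female = function(d) as.numeric(d$female == 1),
      black = function(d) as.numeric(d$black == 1),
      baseline_mci = function(d) as.numeric(d$baseline_mci == 1),
      baseline_cvd = function(d) as.numeric(d$cvd_history == 1))
    subgroups <- subgroups[vapply(names(subgroups), function(nm) {
      col <- sub("age_ge_75", "age", sub("baseline_cvd", "cvd_history", nm))
      col %in% names(cohort)
    }, TRUE)]
  }
  S <- vapply(subgroups, function(f) f(cohort), numeric(nrow(cohort)))
  colnames(S) <- names(subgroups)
  base <- fit_modified_model(cohort, covariate_set, outcome, penalty, ...)
  hybrid <- fit_modified_model(cohort, covariate_set, outcome, penalty,
                               effect_modifiers = S, ...)
  tm <- cohort[[paste0("time_", outcome)]]
  ev <- cohort[[paste0("event_", outcome)]]
  z <- as.numeric(cohort$arm == "intensive")
  lp_base <- base$eta + z * g_of_eta(base, base$eta)
  Sk <- S[, names(hybrid$delta), drop = FALSE]
  lp_hyb <- hybrid$eta + z * g_of_eta(hybrid, hybrid$eta, Sk)
  c_base <- harrell_c(lp_base, tm, ev)
  c_hyb <- harrell_c(lp_hyb, tm, ev)
  list(base_fit = base, hybrid_fit = hybrid,
       c_base = c_base, c_hybrid = c_hyb,
       c_difference = c_hyb - c_base,
       subgroup_coefficients = hybrid$delta,
       n = nrow(cohort), n_events = sum(ev))
}
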