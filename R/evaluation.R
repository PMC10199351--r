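#' Harrell's concordance statistic for censored data
#'
#' Fraction of comparable subject pairs (the earlier time is an event) in
#' which the subject failing earlier has the higher risk score; score ties
#' count one half. 0.5 is random concordance, 1 perfect ranking. Computed via
#' `survival::concordance`.
#'
#' @param scores Risk scores (higher = higher predicted risk).
#' @param time Follow-up times.
#' @param event Event indicators in \{0, 1\}.
#' @return Concordance in \[0, 1\].
#' @export
harrell_c <- function(scores, time, event) {
  stopifnot(length(scores) == length(time), length(event) == length(time))
  cf <- survival::concordance(survival::Surv(time, event) ~ scores,
                              reverse = TRUE)
  counts <- cf$count
  if (sum(counts[c("concordant", "discordant", "tied.x")]) == 0)
    stop("no comparable pairs")
  unname(cf$concordance)
}

# Stable near-equal-size grouping by ascending value: group sizes differ by
# at most 1 and ties are broken by original subject order.
risk_groups <- function(values, g) {
  n <- length(values)
  if (n < g) stop("fewer subjects than groups")
  o <- order(values)  # stable in R: ties keep original order
  grp <- integer(n)
  sizes <- rep(n %/% g, g) + c(rep(1, n %% g), rep(0, g - n %% g))
  grp[o] <- rep(seq_len(g), sizes)
  grp
}

#' Decile calibration of estimated fixed-time risks
#'
#' Splits the cohort into deciles of estimated risk (pooled across arms,
#' stable ties), estimates the observed risk at `t_star` in each decile by
#' Kaplan-Meier with Greenwood variance, and summarizes calibration by the
#' mean absolute error between observed and mean estimated risks across the
#' deciles.
#'
#' @param estimated_risks One estimated risk per subject.
#' @param time Follow-up times.
#' @param event Event indicators in \{0, 1\}.
#' @param t_star Horizon in years.
#' @param groups Number of risk groups (default 10).
#' @return A `calibration_report`: data frame `groups` (per decile: `n`,
#'   `events` by `t_star`, `mean_estimated`, `observed`, `greenwood_var`),
#'   plus `mae` and `t_star`.
#' @export
decile_calibration <- function(estimated_risks, time, event, t_star,
                               groups = 10) {
  n <- length(estimated_risks)
  stopifnot(length(time) == n, length(event) == n)
  grp <- risk_groups(estimated_risks, groups)
  rows <- lapply(seq_len(groups), function(g) {
    sel <- grp == g
    if (!sum(sel)) stop("empty risk group ", g)
    kr <- km_risk_at(kaplan_meier(time[sel], event[sel]), t_star)
    data.frame(group = g, n = sum(sel),
               events = sum(event[sel] == 1 & time[sel] <= t_star),
               mean_estimated = mean(estimated_risks[sel]),
               observed = kr$risk, greenwood_var = kr$variance)
  })
  tab <- do.call(rbind, rows)
  structure(list(groups = tab,
                 mae = mean(abs(tab$observed - tab$mean_estimated)),
                 t_star = t_star,
                 assignment = grp,
                 data = data.frame(time = time, event = event,
                                   estimated = estimated_risks)),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat("Calibration across", nrow(x$groups), "risk groups at t* =",
      x$t_star, "years\n")
  print(x$groups, row.names = FALSE, digits = 4)
  cat(sprintf("MAE = %.4f\n", x$mae))
  if (!is.null(x$gnd_chi2))
    cat(sprintf("GND chi-square = %.2f on %d df, P = %.3g\n",
                x$gnd_chi2, x$gnd_df, x$gnd_p))
  invisible(x)
}

#' Greenwood-Nam-D'Agostino calibration test
#'
#' Chi-square test of survival-model calibration across risk groups:
#' `chi2 = sum_g (O_g - E_g)^2 / V_g` with `O_g` the Kaplan-Meier observed
#' risk, `E_g` the mean estimated risk, and `V_g` the Greenwood variance of
#' `O_g`. Groups with fewer than `min_events` events by `t_star` are merged
#' into the adjacent group (pooling subjects and re-estimating the
#' Kaplan-Meier risk) before computation; the degrees of freedom are the
#' number of retained groups minus 1. A nonsignificant P value (> .05) reads
#' as consistent with calibration.
#'
#' @param report A `calibration_report` from [decile_calibration()].
#' @param min_events Merge threshold (default 5).
#' @return The report with `gnd_chi2`, `gnd_df`, `gnd_p` and the merged
#'   `gnd_groups` table added.
#' @export
gnd_test <- function(report, min_events = 5) {
  stopifnot(inherits(report, "calibration_report"))
  grp <- report$assignment
  dat <- report$data
  # merge low-event groups into the next group (previous for the last)
  members <- lapply(sort(unique(grp)), function(g) which(grp == g))
  ev_count <- function(idx) sum(dat$event[idx] == 1 & dat$time[idx] <= report$t_star)
  repeat {
    evs <- vapply(members, ev_count, 0L)
    if (length(members) < 2)
      stop("insufficient groups after merging (< 2 retained)")
    low <- which(evs < min_events)
    if (!length(low)) break
    i <- low[1]
    j <- if (i < length(members)) i + 1 else i - 1
    members[[j]] <- c(members[[j]], members[[i]])
    members[[i]] <- NULL
  }
  rows <- lapply(members, function(idx) {
    kr <- km_risk_at(kaplan_meier(dat$time[idx], dat$event[idx]),
                     report$t_star)
    data.frame(n = length(idx), events = ev_count(idx),
               mean_estimated = mean(dat$estimated[idx]),
               observed = kr$risk, greenwood_var = kr$variance)
  })
  tab <- do.call(rbind, rows)
  chi2 <- sum((tab$observed - tab$mean_estimated)^2 / tab$greenwood_var)
  df <- nrow(tab) - 1
  report$gnd_chi2 <- chi2
  report$gnd_df <- df
  report$gnd_p <- stats::pchisq(chi2, df, lower.tail = FALSE)
  report$gnd_groups <- tab
  report
}

#' Standardized univariable hazard ratio
#'
#' Univariable Cox regression of the outcome on a single covariate scaled by
#' its sample SD, so the hazard ratio is per 1-SD increase; invariant to
#' positive rescaling of the covariate.
#'
#' @param x Covariate (nonzero variance required).
#' @param time Follow-up times.
#' @param event Event indicators in \{0, 1\}.
#' @param conf_level Confidence level (default 0.95).
#' @return A list with `hr`, `ci`, `log_hr`, `se`.
#' @export
standardized_univariate_hr <- function(x, time, event, conf_level = 0.95) {
  s <- stats::sd(x)
  if (!is.finite(s) || s < 1e-12) stop("covariate has zero variance")
  xs <- x / s
  fit <- survival::coxph(survival::Surv(time, event) ~ xs, ties = "efron")
  b <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(hr = exp(b), ci = exp(c(b - zq * se, b + zq * se)),
       log_hr = b, se = se)
}
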