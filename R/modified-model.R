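#' Default covariate set definitions
#'
#' Three nested name lists over the default 58 candidate covariates: the full
#' set; an augmented reduced set of covariates most strongly tied to cognitive
#' outcomes regardless of point-of-care availability; and a basic reduced set
#' of about 14 variables routinely available in primary care in discrete data
#' fields.
#'
#' @param specs Covariate specs (default [default_covariate_specs()]);
#'   supplies the full set.
#' @return Named list of character vectors (`full`, `augmented`, `basic`).
#' @export
default_covariate_sets <- function(specs = default_covariate_specs()) {
  basic <- c("age", "female", "black", "current_smoker", "sbp", "dbp",
             "heart_rate", "bmi", "creatinine", "glucose",
             "total_cholesterol", "hdl_cholesterol", "n_bp_meds",
             "cvd_history")
  augmented <- unique(c(basic, "moca", "logical_memory_ii",
                        "digit_symbol_coding", "serial_sevens", "employed",
                        "educ_lt_high_school", "educ_high_school",
                        "educ_post_high_school", "medicare", "va_insurance",
                        "log_acr", "depression_history", "baseline_mci"))
  list(full = specs$name, augmented = augmented, basic = basic)
}

#' Build and standardize the design matrix for a named covariate set
#'
#' Subsets the cohort's covariate columns, one-hot expands factor/character
#' columns (dropping the first level), and standardizes every column to mean
#' 0, SD 1, recording the transform for later prediction.
#'
#' @param cohort A `cohort` data frame.
#' @param set_name Name of the covariate set.
#' @param sets Named list of covariate-name vectors
#'   (default [default_covariate_sets()] restricted to available columns).
#' @return A list with `X` (standardized matrix), `center`, `scale`,
#'   `columns` (design column names), `set_name`.
#' @export
select_covariate_set <- function(cohort, set_name = "full", sets = NULL) {
  if (is.null(sets)) {
    avail <- attr(cohort, "covariate_names")
    sets <- lapply(default_covariate_sets(), intersect, y = avail)
    sets$full <- avail
  }
  if (!set_name %in% names(sets))
    stop("unknown covariate set: ", set_name)
  vars <- sets[[set_name]]
  missing <- setdiff(vars, names(cohort))
  if (length(missing))
    stop("covariates not present in cohort: ", paste(missing, collapse = ", "))
  cols <- list()
  for (v in vars) {
    x <- cohort[[v]]
    if (is.numeric(x)) {
      cols[[v]] <- x
    } else {
      f <- factor(x)
      for (lev in levels(f)[-1])
        cols[[paste0(v, "_", lev)]] <- as.numeric(f == lev)
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  zero <- scl < 1e-12
  if (any(zero))
    stop("zero-variance column(s): ",
         paste(colnames(X)[zero], collapse = ", "))
  Xs <- sweep(sweep(X, 2, ctr, "-"), 2, scl, "/")
  list(X = Xs, center = ctr, scale = scl, columns = colnames(X),
       set_name = set_name)
}

# Restricted cubic spline with 3 knots: one nonlinear basis column, linear
# beyond the outer knots (Harrell's truncated-power parameterization).
rcs_basis <- function(eta, knots) {
  k1 <- knots[1]; k2 <- knots[2]; k3 <- knots[3]
  pp <- function(x) pmax(x, 0)^3
  (pp(eta - k1) - pp(eta - k2) * (k3 - k1) / (k3 - k2) +
      pp(eta - k3) * (k2 - k1) / (k3 - k2)) / (k3 - k1)^2
}

# Treatment-effect function g(eta) (+ optional subgroup shifts).
g_of_eta <- function(fit, eta, subgroup = NULL) {
  g <- fit$gamma[["const"]] + fit$gamma[["eta"]] * eta
  if (!is.na(fit$gamma["spline1"]) && fit$gamma[["spline1"]] != 0)
    g <- g + fit$gamma[["spline1"]] * rcs_basis(eta, fit$knots)
  if (!is.null(fit$delta) && length(fit$delta) && !is.null(subgroup))
    g <- g + drop(as.matrix(subgroup) %*% fit$delta)
  g
}

#' Fit the modified elastic-net Cox model
#'
#' Jointly estimates a multivariable baseline risk score
#' `eta(x) = beta . x_std` (elastic-net penalized) and its interaction with
#' randomized treatment, under the hazard
#' `lambda_0(t) exp(eta(x) + z g(eta(x)))` with
#' `g(eta) = gamma_0 + gamma_1 eta + gamma_2 s(eta)` (optional restricted-
#' cubic-spline term with knots at the 0.1/0.5/0.9 quantiles of eta).
#' Treatment enters only through the multiplicative hazard factor
#' `exp(z g(eta))`, so the implied between-arm absolute risk difference
#' approaches 0 as the risk score approaches minus infinity: both arms' risks
#' vanish there (the zero-risk constraint). The intercept `gamma_0` lets `g`
#' represent a constant relative effect, which the slope/spline terms alone
#' cannot.
#'
#' Estimation alternates (i) a penalized fit of `beta` with the interaction
#' contribution held fixed as an offset and (ii) an unpenalized Cox fit of the
#' interaction coefficients given `eta`, until the relative change in `eta`
#' falls below `eta_tol` or `max_iter` rounds. The penalty strength is
#' selected (by CV if requested) in the first round and then held fixed.
#'
#' @param cohort A `cohort` data frame with both arms present.
#' @param covariate_set Covariate-set name (see [select_covariate_set()]).
#' @param outcome Outcome name (`time_<outcome>` / `event_<outcome>` columns).
#' @param penalty A [penalty_spec()].
#' @param interaction_basis `"spline"` (linear + one restricted-cubic-spline
#'   term, the default) or `"linear"`.
#' @param effect_modifiers Optional matrix/data frame of 0/1 subgroup
#'   indicators whose treatment interactions are added to `g` (the hybrid
#'   risk-plus-effect model).
#' @param sets Optional covariate-set definitions passed through to
#'   [select_covariate_set()].
#' @param max_iter,eta_tol Alternation controls.
#' @param seed Seed for CV fold assignment.
#' @return An object of class `modified_cox_fit` with the penalized risk-score
#'   coefficients, standardization table, interaction coefficients and their
#'   covariance, Breslow baseline cumulative hazard, and fitting metadata.
#' @export
fit_modified_model <- function(cohort, covariate_set = "full",
                               outcome = "primary",
                               penalty = penalty_spec(),
                               interaction_basis = c("spline", "linear"),
                               effect_modifiers = NULL, sets = NULL,
                               max_iter = 20, eta_tol = 1e-6, seed = 1L) {
  interaction_basis <- match.arg(interaction_basis)
  tm <- cohort[[paste0("time_", outcome)]]
  ev <- cohort[[paste0("event_", outcome)]]
  if (is.null(tm) || is.null(ev)) stop("outcome not found: ", outcome)
  z <- as.numeric(cohort$arm == "intensive")
  if (length(unique(z)) < 2) stop("both treatment arms must be present")
  if (sum(ev) < 30) stop("need at least 30 events, found ", sum(ev))
  design <- select_covariate_set(cohort, covariate_set, sets = sets)
  X <- design$X
  n <- nrow(X)
  S <- NULL
  if (!is.null(effect_modifiers)) {
    S <- as.matrix(effect_modifiers)
    keep <- apply(S, 2, function(s) length(unique(s)) > 1)
    if (!all(keep)) {
      warning("dropping single-level effect modifier(s): ",
              paste(colnames(S)[!keep], collapse = ", "))
      S <- S[, keep, drop = FALSE]
    }
    if (!ncol(S)) S <- NULL
  }
  offset <- numeric(n)
  eta <- numeric(n)
  gamma <- c(const = 0, eta = 0,
             spline1 = if (interaction_basis == "spline") 0 else NA)
  delta <- if (!is.null(S)) stats::setNames(numeric(ncol(S)), colnames(S))
  knots <- NULL
  gvcov <- NULL
  lambda_fixed <- NULL
  converged <- FALSE
  iters <- 0
  beta_prev <- NULL
  for (it in seq_len(max_iter)) {
    iters <- it
    if (is.null(lambda_fixed)) {
      # lambda selected once (by CV if requested), then held fixed
      enet <- fit_elastic_net_cox(X, tm, ev, penalty, offset = offset,
                                  seed = seed)
      lambda_fixed <- enet$lambda
      pf <- enet$penalty_factor
    } else {
      core <- enet_cox_core(X, tm, ev, offset, lambda_fixed,
                            penalty$alpha, pf, beta0 = beta_prev)
      enet$beta <- stats::setNames(core$beta, colnames(X))
      enet$iterations <- core$iterations
      enet$kkt <- core$kkt
    }
    beta_prev <- unname(enet$beta)
    eta_raw <- drop(X %*% enet$beta)
    degenerate <- stats::sd(eta_raw) < 1e-10
    if (degenerate) {
      # penalty removed every covariate: only a constant effect is left
      warning("risk score is degenerate (all coefficients zero); ",
              "only the constant treatment effect is estimated")
      B <- cbind(g_const = rep(1, n))
      zB <- z * B
      if (!is.null(S)) zB <- cbind(zB, z * S)
      cfit <- survival::coxph(survival::Surv(tm, ev) ~ zB, ties = "efron")
      co <- stats::coef(cfit); co[is.na(co)] <- 0
      gamma["const"] <- co[1]
      gamma["eta"] <- 0
      if (interaction_basis == "spline") gamma["spline1"] <- 0
      if (!is.null(S)) delta[] <- co[2:(1 + ncol(S))]
      gvcov <- stats::vcov(cfit)
      eta <- eta_raw
      offset <- drop(zB %*% co)
      cal_slope <- 1
      converged <- TRUE
      break
    }
    B <- cbind(g_const = rep(1, n), g_eta = eta_raw)
    knots_raw <- NULL
    if (interaction_basis == "spline") {
      knots_raw <- unname(stats::quantile(eta_raw, c(0.1, 0.5, 0.9)))
      if (knots_raw[3] - knots_raw[1] < 1e-8 ||
          knots_raw[2] == knots_raw[1] || knots_raw[3] == knots_raw[2]) {
        knots_raw <- unname(stats::quantile(eta_raw, c(0.05, 0.5, 0.95)))
      }
      B <- cbind(B, g_spline1 = rcs_basis(eta_raw, knots_raw))
    }
    zB <- z * B
    if (!is.null(S)) zB <- cbind(zB, z * S)
    # Unpenalized step: a free calibration slope on eta (both arms) absorbs
    # the scale shrinkage of the penalized beta-step, so the interaction
    # terms do not have to compensate it in the treated arm alone.
    cfit <- survival::coxph(survival::Surv(tm, ev) ~ eta_raw + zB,
                            ties = "efron")
    co <- stats::coef(cfit)
    co[is.na(co)] <- 0
    a <- co[1]
    if (!is.finite(a) || a <= 0.05) a <- 1  # guard against a collapsed slope
    co_g <- co[-1]
    gamma["const"] <- co_g[1]
    gamma["eta"] <- co_g[2] / a
    if (interaction_basis == "spline")
      gamma["spline1"] <- co_g[3] / a
    if (!is.null(S))
      delta[] <- co_g[(ncol(B) + 1):(ncol(B) + ncol(S))]
    gvcov <- stats::vcov(cfit)
    knots <- if (!is.null(knots_raw)) a * knots_raw
    cal_slope <- a
    g_now <- drop(B %*% co_g[seq_len(ncol(B))])
    if (!is.null(S)) g_now <- g_now + drop(S %*% delta)
    offset <- z * g_now
    eta_new <- a * eta_raw  # calibrated risk score
    rel <- sqrt(sum((eta_new - eta)^2)) / max(sqrt(sum(eta^2)), 1)
    eta <- eta_new
    if (rel < eta_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged && iters == max_iter)
    warning("alternation did not converge in ", max_iter, " rounds")
  lp <- eta + offset
  H0 <- breslow_baseline(tm, ev, lp)
  structure(list(beta = stats::setNames(cal_slope * unname(enet$beta),
                                        names(enet$beta)),
                 calibration_slope = cal_slope,
                 center = design$center, scale = design$scale,
                 columns = design$columns,
                 covariate_set = design$set_name, outcome = outcome,
                 gamma = gamma, delta = delta, knots = knots,
                 gvcov = gvcov,
                 interaction_basis = interaction_basis,
                 baseline_cumhaz = H0,
                 lambda_selected = lambda_fixed, alpha = penalty$alpha,
                 iterations = iters, converged = converged,
                 n = n, n_events = sum(ev), t_max = max(tm),
                 eta = eta, arm = cohort$arm),
            class = "modified_cox_fit")
}

#' @export
print.modified_cox_fit <- function(x, ...) {
  cat("Modified elastic-net Cox fit\n")
  cat("  outcome:", x$outcome, "  covariate set:", x$covariate_set, "\n")
  cat("  n =", x$n, " events =", x$n_events, "\n")
  cat("  nonzero risk-score coefficients:", sum(x$beta != 0), "of",
      length(x$beta), " (lambda =", signif(x$lambda_selected, 4),
      ", alpha =", x$alpha, ")\n")
  g <- x$gamma[!is.na(x$gamma)]
  cat("  interaction g(eta):",
      paste(sprintf("%s = %.4f", names(g), g), collapse = ", "), "\n")
  if (!is.null(x$delta) && length(x$delta))
    cat("  subgroup interactions:",
        paste(sprintf("%s = %.3f", names(x$delta), x$delta),
              collapse = ", "), "\n")
  cat("  alternation:", x$iterations, "rounds,",
      if (x$converged) "converged" else "NOT converged", "\n")
  invisible(x)
}

# Standardized design + risk score for new data under a fit.
predict_eta <- function(fit, newdata) {
  missing <- setdiff(fit$columns, names(newdata))
  if (length(missing))
    stop("newdata lacks design columns: ", paste(missing, collapse = ", "))
  X <- as.matrix(as.data.frame(newdata)[, fit$columns, drop = FALSE])
  Xs <- sweep(sweep(X, 2, fit$center, "-"), 2, fit$scale, "/")
  drop(Xs %*% fit$beta)
}

#' Absolute outcome risk at a fixed horizon from a risk-score value
#'
#' `1 - exp(-H0(t_star) * exp(eta + z g(eta)))` with the Breslow baseline
#' cumulative hazard of the fit.
#'
#' @param fit A `modified_cox_fit`.
#' @param eta Risk-score value(s).
#' @param arm `"standard"` or `"intensive"`.
#' @param t_star Horizon in years; must not exceed the last observed time.
#' @param subgroup Optional subgroup-indicator row(s) for hybrid fits.
#' @return Risk(s) in \[0, 1\].
#' @export
risk_from_score <- function(fit, eta, arm = c("standard", "intensive"),
                            t_star, subgroup = NULL) {
  arm <- match.arg(arm)
  if (t_star > fit$t_max)
    stop("t_star ", t_star, " exceeds the last observed time ",
         signif(fit$t_max, 4))
  H <- evaluate_hazard(fit$baseline_cumhaz, t_star)
  z <- as.numeric(arm == "intensive")
  lp <- eta + z * g_of_eta(fit, eta, subgroup)
  1 - exp(-H * exp(lp))
}

#' Model-estimated absolute risk for subjects
#'
#' @param fit A `modified_cox_fit`.
#' @param newdata Data frame with the fit's covariate columns.
#' @param arm `"standard"` or `"intensive"`.
#' @param t_star Horizon in years (must be within observed follow-up).
#' @param subgroup Optional subgroup indicators for hybrid fits.
#' @return Risk(s) in \[0, 1\].
#' @export
absolute_risk <- function(fit, newdata, arm = c("standard", "intensive"),
                          t_star, subgroup = NULL) {
  arm <- match.arg(arm)
  risk_from_score(fit, predict_eta(fit, newdata), arm, t_star, subgroup)
}

#' Model-estimated between-arm absolute risk difference
#'
#' Intensive-arm minus standard-arm estimated risk at `t_star`; negative
#' values indicate benefit from intensive treatment.
#'
#' @inheritParams absolute_risk
#' @return Risk difference(s).
#' @export
estimated_risk_difference <- function(fit, newdata, t_star,
                                      subgroup = NULL) {
  eta <- predict_eta(fit, newdata)
  risk_from_score(fit, eta, "intensive", t_star, subgroup) -
    risk_from_score(fit, eta, "standard", t_star, subgroup)
}

#' Convert a risk difference to events prevented per 1000 treated
#'
#' A risk difference of -0.027 corresponds to 27 events prevented per 1000
#' persons treated.
#'
#' @param rd Risk difference(s) (negative = benefit).
#' @return Events prevented per 1000 treated.
#' @export
events_prevented_per_1000 <- function(rd) -1000 * rd

# Subject-level model predictions for the analysis cohort: risk score,
# per-arm risks, risk difference, and risk under the assigned arm.
predict_cohort <- function(fit, cohort, t_star, subgroup = NULL) {
  eta <- predict_eta(fit, cohort)
  r_int <- risk_from_score(fit, eta, "intensive", t_star, subgroup)
  r_std <- risk_from_score(fit, eta, "standard", t_star, subgroup)
  data.frame(eta = eta, risk_intensive = r_int, risk_standard = r_std,
             rd = r_int - r_std,
             risk_assigned = ifelse(cohort$arm == "intensive", r_int, r_std))
}
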