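# Shared fixtures: small survival data sets generated in code.

# Exponential survival with uniform administrative censoring.
sim_exp <- function(n, rate = 0.05, lp = rep(0, n), seed = 1,
                    censor = c(3.5, 5.88)) {
  set.seed(seed)
  tt <- stats::rexp(n) / (rate * exp(lp))
  cens <- stats::runif(n, censor[1], censor[2])
  list(time = pmin(tt, cens), event = as.integer(tt <= cens))
}

# Small random Cox regression data set.
sim_cox_data <- function(n = 60, p = 2, beta = rep(0.4, p), seed = 1) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  d <- sim_exp(n, rate = 0.1, lp = drop(X %*% beta), seed = seed + 1)
  list(X = X, time = d$time, event = d$event)
}

# A tiny deterministic generative truth with one component and no covariates,
# convenient for closed-form checks.
flat_truth <- function(rate = 0.05, theta = 0, loadings = 1) {
  truth_parameters(beta = c(age = 0),
                   component_base_rates = c(amci = rate),
                   component_loadings = c(amci = loadings),
                   effect_kind = "constant_hr",
                   effect_params = list(theta = theta))
}

# A hand-built modified Cox fit for unit tests of the prediction surface:
# risk score = standardized `x`, interaction g(eta) = g0 + g1 * eta, baseline
# cumulative hazard H0(t) = h_rate * t on a fine grid up to t_max.
toy_fit <- function(g0 = 0, g1 = 0, h_rate = 0.05, t_max = 6,
                    center = 0, scale = 1) {
  grid <- seq(0.01, t_max, by = 0.01)
  structure(list(beta = c(x = 1), calibration_slope = 1,
                 center = c(x = center), scale = c(x = scale),
                 columns = "x", covariate_set = "toy", outcome = "primary",
                 gamma = c(const = g0, eta = g1, spline1 = NA_real_),
                 delta = NULL, knots = NULL, gvcov = NULL,
                 interaction_basis = "linear",
                 baseline_cumhaz = structure(
                   data.frame(time = grid, hazard = h_rate * grid),
                   class = c("breslow_hazard", "data.frame")),
                 lambda_selected = 0, alpha = 0.5, iterations = 1,
                 converged = TRUE, n = 0, n_events = 0, t_max = t_max),
            class = "modified_cox_fit")
}

# Quick simulated cohort at reduced size under the default truth.
small_cohort <- function(n = 1500, seed = 42, truth = truth_parameters()) {
  simulate_cohort(cohort_config(n_subjects = n, seed = seed), truth)
}

fixed_penalty <- function(lambda = 0.01, alpha = 0.5)
  penalty_spec(alpha = alpha, lambda = lambda)
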