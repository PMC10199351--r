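#' Draw baseline covariates and randomized arm assignments
#'
#' Covariates are generated through a Gaussian copula: a latent multivariate
#' normal vector with the configured correlation is transformed marginal by
#' marginal (thresholding for binary covariates, affine rescaling for
#' continuous ones). Arms are assigned by independent Bernoulli draws, so the
#' randomization is independent of every covariate.
#'
#' @param config A [cohort_config()].
#' @return A list with `covariates` (numeric matrix, one column per covariate)
#'   and `arm` (factor with levels `standard`, `intensive`).
#' @export
generate_covariates <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  specs <- config$covariate_specs
  n <- config$n_subjects
  p <- nrow(specs)
  set.seed(config$seed)
  z <- matrix(stats::rnorm(n * p), n, p)
  if (!is.null(config$correlation)) {
    ev <- eigen(config$correlation, symmetric = TRUE)
    rt <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
    z <- z %*% rt
  }
  x <- matrix(NA_real_, n, p, dimnames = list(NULL, specs$name))
  for (j in seq_len(p)) {
    x[, j] <- if (specs$type[j] == "binary") {
      as.numeric(stats::pnorm(z[, j]) < specs$prevalence[j])
    } else {
      specs$mean[j] + specs$sd[j] * z[, j]
    }
  }
  arm <- factor(ifelse(stats::runif(n) < config$arm_ratio,
                       "intensive", "standard"),
                levels = c("standard", "intensive"))
  list(covariates = x, arm = arm)
}

# Population standardization of raw covariates using the configured moments
# (binary: mean p, SD sqrt(p(1-p))), so the generative risk score does not
# depend on the realized sample.
.standardize_by_spec <- function(x, specs) {
  mu <- ifelse(specs$type == "binary", specs$prevalence, specs$mean)
  sd <- ifelse(specs$type == "binary",
               sqrt(specs$prevalence * (1 - specs$prevalence)), specs$sd)
  sweep(sweep(x, 2, mu, "-"), 2, sd, "/")
}

# True risk score eta for a raw covariate matrix.
truth_risk_score <- function(x, specs, beta) {
  xs <- .standardize_by_spec(x, specs)
  b <- stats::setNames(numeric(ncol(xs)), colnames(xs))
  if (length(beta)) {
    missing <- setdiff(names(beta), names(b))
    if (length(missing))
      stop("truth beta names not among covariates: ",
           paste(missing, collapse = ", "))
    b[names(beta)] <- beta
  }
  drop(xs %*% b)
}

#' Simulate composite time-to-event outcomes under the generative truth
#'
#' Each latent component time is exponential with per-subject hazard
#' `lambda_k * exp(a_k * eta + z * theta(eta))`, where `z` is 1 for the
#' intensive arm. A composite outcome's latent time is the minimum over its
#' components; observed time is the minimum of the latent time, the
#' administrative censoring time (uniform over the configured window) and any
#' dropout time, with the event indicator set accordingly.
#'
#' @param covariates Complete raw covariate matrix from
#'   [generate_covariates()] (missingness is applied afterwards).
#' @param arm Factor of arm assignments.
#' @param truth A [truth_parameters()].
#' @param outcome_defs List of [outcome_definition()]s.
#' @param specs Covariate specs used to standardize covariates for the risk
#'   score (defaults to [default_covariate_specs()]).
#' @param seed Integer seed for event and censoring draws.
#' @return A `cohort` data frame: `id`, `arm`, `has_followup`, `truth_eta`,
#'   per-outcome `time_<name>`/`event_<name>` columns, then covariates.
#' @export
generate_outcomes <- function(covariates, arm, truth, outcome_defs,
                              specs = default_covariate_specs(), seed = 1L) {
  stopifnot(inherits(truth, "truth_parameters"))
  if (inherits(outcome_defs, "outcome_definition"))
    outcome_defs <- list(outcome_defs)
  n <- nrow(covariates)
  eta <- truth_risk_score(covariates, specs, truth$beta)
  z <- as.numeric(arm == "intensive")
  theta <- truth_effect(truth, eta)
  set.seed(seed)
  comps <- names(truth$component_base_rates)
  comp_times <- matrix(NA_real_, n, length(comps),
                       dimnames = list(NULL, comps))
  for (k in seq_along(comps)) {
    lam <- truth$component_base_rates[k]
    a <- truth$component_loadings[comps[k]]
    rate <- lam * exp(a * eta + z * theta)
    comp_times[, k] <- stats::rexp(n) / rate
  }
  cens <- stats::runif(n, truth$censor_window[1], truth$censor_window[2])
  if (truth$dropout_rate > 0)
    cens <- pmin(cens, stats::rexp(n, truth$dropout_rate))
  out <- data.frame(id = seq_len(n), arm = arm,
                    has_followup = 1L, truth_eta = eta)
  for (def in outcome_defs) {
    lat <- do.call(pmin, as.data.frame(comp_times[, def$components,
                                                  drop = FALSE]))
    out[[paste0("time_", def$name)]] <- pmin(lat, cens)
    out[[paste0("event_", def$name)]] <- as.integer(lat <= cens)
  }
  out <- cbind(out, as.data.frame(covariates))
  attr(out, "outcomes") <- unname(vapply(outcome_defs, `[[`, "", "name"))
  attr(out, "covariate_names") <- colnames(covariates)
  class(out) <- c("cohort", "data.frame")
  out
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper: draws covariates and arms, simulates outcomes, then
#' applies MCAR covariate missingness and flags subjects without follow-up
#' according to the configured rates.
#'
#' @param config A [cohort_config()].
#' @param truth A [truth_parameters()].
#' @param outcome_defs List of outcome definitions
#'   (default [default_outcome_definitions()]).
#' @return A `cohort` data frame (see [generate_outcomes()]).
#' @export
simulate_cohort <- function(config, truth = truth_parameters(),
                            outcome_defs = default_outcome_definitions()) {
  base <- generate_covariates(config)
  cohort <- generate_outcomes(base$covariates, base$arm, truth, outcome_defs,
                              specs = config$covariate_specs,
                              seed = config$seed + 1L)
  set.seed(config$seed + 2L)
  covs <- attr(cohort, "covariate_names")
  if (config$missingness_rate > 0) {
    for (nm in covs) {
      miss <- stats::runif(nrow(cohort)) < config$missingness_rate
      cohort[[nm]][miss] <- NA_real_
    }
  }
  if (config$no_followup_rate > 0) {
    cohort$has_followup <-
      as.integer(stats::runif(nrow(cohort)) >= config$no_followup_rate)
  }
  cohort
}

#' Apply the analytic eligibility filter
#'
#' Removes subjects without any follow-up assessment, then subjects with a
#' missing baseline covariate value, tallying exclusions per reason.
#'
#' @param cohort A `cohort` data frame.
#' @return A list of class `eligibility_filter` with elements `cohort` (the
#'   filtered cohort), `n_randomized`, `n_no_followup`,
#'   `n_missing_covariates`, `n_analytic` and `pct_excluded`.
#' @export
apply_eligibility_filter <- function(cohort) {
  covs <- attr(cohort, "covariate_names")
  if (is.null(covs) || is.null(cohort$has_followup))
    stop("cohort must carry has_followup and covariate columns")
  n0 <- nrow(cohort)
  no_fu <- cohort$has_followup == 0
  rest <- cohort[!no_fu, , drop = FALSE]
  miss <- rowSums(is.na(rest[, covs, drop = FALSE])) > 0
  kept <- rest[!miss, , drop = FALSE]
  if (!nrow(kept))
    stop("eligibility filter removed every subject (",
         sum(no_fu), " without follow-up, ", sum(miss),
         " with missing covariates)")
  attr(kept, "outcomes") <- attr(cohort, "outcomes")
  attr(kept, "covariate_names") <- covs
  class(kept) <- c("cohort", "data.frame")
  structure(list(cohort = kept,
                 n_randomized = n0,
                 n_no_followup = sum(no_fu),
                 n_missing_covariates = sum(miss),
                 n_analytic = nrow(kept),
                 pct_excluded = 100 * (n0 - nrow(kept)) / n0),
            class = "eligibility_filter")
}

#' @export
print.eligibility_filter <- function(x, ...) {
  cat("Eligibility filter:", x$n_randomized, "randomized ->",
      x$n_analytic, "analytic\n")
  cat("  excluded without follow-up assessment:", x$n_no_followup, "\n")
  cat("  excluded with missing baseline covariates:",
      x$n_missing_covariates, "\n")
  cat(sprintf("  total excluded: %.1f%%\n", x$pct_excluded))
  invisible(x)
}

#' Closed-form absolute outcome risk under the generative truth
#'
#' For a subject with risk score `eta` the composite outcome hazard is
#' constant in time, so the risk by time `t` is
#' `1 - exp(-t * sum_k lambda_k exp(a_k eta + z theta(eta)))` over the
#' outcome's components.
#'
#' @param truth A [truth_parameters()].
#' @param eta True risk score(s).
#' @param arm `"intensive"` or `"standard"`.
#' @param t_star Horizon in years (> 0 unless exactly 0, which gives risk 0).
#' @param components Components of the composite (default: the primary
#'   cognitive composite).
#' @return Risk(s) in \[0, 1\].
#' @export
oracle_absolute_risk <- function(truth, eta, arm = c("standard", "intensive"),
                                 t_star,
                                 components = c("amci", "probable_dementia")) {
  arm <- match.arg(arm)
  if (any(t_star < 0)) stop("t_star must be >= 0")
  comps <- intersect(names(truth$component_base_rates), components)
  if (!length(comps)) stop("no matching components in truth")
  z <- as.numeric(arm == "intensive")
  theta <- truth_effect(truth, eta)
  haz <- 0
  for (k in comps) {
    haz <- haz + truth$component_base_rates[[k]] *
      exp(truth$component_loadings[[k]] * eta + z * theta)
  }
  1 - exp(-t_star * haz)
}

#' Closed-form between-arm risk difference under the generative truth
#'
#' Intensive-arm minus standard-arm absolute risk at `t_star`; negative values
#' indicate benefit. Tends to 0 as `eta` tends to minus infinity for any
#' bounded treatment-effect function, the zero-risk limit the estimation model
#' is constrained to respect.
#'
#' @inheritParams oracle_absolute_risk
#' @return Risk difference(s) in \[-1, 1\].
#' @export
oracle_risk_difference <- function(truth, eta, t_star,
                                   components = c("amci",
                                                  "probable_dementia")) {
  oracle_absolute_risk(truth, eta, "intensive", t_star, components) -
    oracle_absolute_risk(truth, eta, "standard", t_star, components)
}
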