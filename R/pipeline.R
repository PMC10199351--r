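#' Pipeline configuration
#'
#' Bundles everything an end-to-end replication run needs: the input mode,
#' the estimation horizon, the outcome and covariate-set grids, penalty and
#' bootstrap settings, and the three named seeds from which all randomness
#' flows (simulation, CV fold assignment, bootstrap).
#'
#' @param mode `"simulate"` (default) or `"file"`.
#' @param cohort_file Cohort CSV path when `mode = "file"`.
#' @param cohort_cfg A [cohort_config()] for simulate mode.
#' @param truth A [truth_parameters()] for simulate mode.
#' @param t_star Estimation horizon in years (default 4.13, the median
#'   follow-up the default generator emulates).
#' @param outcomes Named list of [outcome_definition()]s.
#' @param covariate_sets Covariate-set names to run (subset of the names of
#'   [default_covariate_sets()], or of `sets`).
#' @param sets Optional explicit covariate-set definitions.
#' @param penalty A [penalty_spec()].
#' @param n_boot Bootstrap replicates for magnification bands.
#' @param include_hybrid Whether to run the hybrid subgroup-interaction model
#'   per combination.
#' @param seeds Named list with `simulation`, `cv`, `bootstrap`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "file"), cohort_file = NULL,
                            cohort_cfg = cohort_config(),
                            truth = truth_parameters(), t_star = 4.13,
                            outcomes = default_outcome_definitions(),
                            covariate_sets = c("full", "augmented", "basic"),
                            sets = NULL, penalty = penalty_spec(),
                            n_boot = 200, include_hybrid = TRUE,
                            seeds = list(simulation = 1L, cv = 2L,
                                         bootstrap = 3L)) {
  mode <- match.arg(mode)
  if (t_star <= 0) stop("t_star must be > 0")
  if (mode == "file" && is.null(cohort_file))
    stop("mode = \"file\" requires cohort_file")
  stopifnot(all(c("simulation", "cv", "bootstrap") %in% names(seeds)))
  if (mode == "simulate") {
    known <- cohort_cfg$covariate_specs$name
    ref <- if (is.null(sets))
      unique(unlist(default_covariate_sets(cohort_cfg$covariate_specs)[
        intersect(covariate_sets, c("full", "augmented", "basic"))]))
    else unique(unlist(sets[covariate_sets]))
    miss <- setdiff(ref, known)
    if (length(miss))
      stop("configured covariate(s) not in cohort specs: ",
           paste(miss, collapse = ", "))
  }
  structure(list(mode = mode, cohort_file = cohort_file,
                 cohort_cfg = cohort_cfg, truth = truth, t_star = t_star,
                 outcomes = outcomes, covariate_sets = covariate_sets,
                 sets = sets, penalty = penalty, n_boot = n_boot,
                 include_hybrid = include_hybrid, seeds = seeds),
            class = "pipeline_config")
}

#' Run the full risk-magnification analysis pipeline
#'
#' Simulates or loads a cohort, applies the eligibility filter, and for every
#' (outcome, covariate set) combination fits the modified elastic-net Cox
#' model and produces the calibration report (with C statistic and GND test),
#' the tertile-of-benefit table, the risk-magnification curve and, optionally,
#' the hybrid subgroup-interaction comparison. A failure in one combination
#' is recorded and does not abort the others.
#'
#' @param config A [pipeline_config()].
#' @return A `run_report`: list with `cohort` (filtered), `filter` tally,
#'   `combinations` (named list of per-combination results or failure
#'   records), and `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- if (config$mode == "simulate") {
    cfg <- config$cohort_cfg
    cfg$seed <- as.integer(config$seeds$simulation)
    simulate_cohort(cfg, config$truth, config$outcomes)
  } else {
    read_cohort(config$cohort_file)
  }
  filt <- apply_eligibility_filter(cohort)
  cohort <- filt$cohort
  combos <- list()
  for (def in config$outcomes) {
    for (set_name in config$covariate_sets) {
      key <- paste(def$name, set_name, sep = ".")
      combos[[key]] <- tryCatch({
        fit <- fit_modified_model(cohort, set_name, def$name,
                                  config$penalty, sets = config$sets,
                                  seed = as.integer(config$seeds$cv))
        pr <- predict_cohort(fit, cohort, config$t_star)
        tm <- cohort[[paste0("time_", def$name)]]
        ev <- cohort[[paste0("event_", def$name)]]
        calib <- gnd_test(decile_calibration(pr$risk_assigned, tm, ev,
                                             config$t_star))
        cstat <- harrell_c(fit$eta, tm, ev)
        tert <- tertile_benefit_table(fit, cohort, config$t_star)
        curve <- magnification_curve(fit, cohort, config$t_star,
                                     n_boot = config$n_boot,
                                     seed = as.integer(config$seeds$bootstrap))
        hybrid <- if (config$include_hybrid)
          tryCatch(hybrid_effect_model(cohort, set_name, def$name,
                                       config$penalty, sets = config$sets,
                                       seed = as.integer(config$seeds$cv)),
                   error = function(e) NULL)
        list(status = "ok", outcome = def$name, covariate_set = set_name,
             fit = fit, calibration = calib, c_statistic = cstat,
             tertiles = tert, curve = curve,
             hybrid = if (!is.null(hybrid))
               hybrid[c("c_base", "c_hybrid", "c_difference",
                        "subgroup_coefficients")])
      }, error = function(e) {
        list(status = "failed", outcome = def$name,
             covariate_set = set_name, error = conditionMessage(e))
      })
    }
  }
  structure(list(cohort = cohort, filter = filt, combinations = combos,
                 config = config),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  ok <- vapply(x$combinations, function(cb) cb$status == "ok", TRUE)
  cat("Pipeline run:", length(x$combinations), "combinations (",
      sum(ok), "ok /", sum(!ok), "failed )\n")
  for (key in names(x$combinations)) {
    cb <- x$combinations[[key]]
    if (cb$status == "ok") {
      cat(sprintf("  %-40s C = %.3f  MAE = %.4f  GND P = %.3g\n", key,
                  cb$c_statistic, cb$calibration$mae, cb$calibration$gnd_p))
    } else {
      cat(sprintf("  %-40s FAILED: %s\n", key, cb$error))
    }
  }
  invisible(x)
}

#' Render a pipeline report to files
#'
#' Writes, per combination, the calibration table and plot, the tertile
#' table, and the magnification curve table and plot, plus a summary index
#' (`summary.csv`) listing C statistic, MAE, GND P, linearity P and hybrid
#' C-difference per combination. Failed combinations get a placeholder row
#' naming the failure.
#'
#' @param report A `run_report`.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
render_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  paths <- character()
  summ <- list()
  for (key in names(report$combinations)) {
    cb <- report$combinations[[key]]
    if (cb$status != "ok") {
      summ[[key]] <- data.frame(combination = key, status = "failed",
                                c_statistic = NA, mae = NA, gnd_p = NA,
                                linearity_p = NA, hybrid_c_difference = NA,
                                note = cb$error)
      next
    }
    base <- file.path(outdir, key)
    utils::write.csv(cb$calibration$groups,
                     paste0(base, "_calibration.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(cb$tertiles),
                     paste0(base, "_tertiles.csv"), row.names = FALSE)
    utils::write.csv(cb$curve$curve, paste0(base, "_curve.csv"),
                     row.names = FALSE)
    ggplot2::ggsave(paste0(base, "_calibration.pdf"),
                    plot_calibration(cb$calibration),
                    width = 5, height = 5)
    ggplot2::ggsave(paste0(base, "_magnification.pdf"),
                    plot_magnification(cb$curve), width = 6, height = 5)
    paths <- c(paths, paste0(base, c("_calibration.csv", "_tertiles.csv",
                                     "_curve.csv", "_calibration.pdf",
                                     "_magnification.pdf")))
    summ[[key]] <- data.frame(
      combination = key, status = "ok",
      c_statistic = cb$c_statistic, mae = cb$calibration$mae,
      gnd_p = cb$calibration$gnd_p, linearity_p = cb$curve$linearity_p,
      hybrid_c_difference = if (!is.null(cb$hybrid))
        cb$hybrid$c_difference else NA,
      note = "")
  }
  spath <- file.path(outdir, "summary.csv")
  utils::write.csv(do.call(rbind, summ), spath, row.names = FALSE)
  invisible(c(paths, spath))
}

#' Calibration plot: observed vs estimated risk by decile
#'
#' Observed Kaplan-Meier risk with 95% Greenwood whiskers against mean
#' estimated risk per decile, with the identity line.
#'
#' @param report A `calibration_report`.
#' @return A ggplot object.
#' @export
plot_calibration <- function(report) {
  g <- report$groups
  g$se <- sqrt(g$greenwood_var)
  ggplot2::ggplot(g, ggplot2::aes(x = .data$mean_estimated,
                                  y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, color = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$observed - 1.96 * .data$se,
                                        ymax = .data$observed + 1.96 * .data$se),
                           width = 0) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Mean estimated risk",
                  y = "Observed risk (Kaplan-Meier)",
                  title = sprintf("Calibration at %.2f years (MAE = %.3f)",
                                  report$t_star, report$mae)) +
    ggplot2::theme_minimal()
}

#' Risk-magnification plot
#'
#' Estimated risk-difference curve with bootstrap band, the constant-HR
#' direct-magnification reference, observed risk differences within quartiles
#' of estimated benefit, and a histogram of baseline risk.
#'
#' @param curve A `magnification_curve`.
#' @return A ggplot object.
#' @export
plot_magnification <- function(curve) {
  cv <- curve$curve
  hist_df <- data.frame(risk = curve$histogram)
  rng <- range(c(cv$lower, cv$upper, curve$quartiles$ci_low,
                 curve$quartiles$ci_high), na.rm = TRUE)
  hmax <- 0.2 * diff(rng)
  ggplot2::ggplot() +
    ggplot2::geom_histogram(
      data = hist_df,
      ggplot2::aes(x = .data$risk,
                   y = ggplot2::after_stat(.data$count /
                                             max(.data$count)) * hmax + rng[1]),
      bins = 40, fill = "grey80", color = NA) +
    ggplot2::geom_ribbon(data = cv,
                         ggplot2::aes(x = .data$baseline_risk,
                                      ymin = .data$lower, ymax = .data$upper),
                         fill = "grey60", alpha = 0.5) +
    ggplot2::geom_line(data = curve$reference,
                       ggplot2::aes(x = .data$baseline_risk, y = .data$rd),
                       color = "darkorange", linewidth = 0.8) +
    ggplot2::geom_line(data = cv,
                       ggplot2::aes(x = .data$baseline_risk,
                                    y = .data$estimated_rd),
                       color = "steelblue", linewidth = 0.9) +
    ggplot2::geom_pointrange(data = curve$quartiles,
                             ggplot2::aes(x = .data$mean_baseline_risk,
                                          y = .data$observed_rd,
                                          ymin = .data$ci_low,
                                          ymax = .data$ci_high),
                             color = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey40") +
    ggplot2::labs(x = "Estimated baseline risk",
                  y = "Risk difference (intensive - standard)",
                  title = sprintf("Risk magnification at %.2f years",
                                  curve$t_star)) +
    ggplot2::theme_minimal()
}

#' Write / read a pipeline configuration as a structured text file
#'
#' Serializes the portable fields of a [pipeline_config()] (mode, horizon,
#' outcome definitions, covariate-set names, penalty settings, bootstrap
#' size, seeds, and the cohort generator's scalar settings) to YAML.
#' Covariate specs and truth parameters beyond the generator scalars are
#' reconstructed from package defaults on read.
#'
#' @param config A `pipeline_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  obj <- list(
    mode = config$mode,
    cohort_file = config$cohort_file,
    t_star = config$t_star,
    outcomes = lapply(config$outcomes, function(d)
      list(name = d$name, components = d$components)),
    covariate_sets = as.list(config$covariate_sets),
    sets = config$sets,
    penalty = list(alpha = config$penalty$alpha,
                   lambda = config$penalty$lambda,
                   nfolds = config$penalty$nfolds,
                   nlambda = config$penalty$nlambda,
                   lambda_min_ratio = config$penalty$lambda_min_ratio,
                   penalize_interaction = config$penalty$penalize_interaction),
    n_boot = config$n_boot,
    include_hybrid = config$include_hybrid,
    seeds = config$seeds,
    cohort = list(n_subjects = config$cohort_cfg$n_subjects,
                  arm_ratio = config$cohort_cfg$arm_ratio,
                  missingness_rate = config$cohort_cfg$missingness_rate,
                  no_followup_rate = config$cohort_cfg$no_followup_rate,
                  seed = config$cohort_cfg$seed))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- yaml::read_yaml(path)
  outcomes <- lapply(obj$outcomes, function(d)
    outcome_definition(d$name, unlist(d$components)))
  names(outcomes) <- vapply(outcomes, `[[`, "", "name")
  pipeline_config(
    mode = obj$mode,
    cohort_file = obj$cohort_file,
    cohort_cfg = cohort_config(n_subjects = obj$cohort$n_subjects,
                               arm_ratio = obj$cohort$arm_ratio,
                               missingness_rate = obj$cohort$missingness_rate,
                               no_followup_rate = obj$cohort$no_followup_rate,
                               seed = obj$cohort$seed),
    t_star = obj$t_star,
    outcomes = outcomes,
    covariate_sets = unlist(obj$covariate_sets),
    sets = lapply(obj$sets, unlist),
    penalty = penalty_spec(alpha = obj$penalty$alpha,
                           lambda = obj$penalty$lambda,
                           nfolds = obj$penalty$nfolds,
                           nlambda = obj$penalty$nlambda,
                           lambda_min_ratio = obj$penalty$lambda_min_ratio,
                           penalize_interaction =
                             obj$penalty$penalize_interaction),
    n_boot = obj$n_boot,
    include_hybrid = obj$include_hybrid,
    seeds = obj$seeds)
}
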