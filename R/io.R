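#' Write a cohort to a comma-separated file
#'
#' Header schema: `id, arm, has_followup, [truth_eta,] time_<outcome>,
#' event_<outcome>, <covariates>`. Missing covariate values are written as
#' empty fields. Numeric values are written with 17 significant digits so a
#' write/read round trip reproduces every double exactly.
#'
#' @param cohort A `cohort` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)
  for (nm in names(out)) {
    if (is.double(out[[nm]])) {
      v <- sprintf("%.17g", out[[nm]])
      v[is.na(out[[nm]])] <- ""
      out[[nm]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Read a cohort from a comma-separated file
#'
#' Validates the header schema and domains (`event` columns in \{0, 1\},
#' times > 0, known arm labels); empty fields become missing values, never
#' zeros.
#'
#' @param path File written by [write_cohort()] or following its schema.
#' @return A `cohort` data frame.
#' @export
read_cohort <- function(path) {
  raw <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
  required <- c("id", "arm", "has_followup")
  miss <- setdiff(required, names(raw))
  if (length(miss))
    stop("cohort file lacks required column(s): ", paste(miss, collapse = ", "))
  time_cols <- grep("^time_", names(raw), value = TRUE)
  event_cols <- grep("^event_", names(raw), value = TRUE)
  outcomes <- sub("^time_", "", time_cols)
  if (!setequal(outcomes, sub("^event_", "", event_cols)))
    stop("time_/event_ columns do not pair up")
  if (!all(raw$arm %in% c("standard", "intensive"))) {
    bad <- which(!raw$arm %in% c("standard", "intensive"))[1]
    stop("unknown arm label at data row ", bad)
  }
  for (ec in event_cols) {
    bad <- which(!raw[[ec]] %in% c(0, 1))
    if (length(bad))
      stop("column ", ec, " not in {0,1} at data row ", bad[1])
  }
  for (tc in time_cols) {
    bad <- which(!(raw[[tc]] > 0))
    if (length(bad))
      stop("column ", tc, " must be > 0; violated at data row ", bad[1])
  }
  raw$arm <- factor(raw$arm, levels = c("standard", "intensive"))
  covs <- setdiff(names(raw),
                  c(required, "truth_eta", time_cols, event_cols))
  # restore the generator's column types: counts integer, values double
  for (nm in c("id", "has_followup", event_cols))
    raw[[nm]] <- as.integer(raw[[nm]])
  for (nm in c(time_cols, intersect(c("truth_eta", covs), names(raw))))
    if (is.numeric(raw[[nm]])) raw[[nm]] <- as.double(raw[[nm]])
  attr(raw, "outcomes") <- outcomes
  attr(raw, "covariate_names") <- covs
  class(raw) <- c("cohort", "data.frame")
  raw
}

#' Serialize a modified Cox fit to a structured text file
#'
#' Writes the standardization table, coefficient tables, baseline-hazard
#' steps and metadata as JSON (plain text).
#'
#' @param fit A `modified_cox_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  obj <- list(
    meta = list(outcome = fit$outcome, covariate_set = fit$covariate_set,
                lambda = fit$lambda_selected, alpha = fit$alpha,
                iterations = fit$iterations, converged = fit$converged,
                interaction_basis = fit$interaction_basis,
                n = fit$n, n_events = fit$n_events, t_max = fit$t_max),
    standardization = data.frame(column = fit$columns,
                                 center = unname(fit$center),
                                 scale = unname(fit$scale)),
    beta = data.frame(column = names(fit$beta), value = unname(fit$beta)),
    gamma = as.list(fit$gamma[!is.na(fit$gamma)]),
    delta = if (!is.null(fit$delta)) as.list(fit$delta),
    knots = fit$knots,
    baseline_cumhaz = as.data.frame(fit$baseline_cumhaz))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a serialized modified Cox fit
#'
#' @param path File written by [write_fit()].
#' @return A `modified_cox_fit` usable for prediction (without the training
#'   data vectors).
#' @export
read_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  gamma <- c(const = obj$gamma$const, eta = obj$gamma$eta,
             spline1 = if (!is.null(obj$gamma$spline1)) obj$gamma$spline1
             else NA_real_)
  structure(list(beta = stats::setNames(obj$beta$value, obj$beta$column),
                 center = stats::setNames(obj$standardization$center,
                                          obj$standardization$column),
                 scale = stats::setNames(obj$standardization$scale,
                                         obj$standardization$column),
                 columns = obj$standardization$column,
                 covariate_set = obj$meta$covariate_set,
                 outcome = obj$meta$outcome,
                 gamma = gamma,
                 delta = if (!is.null(obj$delta)) unlist(obj$delta),
                 knots = obj$knots, gvcov = NULL,
                 interaction_basis = obj$meta$interaction_basis,
                 baseline_cumhaz = structure(
                   as.data.frame(obj$baseline_cumhaz),
                   class = c("breslow_hazard", "data.frame")),
                 lambda_selected = obj$meta$lambda, alpha = obj$meta$alpha,
                 iterations = obj$meta$iterations,
                 converged = obj$meta$converged,
                 n = obj$meta$n, n_events = obj$meta$n_events,
                 t_max = obj$meta$t_max),
            class = "modified_cox_fit")
}
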