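# Efron-approximation Cox partial likelihood with first derivative and
# diagonal curvature with respect to the linear predictor. Used by the
# coordinate-descent elastic net (outer reweighting) and for the standalone
# log partial likelihood. Vectorized over subjects; the only loop collapses
# tied event times, so with continuous times the work is O(n log n).
#
# For event time k with d_k tied events D_k, risk set R_k, r_i = exp(lp_i):
#   phi_{k,l} = S_R(k) - (l/d_k) S_D(k),  l = 0, ..., d_k - 1
#   loglik    = sum_k [ sum_{i in D_k} lp_i - sum_l log phi_{k,l} ]
#   d loglik / d lp_i = d_i - r_i [ A(t_i) - b_{k(i)} 1(event_i) ]
#   -d2 loglik / d lp_i^2 = r_i [A - b 1(ev)] - r_i^2 [C(t_i) - e_{k(i)} 1(ev)]
# with A = cumulative sum of a_k = sum_l 1/phi over event times <= t_i,
# C the cumulative sum of c_k = sum_l 1/phi^2, and event-specific corrections
# b_k = sum_l (l/d)/phi, e_k = sum_l (2(l/d) - (l/d)^2)/phi^2.
cox_derivs <- function(time, status, lp) {
  n <- length(time)
  stopifnot(length(status) == n, length(lp) == n)
  if (!sum(status)) stop("no events: all subjects censored")
  o <- order(time)
  t_s <- time[o]; d_s <- status[o]
  lp_s <- lp[o] - mean(lp)  # shift-invariant; centered for overflow safety
  r <- exp(lp_s)
  rev_cum_r <- rev(cumsum(rev(r)))
  ev <- which(d_s == 1)
  ev_t <- t_s[ev]
  ut <- unique(ev_t)
  d_k <- as.vector(table(factor(ev_t, levels = ut)))
  S_R <- rev_cum_r[match(ut, t_s)]
  S_D <- as.vector(rowsum(r[ev], factor(ev_t, levels = ut)))
  kk <- rep(seq_along(ut), d_k)
  frac <- (sequence(d_k) - 1) / d_k[kk]
  phi <- S_R[kk] - frac * S_D[kk]
  gk <- factor(kk, levels = seq_along(ut))
  a_k <- as.vector(rowsum(1 / phi, gk))
  b_k <- as.vector(rowsum(frac / phi, gk))
  c_k <- as.vector(rowsum(1 / phi^2, gk))
  e_k <- as.vector(rowsum((2 * frac - frac^2) / phi^2, gk))
  pos <- findInterval(t_s, ut)
  cumA <- c(0, cumsum(a_k))[pos + 1]
  cumC <- c(0, cumsum(c_k))[pos + 1]
  ev_k <- match(ev_t, ut)
  M1 <- cumA; M1[ev] <- M1[ev] - b_k[ev_k]
  M2 <- cumC; M2[ev] <- M2[ev] - e_k[ev_k]
  u_s <- d_s - r * M1
  w_s <- pmax(r * M1 - r^2 * M2, 0)
  loglik <- sum(lp_s[ev]) - sum(log(phi))
  u <- numeric(n); w <- numeric(n)
  u[o] <- u_s; w[o] <- w_s
  list(loglik = loglik, u = u, w = w)
}

#' Cox log partial likelihood (Efron ties)
#'
#' Evaluates the log partial likelihood of a Cox proportional hazards model at
#' a given coefficient vector, using Efron's approximation for tied event
#' times. The value is invariant to adding a constant to any covariate
#' column.
#'
#' @param beta Coefficient vector (length = columns of `design`).
#' @param design Covariate matrix.
#' @param time Follow-up times (> 0).
#' @param event Event indicators in \{0, 1\}.
#' @param offset Optional linear-predictor offset.
#' @return The log partial likelihood (a scalar).
#' @export
cox_partial_loglik <- function(beta, design, time, event, offset = NULL) {
  design <- as.matrix(design)
  stopifnot(length(beta) == ncol(design))
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  if (any(time <= 0)) stop("time must be > 0")
  if (!sum(event)) stop("no events: all subjects censored")
  lp <- drop(design %*% beta)
  if (!is.null(offset)) lp <- lp + offset
  cox_derivs(time, event, lp)$loglik
}

#' Breslow baseline cumulative hazard
#'
#' Step-function estimate `H0(t) = sum_{event times <= t} d_k / sum_{risk set}
#' exp(lp)`, right-continuous and nondecreasing. With all linear predictors
#' zero this is the Nelson-Aalen estimator.
#'
#' @param time Follow-up times.
#' @param event Event indicators in \{0, 1\}.
#' @param lp Linear predictors (default all zero).
#' @return An object of class `breslow_hazard`: a data frame with columns
#'   `time` (ascending unique event times) and `hazard` (cumulative hazard),
#'   evaluable with [evaluate_hazard()].
#' @export
breslow_baseline <- function(time, event, lp = rep(0, length(time))) {
  stopifnot(length(event) == length(time), length(lp) == length(time))
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  o <- order(time)
  t_s <- time[o]; d_s <- event[o]
  r <- exp(lp[o] - max(lp))
  rev_cum_r <- rev(cumsum(rev(r)))
  ev_t <- t_s[d_s == 1]
  ut <- unique(ev_t)
  d_k <- as.vector(table(factor(ev_t, levels = ut)))
  S_R <- rev_cum_r[match(ut, t_s)] * exp(max(lp))
  structure(data.frame(time = ut, hazard = cumsum(d_k / S_R)),
            class = c("breslow_hazard", "data.frame"))
}

#' Evaluate a cumulative-hazard step function
#'
#' @param hazard A `breslow_hazard` object.
#' @param t Times at which to evaluate (right-continuous; 0 before the first
#'   event time, constant after the last).
#' @return Cumulative hazard values.
#' @export
evaluate_hazard <- function(hazard, t) {
  stopifnot(inherits(hazard, "breslow_hazard"))
  idx <- findInterval(t, hazard$time)
  c(0, hazard$hazard)[idx + 1]
}
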