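#' Kaplan-Meier fit of progression to clinical (stage 3) diabetes
#'
#' Product-limit estimate with Greenwood variance and 95% confidence
#' bounds computed on the log(-log) scale and back-transformed, so the
#' bounds stay inside [0, 1]. Time is measured in years from the initial
#' staging OGTT; a child is an event when stage 3 is reached and censored
#' at the final contact otherwise. Ties between events and censorings at
#' the same time are resolved events-first (the standard convention).
#'
#' The estimate itself is delegated to [survival::survfit()].
#'
#' @param times Non-negative follow-up times (years).
#' @param events Logical (or 0/1) event indicators.
#' @return A list of class `"km_curve"`: `time`, `n_risk`, `n_event`,
#'   `surv`, `greenwood_var`, `ci_low`, `ci_high`.
#' @export
km_fit <- function(times, events) {
  if (length(times) == 0) stop("empty survival input", call. = FALSE)
  if (length(times) != length(events)) {
    stop("times and events must have equal length", call. = FALSE)
  }
  if (any(times < 0)) stop("negative follow-up time", call. = FALSE)
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1,
                           conf.type = "log-log", conf.int = 0.95)
  # Greenwood variance of S(t): S^2 * sum d / (n (n - d))
  gw <- fit$surv^2 * cumsum(ifelse(fit$n.risk > fit$n.event,
                                   fit$n.event / (fit$n.risk * (fit$n.risk - fit$n.event)),
                                   0))
  structure(list(
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    surv = fit$surv,
    greenwood_var = gw,
    ci_low = ifelse(is.na(fit$lower) & fit$surv == 1, 1, fit$lower),
    ci_high = ifelse(is.na(fit$upper) & fit$surv == 1, 1, fit$upper)
  ), class = "km_curve")
}

#' Cumulative progression risk at a time point
#'
#' Reads 1 - S(t) off a [km_fit()] curve, using the last step at or before
#' `t`. The confidence interval is the transformed complement of the
#' survival interval. Requesting a time beyond the last observed
#' follow-up returns the value at the last step with `extrapolated = TRUE`.
#'
#' @param curve A `"km_curve"` object.
#' @param t Time in years, `t >= 0`.
#' @return A list with `risk`, `ci_low`, `ci_high`, `extrapolated`.
#' @export
risk_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  if (t < 0) stop("t must be non-negative", call. = FALSE)
  idx <- which(curve$time <= t)
  if (length(idx) == 0) {
    return(list(risk = 0, ci_low = 0, ci_high = 0, extrapolated = FALSE))
  }
  i <- max(idx)
  list(risk = 1 - curve$surv[i],
       ci_low = 1 - curve$ci_high[i],
       ci_high = 1 - curve$ci_low[i],
       extrapolated = t > max(curve$time))
}

#' Logrank test between survival groups
#'
#' Standard (unweighted) logrank test via [survival::survdiff()]; the
#' statistic is referred to a chi-square distribution with k - 1 degrees
#' of freedom for k groups.
#'
#' @param times,events As in [km_fit()].
#' @param group Group labels, at least two distinct values.
#' @return A list with `chisq`, `df`, `p`.
#' @export
logrank <- function(times, events, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2) {
    stop("logrank requires at least two non-empty groups", call. = FALSE)
  }
  sd <- survival::survdiff(survival::Surv(times, as.integer(events)) ~ group)
  df <- length(sd$n) - 1
  list(chisq = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Convert a 2-year risk to an annualised risk
#'
#' The annualised risk a satisfies 1 - (1 - a)^2 = R2, i.e.
#' a = 1 - sqrt(1 - R2): the constant per-year risk that compounds to the
#' observed 2-year risk.
#'
#' @param two_year_risk Probability in [0, 1).
#' @return Annualised risk, same scale.
#' @examples
#' round(100 * annualised_risk(0.48))  # 28
#' @export
annualised_risk <- function(two_year_risk) {
  if (any(two_year_risk < 0 | two_year_risk >= 1)) {
    stop("two_year_risk must be in [0, 1)", call. = FALSE)
  }
  1 - sqrt(1 - two_year_risk)
}
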