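#' Kaplan-Meier product-limit estimate
#'
#' Right-censored product-limit estimator, returned as an explicit step
#' function that [survival_at()] can evaluate. Estimation is delegated to
#' \code{survival::survfit}.
#'
#' @param times Follow-up times (months), >= 0.
#' @param events Event indicators (1 = event, 0 = censored).
#' @return Object of class `km_curve` with `time`, `surv` (step values
#'   after each event time), `n_risk`, `n_event`, and `n`.
#' @export
km_estimate <- function(times, events) {
  stopifnot(length(times) == length(events), length(times) >= 1,
            all(times >= 0))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, n = length(times)),
            class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve at a time point
#'
#' Step-function evaluation: survival just after `t_months`. S(0) = 1.
#' Beyond the last observed time the last value is carried forward and the
#' result is flagged via attribute `"extrapolated"`.
#'
#' @param km A `km_curve` from [km_estimate()].
#' @param t_months Time (months).
#' @return Survival probability; attribute `"extrapolated"` is `TRUE` when
#'   `t_months` exceeds the observed follow-up.
#' @export
survival_at <- function(km, t_months) {
  stopifnot(inherits(km, "km_curve"), t_months >= 0)
  idx <- which(km$time <= t_months)
  p <- if (length(idx)) km$surv[max(idx)] else 1
  out <- as.numeric(p)
  attr(out, "extrapolated") <- t_months > max(km$time)
  out
}

#' Log-rank test across survival groups
#'
#' Standard log-rank chi-square comparing two or more groups, with k - 1
#' degrees of freedom; delegated to \code{survival::survdiff}.
#'
#' @param times,events Pooled follow-up times and event indicators.
#' @param group Group labels (factor/vector), >= 2 nonempty groups.
#' @return List with `chisq`, `df`, `p`, and the per-group observed and
#'   expected event counts.
#' @export
logrank_test <- function(times, events, group) {
  group <- as.factor(group)
  group <- droplevels(group)
  if (nlevels(group) < 2) stop("log-rank test needs at least 2 groups")
  sd <- survival::survdiff(survival::Surv(times, events) ~ group)
  df <- nlevels(group) - 1
  list(chisq = as.numeric(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       observed = as.numeric(sd$obs), expected = as.numeric(sd$exp))
}

#' Log-rank optimal dichotomization cutoff
#'
#' Exhaustive maximally-selected log-rank scan: every midpoint between
#' consecutive distinct order statistics of `values` is a candidate cutoff;
#' candidates leaving either group below `min_group_frac * n` patients are
#' discarded; the cutoff maximizing the log-rank chi-square is returned
#' (ties resolved toward the smaller cutoff). Because the cutoff is
#' selected to maximize the statistic, the accompanying p-value is
#' optimistically biased; it is reported unadjusted, and downstream reports
#' carry that caveat.
#'
#' @param values Continuous marker values.
#' @param times,events Survival endpoint for the same patients.
#' @param min_group_frac Minimum fraction of patients in each group
#'   (0 disables the guard).
#' @return Object of class `cutoff_result`: `variable` (name attribute if
#'   supplied), `cutoff`, `direction` (`"le"` if the low side is high-risk,
#'   `"gt"` otherwise), `chisq`, `p`, `n_low`, `n_high`.
#' @export
find_cutoff <- function(values, times, events, min_group_frac = 0.1) {
  n <- length(values)
  stopifnot(length(times) == n, length(events) == n)
  sv <- sort(unique(values))
  if (length(sv) < 2) stop("constant variable: no cutoff exists")
  cand <- (sv[-1] + sv[-length(sv)]) / 2
  min_n <- ceiling(min_group_frac * n)
  best <- NULL
  for (cut in cand) {
    low <- values <= cut
    if (sum(low) < min_n || sum(!low) < min_n) next
    lr <- tryCatch(logrank_test(times, events, low), error = function(e) NULL)
    if (is.null(lr)) next
    if (is.null(best) || lr$chisq > best$chisq + 1e-12) {
      # direction: the side with more observed than expected deaths is
      # high-risk; survdiff group order is FALSE (high side) then TRUE
      excess_low <- lr$observed[2] - lr$expected[2]
      best <- list(cutoff = cut,
                   direction = if (excess_low >= 0) "le" else "gt",
                   chisq = lr$chisq, p = lr$p,
                   n_low = sum(low), n_high = sum(!low))
    }
  }
  if (is.null(best))
    stop("no admissible cutoff under min_group_frac = ", min_group_frac)
  structure(c(list(variable = deparse(substitute(values))), best),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("cutoff %.6g (%s side high-risk)  chisq %.3f  p %.4g  n %d/%d\n",
              x$cutoff, if (x$direction == "le") "low" else "high",
              x$chisq, x$p, x$n_low, x$n_high))
  cat("note: cutoff selected by maximizing the log-rank statistic;",
      "p is not adjusted for the selection\n")
  invisible(x)
}

#' Cox proportional-hazards regression
#'
#' Partial-likelihood Cox model with Efron tie handling (month-resolution
#' follow-up times routinely produce ties). Returns per-covariate hazard
#' ratios with Wald 95% confidence intervals and p-values.
#'
#' @param x Covariate matrix or data frame (no constant columns).
#' @param times,events Survival endpoint.
#' @return List with `coef` (data frame: term, hr, lower, upper, p,
#'   log_hr, se) and the underlying `coxph` fit.
#' @export
fit_cox <- function(x, times, events) {
  x <- as.data.frame(x)
  if (any(vapply(x, function(c) length(unique(c)) < 2, logical(1))))
    stop("constant covariate supplied to the Cox model")
  if (sum(events) < ncol(x))
    stop("fewer events (", sum(events), ") than covariates (", ncol(x), ")")
  dat <- cbind(x, .time = times, .event = events)
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(names(x), collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = "efron")
  s <- summary(fit)
  co <- s$coefficients
  ci <- s$conf.int
  res <- data.frame(term = rownames(co), log_hr = co[, "coef"],
                    se = co[, "se(coef)"], hr = ci[, "exp(coef)"],
                    lower = ci[, "lower .95"], upper = ci[, "upper .95"],
                    p = co[, ncol(co)], row.names = NULL,
                    stringsAsFactors = FALSE)
  if (any(!is.finite(res$se)) || any(res$se > 1e3))
    stop("Cox model unstable (possible separation); SE: ",
         paste(signif(res$se, 3), collapse = ", "))
  list(coef = res, fit = fit)
}
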