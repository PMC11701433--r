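#' @include AllClasses.R
NULL

#' Median-cutoff stratification
#'
#' Splits a cohort at the sample median of a continuous score: \code{Hi}
#' iff value >= median (midpoint convention for even n; ties at the
#' median go to \code{Hi}).
#'
#' @param values named numeric (sample -> value), n >= 2.
#' @return Named character vector of \code{"Hi"} / \code{"Lo"}.
#' @export
medianStratify <- function(values) {
  if (length(values) < 2L) stopf("need at least 2 values")
  if (length(unique(values)) == 1L)
    stopf("all values identical; median stratification undefined")
  med <- median(values)
  out <- ifelse(values >= med, "Hi", "Lo")
  names(out) <- names(values)
  out
}

#' Kaplan-Meier curve (product-limit estimator)
#'
#' Standard convention: at tied times, events precede censorings; the
#' curve starts at S(0) = 1 and is constant between event times.
#'
#' @param records data.frame with \code{time_months} and \code{event}.
#' @return List of class \code{KMCurve}: \code{time}, \code{n_risk},
#'   \code{n_event}, \code{n_censor}, \code{surv}.
#' @export
kmEstimate <- function(records) {
  if (!nrow(records)) stopf("no records")
  fit <- survival::survfit(
    survival::Surv(time_months, event) ~ 1,
    data = records, conf.type = "none")
  structure(list(time = fit$time, n_risk = fit$n.risk,
                 n_event = fit$n.event, n_censor = fit$n.censor,
                 surv = fit$surv),
            class = "KMCurve")
}

#' @export
print.KMCurve <- function(x, ...) {
  cat("Kaplan-Meier curve:", length(x$time), "time points,",
      sum(x$n_event), "events,", sum(x$n_censor), "censored\n")
  invisible(x)
}

#' Log-rank test across groups
#'
#' Observed-vs-expected test under the hypergeometric distribution at
#' each event time; df = number of groups - 1; p from the chi-square
#' upper tail.
#'
#' @param records data.frame with \code{time_months} and \code{event}.
#' @param group grouping vector (or the name of a column of
#'   \code{records}); at least 2 nonempty groups.
#' @return list with \code{chi2}, \code{df}, \code{p}.
#' @export
logrankTest <- function(records, group) {
  if (is.character(group) && length(group) == 1L) {
    if (!group %in% colnames(records))
      stopf("group column '%s' not found", group)
    group <- records[[group]]
  }
  if (length(unique(group)) < 2L) stopf("need at least 2 groups")
  if (sum(records$event) == 0L) stopf("no events in any group")
  g <- factor(group)
  sd <- survival::survdiff(
    survival::Surv(records$time_months, records$event) ~ g)
  df <- length(sd$n) - 1L
  list(chi2 = unname(sd$chisq), df = df,
       p = pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Univariate Cox proportional-hazards fit
#'
#' Partial-likelihood fit with Efron tie handling; Wald p-value and
#' normal-approximation 95% CI, \code{exp(log_hr +/- 1.96 se)}.
#'
#' @param records data.frame with \code{time_months}, \code{event} and the
#'   covariate column.
#' @param covariate covariate column name; must vary across records.
#' @return list of class \code{CoxFit}: \code{covariate}, \code{log_hr},
#'   \code{se}, \code{hr}, \code{ci95_lo}, \code{ci95_hi}, \code{p}.
#' @export
coxUnivariate <- function(records, covariate) {
  if (!covariate %in% colnames(records))
    stopf("covariate '%s' not found", covariate)
  x <- records[[covariate]]
  if (length(unique(x)) < 2L)
    stopf("covariate '%s' is constant", covariate)
  fml <- stats::as.formula(paste0(
    "survival::Surv(time_months, event) ~ `", covariate, "`"))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = records, ties = "efron",
                    control = survival::coxph.control(iter.max = 100L)),
    warning = function(w) {
      if (grepl("infinite|did not converge|Loglik converged before",
                conditionMessage(w)))
        stopf("Cox fit failed for '%s': %s", covariate,
              conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  beta <- unname(stats::coef(fit)[1L])
  se <- unname(sqrt(diag(stats::vcov(fit)))[1L])
  if (!is.finite(beta) || !is.finite(se) || abs(beta) > 15)
    stopf("Cox fit for '%s': monotone likelihood (separation)", covariate)
  structure(list(covariate = covariate, log_hr = beta, se = se,
                 hr = exp(beta),
                 ci95_lo = exp(beta - 1.96 * se),
                 ci95_hi = exp(beta + 1.96 * se),
                 p = 2 * pnorm(-abs(beta / se))),
            class = "CoxFit")
}

#' @export
print.CoxFit <- function(x, ...) {
  cat(sprintf("Cox fit [%s]: HR %.3f (95%% CI %.3f-%.3f), p = %.4g\n",
              x$covariate, x$hr, x$ci95_lo, x$ci95_hi, x$p))
  invisible(x)
}
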