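# Survival stratification of reclassified clusters: Kaplan-Meier curves,
# log-rank comparison, multivariate Cox regression. The numerics delegate
# to the survival package (product-limit estimator, survdiff, coxph with
# Breslow tie handling).

check_surv <- function(records) {
  records <- tibble::as_tibble(records)
  stopifnot(all(c("time_months", "event") %in% names(records)))
  if (any(records$time_months < 0)) abort("negative survival time")
  if (!all(records$event %in% c(0, 1))) abort("`event` must be 0/1")
  records
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator honoring right-censoring, overall or per group.
#'
#' @param records data frame with `time_months`, `event` (1 = event,
#'   0 = censored) and optionally the `by` column.
#' @param by optional grouping column name (e.g. `"group"`).
#' @return tibble: (group,) time, n_risk, n_event, n_censor, estimate,
#'   std_error, conf_low, conf_high.
#' @examples
#' km_estimate(data.frame(time_months = c(5, 8, 12, 20, 30),
#'                        event = c(1, 1, 0, 1, 0)))
#' @export
km_estimate <- function(records, by = NULL) {
  records <- check_surv(records)
  f <- if (is.null(by)) {
    survival::survfit(survival::Surv(time_months, event) ~ 1, data = records)
  } else {
    stopifnot(by %in% names(records))
    records$..group <- records[[by]]
    survival::survfit(survival::Surv(time_months, event) ~ ..group,
                      data = records)
  }
  s <- summary(f, censored = TRUE)
  out <- tibble::tibble(
    time = s$time, n_risk = s$n.risk, n_event = s$n.event,
    n_censor = s$n.censor, estimate = s$surv, std_error = s$std.err,
    conf_low = s$lower, conf_high = s$upper)
  if (!is.null(by)) {
    out <- dplyr::bind_cols(
      tibble::tibble(group = sub("^\\.\\.group=", "", as.character(s$strata))),
      out)
  }
  out
}

#' Log-rank test between survival groups
#'
#' @param records data frame with `time_months`, `event` and the grouping
#'   column.
#' @param by grouping column name (>= 2 groups required).
#' @return tibble: chi2, df, p_value.
#' @export
logrank_test <- function(records, by = "group") {
  records <- check_surv(records)
  stopifnot(by %in% names(records))
  g <- factor(records[[by]])
  if (nlevels(g) < 2L) abort("log-rank requires >= 2 groups")
  records$..group <- g
  d <- survival::survdiff(survival::Surv(time_months, event) ~ ..group,
                          data = records)
  df <- length(d$n) - 1L
  tibble::tibble(chi2 = d$chisq, df = df,
                 p_value = stats::pchisq(d$chisq, df, lower.tail = FALSE))
}

#' Multivariate Cox proportional-hazards regression
#'
#' Partial-likelihood fit with Breslow tie handling. Covariates without
#' variation are an error; suspected complete separation (diverging
#' coefficients) is flagged rather than silently reported.
#'
#' @param records data frame with `time_months`, `event` and covariates.
#' @param covariates character covariate column names.
#' @return tibble: term, estimate (log HR), hazard_ratio, conf_low,
#'   conf_high, p_value, flagged.
#' @export
cox_ph <- function(records, covariates) {
  records <- check_surv(records)
  stopifnot(all(covariates %in% names(records)))
  for (cv in covariates) {
    if (length(unique(records[[cv]])) < 2L) {
      abort(sprintf("covariate '%s' has no variation", cv))
    }
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(time_months, event) ~",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = records, ties = "breslow"),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite",
                conditionMessage(w))) {
        flagged <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  s <- summary(fit)
  ci <- s$conf.int
  tibble::tibble(
    term = rownames(s$coefficients),
    estimate = s$coefficients[, "coef"],
    hazard_ratio = s$coefficients[, "exp(coef)"],
    conf_low = ci[, "lower .95"],
    conf_high = ci[, "upper .95"],
    p_value = s$coefficients[, "Pr(>|z|)"],
    flagged = flagged | abs(s$coefficients[, "coef"]) > 10)
}
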