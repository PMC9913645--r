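## Kaplan-Meier estimation and log-rank comparison of predicted PD-1 groups.
## Wraps the survival package: product-limit estimate with Brookmeyer-Crowley
## (log(-log) transformed) confidence limits for the median, and the
## standard (O-E)^2/V chi-square log-rank test.

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator `S(t) = prod(1 - d_i/n_i)` over event times, with
#' the median survival time (first time at which `S(t) <= 0.5`) and its 95%
#' confidence interval via the log(-log) transformed Greenwood variance.
#' Deaths precede censorings at tied times (the standard convention). With
#' no censoring the estimate reduces to the empirical survivor function.
#'
#' @param time Positive survival times (months).
#' @param event Event indicator (1 = observed death/relapse, 0 = censored).
#' @param conf_level Confidence level for the median interval.
#' @return List of class `"km_curve"`: `time`, `surv`, `n_risk`, `n_event`
#'   at each observed time, plus `median`, `median_lower`, `median_upper`
#'   (`NA` when the curve never reaches 0.5: median not reached).
#' @export
km_estimate <- function(time, event, conf_level = 0.95) {
  if (any(time <= 0) || !all(event %in% c(0, 1)))
    stop("times must be positive and events 0/1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "log-log", conf.int = conf_level)
  tab <- summary(fit)$table
  ## first time at which the curve drops to 0.5 or below
  med_idx <- which(fit$surv <= 0.5 + 1e-12)
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event,
                 median = if (length(med_idx)) fit$time[min(med_idx)] else NA_real_,
                 median_lower = unname(tab[grep("LCL", names(tab))]),
                 median_upper = unname(tab[grep("UCL", names(tab))]),
                 conf_level = conf_level),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier estimate\n")
  if (is.na(x$median)) {
    cat("  median survival: not reached\n")
  } else {
    cat(sprintf("  median survival: %.2f (%.0f%% CI %.2f-%.2f)\n",
                x$median, 100 * x$conf_level,
                ifelse(is.na(x$median_lower), NA, x$median_lower),
                ifelse(is.na(x$median_upper), NA, x$median_upper)))
  }
  invisible(x)
}

#' @export
plot.km_curve <- function(x, ...) {
  t <- c(0, rep(x$time, each = 2))
  s <- c(1, 1, rep(x$surv, each = 2)[-(2 * length(x$surv))])
  graphics::plot(t, s, type = "l", ylim = c(0, 1), xlab = "Time (months)",
                 ylab = "Survival probability", ...)
  invisible(x)
}

#' Log-rank test between two groups
#'
#' Standard one-degree-of-freedom chi-square `(O-E)^2/V` over the pooled
#' event times; the statistic is invariant to monotone relabeling of the
#' time axis.
#'
#' @param time,event As in [km_estimate()].
#' @param group Binary group membership (e.g. predicted PD-1 status).
#' @return List of class `"logrank_result"`: `chisq` (1 df) and two-sided `p`.
#' @export
log_rank <- function(time, event, group) {
  if (length(unique(group)) != 2) stop("exactly two groups required")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group)
  structure(list(chisq = unname(sd_$chisq),
                 p = stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE)),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.3f (1 df), p = %.4g\n",
              x$chisq, x$p))
  invisible(x)
}

#' Survival comparison of predicted groups
#'
#' Kaplan-Meier curves per predicted class plus the log-rank comparison,
#' the package's analogue of comparing overall or recurrence-free survival
#' between predicted PD-1-positive and PD-1-negative patients.
#'
#' @param time,event As in [km_estimate()].
#' @param group Binary predicted class (or true labels, if preferred).
#' @return List with `curves` (list of two `km_curve`s, names `"0"`/`"1"`)
#'   and `logrank`.
#' @export
survival_by_group <- function(time, event, group) {
  structure(list(curves = list(`0` = km_estimate(time[group == 0], event[group == 0]),
                               `1` = km_estimate(time[group == 1], event[group == 1])),
                 logrank = log_rank(time, event, group)),
            class = "rtn_survfit")
}

#' @export
print.rtn_survfit <- function(x, ...) {
  cat("Group 0: "); print(x$curves[[1]])
  cat("Group 1: "); print(x$curves[[2]])
  print(x$logrank)
  invisible(x)
}
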