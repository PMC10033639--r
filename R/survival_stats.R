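## Kaplan-Meier estimation and two-group log-rank testing, wrapping the
## survival package's product-limit machinery with the median convention
## used in preclinical reporting (smallest time with S(t) <= 0.5,
## "undefined" when the curve never reaches 0.5).

validate_survival_table <- function(tab) {
  need <- c("time", "event", "group")
  if (!is.data.frame(tab) || !all(need %in% names(tab))) {
    stop("survival table needs columns: time, event, group",
         call. = FALSE)
  }
  if (any(tab$time < 0) || anyNA(tab$time)) {
    stop("times must be nonnegative", call. = FALSE)
  }
  if (!all(tab$event %in% c(0L, 1L))) {
    stop("event must be 0 (censored) or 1 (event)", call. = FALSE)
  }
  tab
}

#' Kaplan-Meier fit for one group
#'
#' Product-limit estimator; at tied times events are processed before
#' censorings (the usual convention). The median is the smallest time
#' with S(t) <= 0.5, reported as NA ("undefined") when the curve never
#' drops to 0.5.
#'
#' @param tab Survival table data frame: \code{time}, \code{event}
#'   (1 = event, 0 = censored), \code{group} (and optionally
#'   \code{subject_id}).
#' @param group Group label to fit; \code{NULL} fits all rows together.
#' @return Object of class \code{km_estimate}: \code{time},
#'   \code{surv}, \code{n_risk}, \code{n_event} at each distinct event
#'   or censoring time, plus \code{median} and \code{n}.
#' @export
km_fit <- function(tab, group = NULL) {
  tab <- validate_survival_table(tab)
  if (!is.null(group)) {
    tab <- tab[tab$group == group, , drop = FALSE]
    if (nrow(tab) == 0L) stop("empty group: ", group, call. = FALSE)
  }
  fit <- survival::survfit(
    survival::Surv(time, event) ~ 1, data = tab,
    conf.type = "none")
  med <- if (any(fit$surv <= 0.5)) {
    min(fit$time[fit$surv <= 0.5])
  } else NA_real_
  structure(list(time = fit$time, surv = fit$surv,
                 n_risk = fit$n.risk, n_event = fit$n.event,
                 median = med, n = nrow(tab),
                 group = if (is.null(group)) "all" else group),
            class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate: group %s, n = %d, median = %s\n",
              x$group, x$n,
              if (is.na(x$median)) "undefined" else
                format(x$median)))
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected statistic with hypergeometric
#' variance summed over distinct event times; two-sided p from
#' chi-square with 1 degree of freedom.
#'
#' @param tab Survival table.
#' @param group_a,group_b The two group labels to compare.
#' @return List: \code{chisq}, \code{df} (1), \code{p}, per-group
#'   \code{observed} and \code{expected} event counts.
#' @export
logrank <- function(tab, group_a, group_b) {
  tab <- validate_survival_table(tab)
  tab <- tab[tab$group %in% c(group_a, group_b), , drop = FALSE]
  if (!all(c(group_a, group_b) %in% tab$group)) {
    stop("both groups must have at least one subject", call. = FALSE)
  }
  if (sum(tab$event) == 0L) {
    stop("no events in either group", call. = FALSE)
  }
  sd <- survival::survdiff(
    survival::Surv(time, event) ~ group, data = tab, rho = 0)
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  list(chisq = unname(sd$chisq), df = 1L, p = p,
       observed = sd$obs, expected = sd$exp)
}
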