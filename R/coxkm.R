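#' Cox proportional-hazards fit for a binary carrier indicator
#'
#' Fits the Cox partial likelihood for a single binary covariate
#' (carrier vs comparison) via [survival::coxph()], with Breslow tie
#' handling by default, and reports the hazard ratio of carriers
#' relative to the comparison group with its Wald p-value.  When one
#' group carries no events the partial likelihood is monotone and the
#' numeric estimate meaningless; the fit is then flagged degenerate and
#' the hazard ratio reported qualitatively as `"<1"` (no carrier
#' events: carriers look protected) or `">1"` (no comparison events:
#' carriers look at risk).
#'
#' @param time non-negative follow-up times in days.
#' @param event logical event indicators.
#' @param group logical carrier indicators.
#' @param ties tie-handling method passed to [survival::coxph()]
#'   (`"breslow"` default, `"efron"` available).
#' @return an object of class `cox_fit`: a list with `log_hr`, `hr`,
#'   `se`, `p`, `hr_label` (formatted estimate or `"<1"`/`">1"`),
#'   `events` (named count per group) and `degenerate` (one of
#'   `"none"`, `"no_events"`, `"no_events_in_group"`,
#'   `"nonconvergence"`).
#' @export
cox_fit <- function(time, event, group, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  chk <- check_surv_sample(time, event, group)
  time <- chk$time; event <- chk$event; group <- chk$group
  if (is.null(group)) stop("group is required")
  d1 <- sum(event & group)
  d0 <- sum(event & !group)
  base <- list(log_hr = NA_real_, hr = NA_real_, se = NA_real_,
               p = NA_real_, hr_label = NA_character_,
               events = c(with = d1, without = d0), ties = ties)
  if (d1 + d0 == 0) {
    base$degenerate <- "no_events"
    return(structure(base, class = "cox_fit"))
  }
  if (d1 == 0 || d0 == 0) {
    base$degenerate <- "no_events_in_group"
    base$hr_label <- if (d1 == 0) "<1" else ">1"
    return(structure(base, class = "cox_fit"))
  }
  fit <- tryCatch(
    suppressWarnings(survival::coxph(
      survival::Surv(time, event) ~ g,
      data = data.frame(time = time, event = event, g = as.numeric(group)),
      ties = ties)),
    error = function(e) NULL)
  if (is.null(fit) || is.na(stats::coef(fit))) {
    base$degenerate <- "nonconvergence"
    return(structure(base, class = "cox_fit"))
  }
  beta <- unname(stats::coef(fit))
  se <- unname(sqrt(diag(fit$var)))[1]
  degenerate <- if (abs(beta) > 15 || se > 100) "nonconvergence" else "none"
  structure(list(
    log_hr = beta, hr = exp(beta), se = se,
    p = 2 * stats::pnorm(-abs(beta / se)),
    hr_label = formatC(exp(beta), digits = 3, format = "g"),
    events = c(with = d1, without = d0), ties = ties,
    degenerate = degenerate
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox fit (binary carrier covariate,", x$ties, "ties)\n")
  if (x$degenerate %in% c("no_events", "no_events_in_group")) {
    cat("  degenerate:", x$degenerate, "- HR",
        if (is.na(x$hr_label)) "undetermined" else x$hr_label, "\n")
  } else {
    cat(sprintf("  HR = %.3f (log HR %.3f, se %.3f), Wald p = %.4g%s\n",
                x$hr, x$log_hr, x$se, x$p,
                if (x$degenerate == "nonconvergence")
                  " [nonconvergence]" else ""))
  }
  cat(sprintf("  events: %d carriers / %d comparison\n",
              x$events[["with"]], x$events[["without"]]))
  invisible(x)
}

#' Kaplan-Meier product-limit estimate
#'
#' Wraps [survival::survfit()] for a single group and extracts the step
#' function, numbers at risk and the median survival, defined as the
#' smallest time at which the survival probability drops to 0.5 or
#' below (absent when the curve never reaches 0.5).
#'
#' @param time non-negative follow-up times in days.
#' @param event logical event indicators.
#' @return an object of class `km_curve`: a list with `time` (step
#'   times, starting at 0), `surv` (survival probabilities, starting at
#'   1), `n_risk`, `n_event` and `median` (`NA` when undefined).
#' @export
km_estimate <- function(time, event) {
  chk <- check_surv_sample(time, event)
  time <- chk$time; event <- chk$event
  stopifnot(length(time) >= 1)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1,
                          data = data.frame(time = time, event = event))
  med <- sf$time[which(sf$surv <= 0.5 + 1e-12)[1]]
  structure(list(
    time = c(0, sf$time), surv = c(1, sf$surv),
    n_risk = c(length(time), sf$n.risk), n_event = c(0, sf$n.event),
    median = if (length(med) && !is.na(med)) med else NA_real_,
    n = length(time), d = sum(event)
  ), class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, events = %d, median survival %s\n",
              x$n, x$d,
              if (is.na(x$median)) "not reached"
              else paste0(format(x$median), " days")))
  invisible(x)
}

#' @export
as.data.frame.km_curve <- function(x, ...) {
  data.frame(time = x$time, surv = x$surv, n_risk = x$n_risk,
             n_event = x$n_event)
}

#' @export
plot.km_curve <- function(x, add = FALSE, col = 1, ...) {
  if (!add)
    graphics::plot(NA, xlim = range(x$time), ylim = c(0, 1),
                   xlab = "days", ylab = "survival probability", ...)
  graphics::lines(stats::stepfun(x$time[-1], x$surv), do.points = FALSE,
                  col = col)
  invisible(x)
}
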