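#' Survival comparison of a rare carrier group against a comparison group
#'
#' The central test of the package: compares the overall survival of a
#' (typically small) carrier group against a comparison group using
#' three routes at once --
#' * the signed log-rank statistic `L` with its classical
#'   \eqn{\chi^2_1} p-value ([logrank_statistic()], [asymptotic_p()]),
#' * a two-sided empirical p-value of `L` under the exact conditional
#'   null tabulated by [exact_null()], which remains valid for heavily
#'   unbalanced groups where the \eqn{\chi^2} approximation fails, and
#' * a Cox proportional-hazards fit giving the hazard ratio
#'   ([cox_fit()]).
#'
#' Kaplan-Meier curves of both groups are attached for reporting.
#'
#' @param x follow-up times (numeric), or a formula
#'   `survival::Surv(time, event) ~ group`.
#' @param ... further arguments passed to methods.
#' @return an object of class `hotspot_surv_test`; see
#'   [print.hotspot_surv_test()] and [summary.hotspot_surv_test()].
#' @examples
#' set.seed(7)
#' toy <- data.frame(time = rexp(60, 1 / 1000),
#'                   event = runif(60) < 0.7,
#'                   carrier = rep(c(TRUE, FALSE), c(5, 55)))
#' fit <- hotspot_surv_test(survival::Surv(time, event) ~ carrier,
#'                          data = toy, seed = 1)
#' fit
#' @export
hotspot_surv_test <- function(x, ...) UseMethod("hotspot_surv_test")

#' @rdname hotspot_surv_test
#' @param formula a formula `survival::Surv(time, event) ~ group` with
#'   a single logical/two-level grouping term; the smaller group is
#'   taken as the carrier group.
#' @param data a `data.frame` in which the formula is evaluated.
#' @export
hotspot_surv_test.formula <- function(formula, data = parent.frame(), ...) {
  mf <- stats::model.frame(formula, data = data)
  y <- mf[[1]]
  if (!survival::is.Surv(y))
    stop("left-hand side must be a survival::Surv(time, event) object")
  g <- mf[[2]]
  if (is.factor(g) || is.character(g)) {
    lev <- unique(as.character(g))
    if (length(lev) != 2) stop("grouping term must have two levels")
    sz <- table(as.character(g))
    g <- as.character(g) == names(sz)[which.min(sz)]
  }
  out <- hotspot_surv_test.default(as.numeric(y[, "time"]),
                                   y[, "status"] == 1, as.logical(g), ...)
  out$call <- match.call()
  out
}

#' @rdname hotspot_surv_test
#' @param time non-negative follow-up times in days.
#' @param event logical event indicators (`TRUE` = death observed).
#' @param group logical carrier indicators (`TRUE` = carrier/minority).
#' @param enum_limit,n_perm_per_stratum,seed passed to [exact_null()].
#' @param ties Cox tie handling, see [cox_fit()].
#' @export
hotspot_surv_test.default <- function(x, event, group, time = x,
                                      enum_limit = 1e5,
                                      n_perm_per_stratum = 1e4,
                                      seed = NULL, ties = "breslow", ...) {
  chk <- check_surv_sample(time, event, group)
  time <- chk$time; event <- chk$event; group <- chk$group
  if (is.null(group)) stop("group is required")
  n1 <- sum(group)
  if (n1 == 0 || n1 == length(time))
    stop("no valid comparison: both groups must be non-empty")
  lr <- logrank_statistic(time, event, group)
  nd <- exact_null(time, event, n1 = n1, enum_limit = enum_limit,
                   n_perm_per_stratum = n_perm_per_stratum, seed = seed)
  structure(list(
    L = lr$L, V = lr$V,
    p_asymptotic = asymptotic_p(lr$L, lr$V),
    p_empirical = empirical_p(nd, lr$L),
    null = nd,
    cox = cox_fit(time, event, group, ties = ties),
    km = list(with = km_estimate(time[group], event[group]),
              without = km_estimate(time[!group], event[!group])),
    n = lr$n, n1 = lr$n1, d = lr$d,
    events = c(with = sum(event & group), without = sum(event & !group)),
    no_events = lr$no_events,
    call = match.call()
  ), class = "hotspot_surv_test")
}

#' @export
print.hotspot_surv_test <- function(x, digits = 4, ...) {
  cat("Carrier-group survival comparison\n")
  cat(sprintf("  groups: %d carriers vs %d comparison (%d + %d events)\n",
              x$n1, x$n - x$n1, x$events[["with"]], x$events[["without"]]))
  cat(sprintf("  log-rank L = %.4f (V = %.4f)\n", x$L, x$V))
  cat(sprintf("  p (empirical null) = %s | p (chi-squared) = %s | p (Cox Wald) = %s\n",
              format(x$p_empirical, digits = digits),
              format(x$p_asymptotic, digits = digits),
              if (is.na(x$cox$p)) "NA" else format(x$cox$p, digits = digits)))
  hr <- if (!is.na(x$cox$hr_label)) x$cox$hr_label else "NA"
  cat(sprintf("  hazard ratio (carriers vs comparison): %s\n", hr))
  invisible(x)
}

#' Detailed summary of a carrier-group survival comparison
#'
#' @param object a `hotspot_surv_test`.
#' @param ... unused.
#' @return an object of class `summary.hotspot_surv_test` printing the
#'   group sizes, event counts, median survivals, all three p-values
#'   and the hazard ratio.
#' @export
summary.hotspot_surv_test <- function(object, ...) {
  structure(list(
    n = object$n, n1 = object$n1, events = object$events,
    median_with = object$km$with$median,
    median_without = object$km$without$median,
    L = object$L, V = object$V,
    p_empirical = object$p_empirical,
    p_asymptotic = object$p_asymptotic,
    p_cox = object$cox$p, hr = object$cox$hr,
    hr_label = object$cox$hr_label,
    degenerate = object$cox$degenerate,
    null_mode = object$null$mode
  ), class = "summary.hotspot_surv_test")
}

#' @export
print.summary.hotspot_surv_test <- function(x, ...) {
  fm <- function(v) if (is.na(v)) "not reached" else paste(format(v), "days")
  cat("Carrier-group survival comparison\n")
  cat(sprintf("  carriers:   n = %4d, events = %3d, median survival %s\n",
              x$n1, x$events[["with"]], fm(x$median_with)))
  cat(sprintf("  comparison: n = %4d, events = %3d, median survival %s\n",
              x$n - x$n1, x$events[["without"]], fm(x$median_without)))
  cat(sprintf("  log-rank L = %.4f, V = %.4f (null: %s)\n",
              x$L, x$V, x$null_mode))
  cat(sprintf("  p empirical = %.4g | p chi-squared = %.4g | p Cox = %s\n",
              x$p_empirical, x$p_asymptotic,
              if (is.na(x$p_cox)) "NA" else format(x$p_cox, digits = 4)))
  cat(sprintf("  HR = %s%s\n",
              if (is.na(x$hr_label)) "NA" else x$hr_label,
              if (x$degenerate != "none")
                paste0(" (degenerate: ", x$degenerate, ")") else ""))
  invisible(x)
}

#' @export
coef.hotspot_surv_test <- function(object, ...) {
  c(log_hr = object$cox$log_hr)
}

#' @export
confint.hotspot_surv_test <- function(object, parm = "log_hr",
                                      level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- object$cox$log_hr
  se <- object$cox$se
  out <- matrix(c(est - z * se, est + z * se), nrow = 1,
                dimnames = list("log_hr",
                                sprintf("%.1f %%", c((1 - level) / 2,
                                                     1 - (1 - level) / 2) * 100)))
  out
}

#' Plot a carrier-group survival comparison
#'
#' Left panel: Kaplan-Meier curves of carriers (red) and comparison
#' group (blue).  Right panel: the tabulated null distribution of the
#' signed log-rank statistic with the observed value marked.
#'
#' @param x a `hotspot_surv_test`.
#' @param which `"both"`, `"km"` or `"null"`.
#' @param ... passed to the panel plot functions.
#' @return invisibly `x`.
#' @export
plot.hotspot_surv_test <- function(x, which = c("both", "km", "null"), ...) {
  which <- match.arg(which)
  if (which == "both") {
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
  }
  if (which %in% c("both", "km")) {
    plot(x$km$without, col = "blue3",
         main = sprintf("KM: %d vs %d", x$n1, x$n - x$n1), ...)
    plot(x$km$with, add = TRUE, col = "red3")
    graphics::legend("bottomleft", bty = "n", col = c("red3", "blue3"),
                     lwd = 1, legend = c("carriers", "comparison"))
  }
  if (which %in% c("both", "null"))
    plot(x$null, L_obs = x$L, ...)
  invisible(x)
}
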