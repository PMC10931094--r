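#' Signed log-rank statistic for a two-group comparison
#'
#' Computes the signed log-rank score
#' \deqn{L = \sum_j \left( O_{1j} - d_j r_{1j} / r_j \right)}
#' over the distinct event times \eqn{t_j}, where \eqn{d_j} is the
#' number of events at \eqn{t_j}, \eqn{r_j} the number at risk and
#' \eqn{O_{1j}}, \eqn{r_{1j}} the corresponding counts in the minority
#' (carrier) group, together with the hypergeometric variance
#' \deqn{V = \sum_j d_j \frac{r_{1j}}{r_j}
#'   \left(1 - \frac{r_{1j}}{r_j}\right) \frac{r_j - d_j}{r_j - 1}.}
#' Ties in event times are handled through the multiplicity terms.
#' \eqn{L > 0} means more events than expected in the carrier group
#' (worse survival).
#'
#' @param time non-negative follow-up times in days.
#' @param event logical event indicators (`TRUE` = death observed).
#' @param group logical group indicators (`TRUE` = minority/carrier).
#' @return a list with elements `L`, `V`, `n`, `n1`, `d` and
#'   `no_events` (`TRUE` when the data carry no event, in which case
#'   `L = V = 0`).
#' @seealso [asymptotic_p()], [exact_null()]
#' @export
logrank_statistic <- function(time, event, group) {
  chk <- check_surv_sample(time, event, group)
  time <- chk$time; event <- chk$event; group <- chk$group
  d <- sum(event)
  if (d == 0)
    return(list(L = 0, V = 0, n = length(time), n1 = sum(group), d = 0L,
                no_events = TRUE))
  tj <- sort(unique(time[event]))
  st <- sort(time)
  rj <- length(time) - findInterval(tj, st, left.open = TRUE)
  dj <- vapply(tj, function(t) sum(event & time == t), numeric(1))
  r1 <- vapply(tj, function(t) sum(group & time >= t), numeric(1))
  o1 <- vapply(tj, function(t) sum(group & event & time == t), numeric(1))
  L <- sum(o1 - dj * r1 / rj)
  vterm <- ifelse(rj > 1,
                  dj * (r1 / rj) * (1 - r1 / rj) * (rj - dj) / (rj - 1), 0)
  list(L = L, V = sum(vterm), n = length(time), n1 = sum(group),
       d = as.integer(d), no_events = FALSE)
}

#' Asymptotic (chi-squared) log-rank p-value
#'
#' The classical large-sample p-value: the upper tail of a
#' \eqn{\chi^2_1} distribution at \eqn{L^2/V}.  This approximation
#' assumes large and reasonably balanced groups; for rare-carrier
#' comparisons it can be badly off, which is why [exact_null()] exists.
#'
#' @param L signed log-rank statistic.
#' @param V its variance estimate (`>= 0`).
#' @return p-value in `[0, 1]`; exactly 1 when `V = 0` (no
#'   information).
#' @export
asymptotic_p <- function(L, V) {
  stopifnot(V >= 0)
  if (V == 0) return(1)
  stats::pchisq(L^2 / V, df = 1, lower.tail = FALSE)
}

# validate and coerce a survival sample; shared by the statistics
check_surv_sample <- function(time, event, group = NULL) {
  time <- as.numeric(time)
  event <- as.logical(event)
  if (length(time) != length(event))
    stop("time and event must have equal length")
  if (anyNA(time) || anyNA(event))
    stop("time/event must not contain NA")
  if (any(time < 0)) stop("negative survival time")
  if (!is.null(group)) {
    group <- as.logical(group)
    if (length(group) != length(time))
      stop("group must have the same length as time")
    if (anyNA(group)) stop("group must not contain NA")
  }
  list(time = time, event = event, group = group)
}

# additive per-patient log-rank contributions: with H the cumulative
# event-rate step function H(t) = sum_{t_j <= t} d_j / r_j, the signed
# statistic of any group assignment g is L(g) = sum_{i in g} c_i with
# c_i = event_i - H(time_i).  This linearity is what makes exhaustive
# and stratified tabulation of the null cheap.
logrank_scores <- function(time, event) {
  n <- length(time)
  if (!any(event)) return(numeric(n))
  tj <- sort(unique(time[event]))
  st <- sort(time)
  rj <- n - findInterval(tj, st, left.open = TRUE)
  dj <- vapply(tj, function(t) sum(event & time == t), numeric(1))
  H <- cumsum(dj / rj)
  idx <- findInterval(time, tj)
  as.numeric(event) - c(0, H)[idx + 1L]
}
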