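#' Person-time rates, exact rate ratios, and 5-year risks
#'
#' Incident rates count each child's first qualifying event with person-time
#' truncated at that event; all-event rates count every event over full
#' follow-up. Rate-ratio confidence intervals and p-values use the exact
#' conditional-binomial construction: given the total count, the exposed
#' count is binomial with success probability determined by the rate ratio
#' and the person-time split, and the Clopper-Pearson interval for that
#' binomial probability is transformed back to the rate-ratio scale.
#'
#' @name rates
#' @keywords internal
NULL

#' Count events and person-time per exposure group
#'
#' @param events data.frame with `child_id`, `age_days`, `setting`.
#' @param cohort data.frame of children with `child_id`, `exposure`,
#'   `age_end_days`, `person_years` (see [define_followup()]).
#' @param kind `"incident"` (first event per child, person-time censored at
#'   it) or `"all"` (every event, full person-time).
#' @param setting optional character vector; only events whose `setting` is
#'   in it are counted (e.g. `c("inpatient", "outpatient")` for hospital
#'   visits combined). Incident censoring applies at the first event of the
#'   filtered settings.
#' @return data.frame with one row per group (`exposed`, `comparator`):
#'   `count`, `person_years`.
#' @export
count_events <- function(events, cohort, kind = c("incident", "all"),
                         setting = NULL) {
  kind <- match.arg(kind)
  if (!is.null(setting)) events <- events[events$setting %in% setting, ,
                                          drop = FALSE]
  events <- events[events$child_id %in% cohort$child_id, , drop = FALSE]
  end <- cohort$age_end_days[match(events$child_id, cohort$child_id)]
  if (any(events$age_days > end))
    stop("event outside follow-up window (upstream bug)", call. = FALSE)
  grp <- ifelse(cohort$exposure, "exposed", "comparator")

  if (kind == "all") {
    cnt <- tapply(rep(1L, nrow(events)),
                  factor(ifelse(cohort$exposure[match(events$child_id,
                                                      cohort$child_id)],
                                "exposed", "comparator"),
                         levels = c("exposed", "comparator")),
                  sum, default = 0L)
    pt <- tapply(cohort$person_years,
                 factor(grp, levels = c("exposed", "comparator")), sum)
    return(data.frame(group = c("exposed", "comparator"),
                      count = as.integer(cnt[c("exposed", "comparator")]),
                      person_years = as.numeric(pt[c("exposed",
                                                     "comparator")])))
  }
  # incident: first filtered event per child; censor person-time there
  first <- tapply(events$age_days, events$child_id, min)
  first_of <- first[as.character(cohort$child_id)]
  has <- !is.na(first_of)
  pt_days <- ifelse(has, pmin(first_of, cohort$age_end_days),
                    cohort$age_end_days)
  f <- factor(grp, levels = c("exposed", "comparator"))
  cnt <- tapply(as.integer(has), f, sum)
  pt <- tapply(pt_days / .DAYS_PER_YEAR, f, sum)
  data.frame(group = c("exposed", "comparator"),
             count = as.integer(cnt[c("exposed", "comparator")]),
             person_years = as.numeric(pt[c("exposed", "comparator")]))
}

#' Exact rate ratio with conditional-binomial confidence interval
#'
#' With counts \eqn{c_1, c_0} over person-times \eqn{T_1, T_0}, condition on
#' \eqn{c_1 + c_0}: \eqn{c_1} is binomial with success probability
#' \eqn{\pi = RR\,T_1 / (RR\,T_1 + T_0)}. The Clopper-Pearson interval for
#' \eqn{\pi} maps monotonically to an exact interval for the rate ratio,
#' and the exact two-sided p-value for RR = 1 is the binomial test of
#' \eqn{c_1} at \eqn{\pi_0 = T_1/(T_1+T_0)}.
#'
#' @param c1,pt1 exposed count and person-years.
#' @param c0,pt0 comparator count and person-years.
#' @param conf.level confidence level, default 0.95.
#' @return list of class `rate_result`: `rate1`, `rate0`, `rr`, `lower`,
#'   `upper`, `p.value`, plus the inputs. `upper` is `Inf` (flagged via
#'   `note`) when `c0 = 0`.
#' @export
rate_ratio_exact <- function(c1, pt1, c0, pt0, conf.level = 0.95) {
  stopifnot(pt1 > 0, pt0 > 0, c1 >= 0, c0 >= 0, c1 + c0 >= 1)
  alpha <- 1 - conf.level
  n <- c1 + c0
  # Clopper-Pearson bounds for the conditional binomial probability
  piL <- if (c1 == 0) 0 else stats::qbeta(alpha / 2, c1, c0 + 1)
  piU <- if (c0 == 0) 1 else stats::qbeta(1 - alpha / 2, c1 + 1, c0)
  to_rr <- function(pi) if (pi >= 1) Inf else (pi / (1 - pi)) * (pt0 / pt1)
  p0 <- pt1 / (pt1 + pt0)
  structure(list(
    c1 = c1, pt1 = pt1, c0 = c0, pt0 = pt0,
    rate1 = c1 / pt1, rate0 = c0 / pt0,
    rr = (c1 / pt1) / (c0 / pt0),
    lower = to_rr(piL), upper = to_rr(piU),
    p.value = stats::binom.test(c1, n, p0)$p.value,
    conf.level = conf.level,
    note = if (c0 == 0) "comparator count 0: upper bound infinite" else NULL),
    class = "rate_result")
}

#' @export
print.rate_result <- function(x, ...) {
  cat(sprintf(
    "rate ratio %.2f (%.0f%% CI %.2f-%s), p = %.3g\n  rates %.4g vs %.4g per person-year (%d/%.1f vs %d/%.1f)\n",
    x$rr, 100 * x$conf.level, x$lower,
    if (is.finite(x$upper)) sprintf("%.2f", x$upper) else "Inf",
    x$p.value, x$rate1, x$rate0, x$c1, x$pt1, x$c0, x$pt0))
  invisible(x)
}

#' 5-year risks, risk ratio, and risk difference from counts
#'
#' Risks are percentages of cohort children with at least one qualifying
#' event within five years; the ratio and difference are computed on the
#' unrounded risks (display rounding to 2 decimals is applied by the report
#' writers, not here).
#'
#' @param c1,n1 exposed children with the event, exposed cohort size.
#' @param c0,n0 comparator children with the event, comparator cohort size.
#' @return list of class `risk_result`: `risk1`, `risk0` (percent), `rr`,
#'   `rd` (percentage points). `rr` is `NA` (not estimable) when `c0 = 0`.
#' @export
risk_and_ratio <- function(c1, n1, c0, n0) {
  stopifnot(n1 >= 1, n0 >= 1, c1 >= 0, c1 <= n1, c0 >= 0, c0 <= n0)
  risk1 <- 100 * c1 / n1
  risk0 <- 100 * c0 / n0
  structure(list(c1 = c1, n1 = n1, c0 = c0, n0 = n0,
                 risk1 = risk1, risk0 = risk0,
                 rr = if (c0 == 0) NA_real_ else risk1 / risk0,
                 rd = risk1 - risk0),
            class = "risk_result")
}

#' Per-child utilisation summary
#'
#' @param totals integer vector, one total event count per cohort child
#'   (zeros included).
#' @return list: `median`, `iqr` (length-2, linear-interpolation quantiles),
#'   `pct_zero`.
#' @export
summarize_utilisation <- function(totals) {
  if (!length(totals)) stop("empty cohort", call. = FALSE)
  q <- stats::quantile(totals, c(.25, .5, .75), type = 7, names = FALSE)
  list(median = q[2], iqr = c(q[1], q[3]),
       pct_zero = 100 * mean(totals == 0))
}
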