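## Cohort statistics: Fisher exact and chi-square tests, Benjamini-Hochberg
## FDR, Kaplan-Meier estimation and the log-rank test. These wrap the
## canonical base-R / survival implementations behind a uniform surface;
## the test suite checks them against independent oracles (hypergeometric
## enumeration, the step-up formula, hand product-limit arithmetic).

.as2x2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2L, 2L))) stop("a 2x2 table is required")
  if (any(m < 0) || any(m != round(m)))
    stop("table entries must be non-negative integers")
  if (sum(m) == 0L) stop("table total must be > 0")
  m
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Two-sided p-value by the small-p-values method: the sum of probabilities
#' of all tables with the observed margins whose hypergeometric probability
#' does not exceed that of the observed table.
#'
#' @param table 2x2 matrix (or anything coercible) of non-negative counts.
#' @return the two-sided p-value.
#' @export
fisherExact <- function(table) {
  m <- .as2x2(table)
  stats::fisher.test(m, alternative = "two.sided")$p.value
}

#' Chi-square test for a contingency table
#'
#' @param table contingency table of counts.
#' @param correct apply the Yates continuity correction (default FALSE).
#' @return list with `statistic`, `df`, `p`.
#' @export
chisqTest <- function(table, correct = FALSE) {
  ct <- suppressWarnings(stats::chisq.test(as.matrix(table),
                                           correct = correct))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up adjustment: q_(i) = min over j >= i of p_(j) * m / j, capped at 1
#' and mapped back to the input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return q-values in input order.
#' @export
bhFdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator with Greenwood variance; events precede
#' censorings at identical times (the standard convention). Optionally
#' evaluates survival and its confidence interval at a horizon (e.g. 60
#' months for a 5-year rate).
#'
#' @param time follow-up times (months, >= 0).
#' @param event logical/0-1 event indicator.
#' @param horizon optional time at which to report survival.
#' @param conf.type confidence-interval transform passed to
#'   [survival::survfit()] (default `"log"`).
#' @return list with `steps` (time, n_risk, n_event, surv, lower, upper) and,
#'   when `horizon` is given, `horizon` (surv, lower, upper at that time).
#' @export
kmEstimate <- function(time, event, horizon = NULL, conf.type = "log") {
  if (any(time < 0)) stop("survival times must be >= 0")
  if (length(time) == 0L) stop("at least one subject is required")
  fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ 1,
                           conf.type = conf.type)
  steps <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, surv = fit$surv,
                      lower = fit$lower, upper = fit$upper)
  out <- list(steps = steps)
  if (!is.null(horizon)) {
    s <- summary(fit, times = horizon, extend = TRUE)
    out$horizon <- data.frame(time = horizon, surv = s$surv,
                              lower = s$lower, upper = s$upper)
  }
  out
}

#' Log-rank test between two groups
#'
#' Standard observed-minus-expected log-rank statistic on 1 degree of
#' freedom.
#'
#' @param time,event follow-up times and event indicators.
#' @param group two-level grouping vector.
#' @return list with `statistic`, `df`, `p`.
#' @export
logrankTest <- function(time, event, group) {
  g <- factor(group)
  if (nlevels(g) != 2L || any(table(g) == 0L))
    stop("exactly two non-empty groups are required")
  sd <- survival::survdiff(survival::Surv(time, as.integer(event)) ~ g)
  stat <- sd$chisq
  list(statistic = stat, df = 1L,
       p = stats::pchisq(stat, df = 1L, lower.tail = FALSE))
}
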