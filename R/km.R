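#' Kaplan-Meier product-limit estimate
#'
#' Computes the product-limit estimator of the survival function, overall
#' or per group. Censored subjects leave the risk set without producing a
#' step; subjects censored at an event time are counted at risk at that
#' time (events precede censorings).
#'
#' @param outcome a [survival_outcome()].
#' @param group optional grouping vector (factor/character/logical) of the
#'   same length; when supplied a named list of curves is returned.
#' @return A `km_curve` data frame (`time`, `n_risk`, `n_event`,
#'   `survival`) with one row per distinct event time, or a named list of
#'   such curves. A curve with no events has zero rows (survival constant
#'   at 1).
#' @export
km_estimate <- function(outcome, group = NULL) {
  if (!inherits(outcome, "survival_outcome")) {
    stop_input("'outcome' must be a survival_outcome")
  }
  if (is.null(group)) {
    return(km_one(outcome$time, outcome$event))
  }
  if (length(group) != length(outcome$time)) {
    stop_input("'group' length does not match the outcome")
  }
  g <- if (is.factor(group)) group else factor(group)
  if (any(tabulate(g, nbins = nlevels(g)) == 0L)) {
    stop_input("empty group: ",
               levels(g)[which(tabulate(g, nbins = nlevels(g)) == 0L)[1L]])
  }
  out <- lapply(levels(g), function(lv) {
    sel <- g == lv
    km_one(outcome$time[sel], outcome$event[sel], label = lv)
  })
  stats::setNames(out, levels(g))
}

km_one <- function(time, event, label = NULL) {
  if (!length(time)) stop_input("empty group")
  et <- sort(unique(time[event == 1]))
  n_risk <- vapply(et, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(et, function(t) sum(time == t & event == 1), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  out <- data.frame(time = et, n_risk = n_risk, n_event = n_event,
                    survival = surv)
  class(out) <- c("km_curve", "data.frame")
  attr(out, "group") <- label
  attr(out, "n") <- length(time)
  out
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' @param curve a `km_curve`.
#' @param times numeric vector of evaluation times.
#' @return Step-function survival probabilities (1 before the first event
#'   time).
#' @export
km_survival_at <- function(curve, times) {
  if (!inherits(curve, "km_curve")) stop_input("'curve' must be a km_curve")
  if (!nrow(curve)) return(rep(1, length(times)))
  idx <- findInterval(times, curve$time)
  ifelse(idx == 0L, 1, curve$survival[pmax(idx, 1L)])
}

#' Two-sample log-rank test
#'
#' Standard two-sample log-rank chi-square on 1 degree of freedom: at each
#' distinct event time the observed number of events in the first group is
#' compared with its hypergeometric expectation given the risk sets, and
#' contributions are pooled over event times.
#'
#' @param outcome a [survival_outcome()].
#' @param group a binary grouping vector (two non-empty levels).
#' @return An object of class `logrank_test`: `statistic` (chi-square),
#'   `p_value`, `z` (signed standardized statistic for the first level),
#'   `observed`, `expected`, `variance`, `df`.
#' @export
logrank_test <- function(outcome, group) {
  if (!inherits(outcome, "survival_outcome")) {
    stop_input("'outcome' must be a survival_outcome")
  }
  if (length(group) != length(outcome$time)) {
    stop_input("'group' length does not match the outcome")
  }
  g <- if (is.factor(group)) group else factor(group)
  if (nlevels(g) != 2L || any(tabulate(g, nbins = 2L) == 0L)) {
    stop_input("exactly two non-empty groups are required")
  }
  if (sum(outcome$event) < 1) stop_input("at least one event is required")
  res <- logrank_core(outcome$time, outcome$event, g == levels(g)[1L])
  structure(c(res, list(df = 1L, groups = levels(g))),
            class = "logrank_test")
}

# core O-E computation for membership indicator g1 (TRUE = group 1)
logrank_core <- function(time, event, g1) {
  et <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in et) {
    at <- time >= t
    nk <- sum(at); n1k <- sum(at & g1)
    dk <- sum(time == t & event == 1)
    d1k <- sum(time == t & event == 1 & g1)
    O1 <- O1 + d1k
    E1 <- E1 + dk * n1k / nk
    if (nk > 1) {
      V <- V + dk * (n1k / nk) * (1 - n1k / nk) * (nk - dk) / (nk - 1)
    }
  }
  z <- if (V > 0) (O1 - E1) / sqrt(V) else 0
  stat <- z^2
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       z = z, observed = O1, expected = E1, variance = V)
}

#' @export
print.logrank_test <- function(x, ...) {
  cat("Two-sample log-rank test\n",
      "  chi-square = ", format(x$statistic, digits = 5),
      " on 1 df, p = ", format(x$p_value, digits = 4), "\n",
      "  group '", x$groups[1L], "': observed ", x$observed,
      ", expected ", format(x$expected, digits = 5), "\n", sep = "")
  invisible(x)
}
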