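#' Two-group log-rank statistic
#'
#' Direct evaluation of the log-rank tables: at every event time the
#' observed events in group A are compared with the hypergeometric
#' expectation and variance given the risk sets; the chi-square statistic
#' is \code{(O_A - E_A)^2 / V} with 1 df. Implemented in-package because
#' the maximally selected cutpoint scan evaluates it at every candidate.
#'
#' @param time,event,group survival triplets; \code{group} logical or
#'   two-level, TRUE/second level = "group A"
#' @return list with \code{observed}, \code{expected}, \code{variance},
#'   \code{z} (signed standardized statistic \code{(O-E)/sqrt(V)}),
#'   \code{chisq}, \code{p_value}.
#' @export
logrank_test <- function(time, event, group) {
  g <- if (is.logical(group)) group else group == sort(unique(group))[2]
  assert_that(length(unique(g)) == 2, "need two nonempty groups")
  et <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in et) {
    at <- time >= t
    n <- sum(at); nA <- sum(at & g)
    d <- sum(time == t & event == 1)
    dA <- sum(time == t & event == 1 & g)
    O <- O + dA
    E <- E + d * nA / n
    if (n > 1) V <- V + d * (nA / n) * (1 - nA / n) * (n - d) / (n - 1)
  }
  z <- if (V > 0) (O - E) / sqrt(V) else 0
  chisq <- z^2
  list(observed = O, expected = E, variance = V, z = z, chisq = chisq,
       p_value = pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Maximally selected log-rank cutpoint
#'
#' Scans candidate cutpoints (midpoints of sorted unique scores) that
#' leave at least \code{minprop} of patients on each side and selects the
#' one maximizing the absolute standardized log-rank statistic between
#' the \code{score > c} and \code{score <= c} arms; ties are broken by
#' the smallest cutpoint. No selection-adjusted p-value is computed; the
#' chosen split is meant to be reported with the plain log-rank test.
#'
#' @param d data.frame with columns \code{time}, \code{event},
#'   \code{score} (>= 2 distinct scores and >= 1 event)
#' @param minprop minimum per-arm proportion, default 0.3
#' @return list of class \code{cutpoint_result}: \code{cutpoint},
#'   \code{statistic} (|z| at the cutpoint), \code{group_sizes},
#'   \code{minprop}, \code{candidates} (data.frame cutpoint, abs_z).
#' @export
optimal_cutpoint <- function(d, minprop = 0.3) {
  assert_that(all(c("time", "event", "score") %in% names(d)),
              "need columns time, event, score")
  assert_that(sum(d$event) >= 1, "need at least one event")
  s <- sort(unique(d$score))
  assert_that(length(s) >= 2, "scores are constant: no valid cutpoint")
  cand <- (s[-1] + s[-length(s)]) / 2
  n <- nrow(d)
  ok <- vapply(cand, function(c) {
    hi <- sum(d$score > c)
    min(hi, n - hi) / n >= minprop
  }, TRUE)
  cand <- cand[ok]
  if (!length(cand))
    stop("no candidate cutpoint satisfies minprop = ", minprop,
         call. = FALSE)
  absz <- vapply(cand, function(c) {
    abs(logrank_test(d$time, d$event, d$score > c)$z)
  }, 0)
  best <- cand[which.max(absz)]  # which.max takes the first (smallest c)
  structure(list(cutpoint = best, statistic = max(absz),
                 group_sizes = c(low = sum(d$score <= best),
                                 high = sum(d$score > best)),
                 minprop = minprop,
                 candidates = data.frame(cutpoint = cand, abs_z = absz)),
            class = "cutpoint_result")
}

#' Kaplan-Meier curves and log-rank test for a dichotomized score
#'
#' Splits the cohort at the cutpoint, fits Kaplan-Meier product-limit
#' curves per arm (right censoring) and reports the two-group log-rank
#' chi-square with its upper-tail p-value. A warning is emitted when an
#' arm has no events.
#'
#' @param d data.frame with \code{time}, \code{event}, \code{score}
#' @param cutpoint score threshold; arms are \code{score > cutpoint}
#'   (high) vs \code{score <= cutpoint} (low)
#' @return list with \code{fit} (a \code{survival::survfit} object over
#'   both arms), \code{chisq}, \code{p_value}, \code{group_sizes}.
#' @export
km_logrank <- function(d, cutpoint) {
  arm <- factor(ifelse(d$score > cutpoint, "high", "low"),
                levels = c("low", "high"))
  assert_that(all(table(arm) > 0), "both arms must be nonempty")
  for (a in levels(arm)) {
    if (sum(d$event[arm == a]) == 0)
      warning("arm '", a, "' has zero events")
  }
  fit <- survival::survfit(
    survival::Surv(d$time, d$event) ~ arm,
    type = "kaplan-meier", error = "tsiatis")
  lr <- logrank_test(d$time, d$event, arm == "high")
  list(fit = fit, chisq = lr$chisq, p_value = lr$p_value,
       group_sizes = table(arm))
}
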