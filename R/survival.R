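#' Median dichotomization of a continuous marker
#'
#' Splits marker values (e.g. microvessel density) at the median. By the
#' default convention values at or above the median are "high" and values
#' strictly below are "low", which on an odd number of distinct values
#' yields floor(n/2) low and ceiling(n/2) high (e.g. 32 low / 33 high at
#' n = 65); `at_median = "low"` mirrors the convention. Heavy ties at the
#' median can unbalance the split; the assignment is deterministic either
#' way.
#'
#' @param x numeric marker values (>= 4 finite values, not all identical).
#' @param at_median which group receives values exactly at the median.
#' @return Factor with levels `low`, `high`.
#' @export
dichotomize <- function(x, at_median = c("high", "low")) {
  at_median <- match.arg(at_median)
  if (sum(is.finite(x)) < 4L) stop("need at least 4 finite values",
                                   call. = FALSE)
  if (length(unique(x[is.finite(x)])) == 1L) {
    stop("all values identical; no split possible", call. = FALSE)
  }
  m <- median(x, na.rm = TRUE)
  high <- if (at_median == "high") x >= m else x > m
  factor(ifelse(high, "high", "low"), levels = c("low", "high"))
}

check_survival_df <- function(records) {
  stopifnot(all(c("time", "event") %in% names(records)))
  if (any(records$time < 0) || any(!is.finite(records$time))) {
    stop("survival times must be finite and non-negative", call. = FALSE)
  }
  if (!all(records$event %in% c(0, 1))) {
    stop("event indicators must be 0/1", call. = FALSE)
  }
  invisible(records)
}

#' Kaplan-Meier survival estimate per group
#'
#' Product-limit estimator (via the survival package): the curve starts at
#' S(0) = 1, steps down at event times, and censored subjects leave the
#' risk set without a step.
#'
#' @param records data.frame with `time`, `event` (0/1) and optionally
#'   `group`.
#' @return A data.frame of curve steps: `group`, `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`.
#' @export
km_estimate <- function(records) {
  check_survival_df(records)
  if (is.null(records$group)) records$group <- "all"
  fit <- survival::survfit(
    survival::Surv(time, event) ~ group, data = records)
  s <- summary(fit, censored = TRUE)
  grp <- if (is.null(s$strata)) rep(records$group[1L], length(s$time))
         else sub("^group=", "", as.character(s$strata))
  data.frame(group = grp, time = s$time, n_risk = s$n.risk,
             n_event = s$n.event, n_censor = s$n.censor, surv = s$surv,
             stringsAsFactors = FALSE)
}

#' Log-rank test between survival groups
#'
#' Standard observed-minus-expected log-rank statistic with hypergeometric
#' variance (via `survival::survdiff`), chi-square with k-1 degrees of
#' freedom for k groups.
#'
#' @param records data.frame with `time`, `event`, `group`.
#' @return A list: `statistic`, `df`, `p`, `observed`, `expected`.
#' @export
logrank_test <- function(records) {
  check_survival_df(records)
  stopifnot("group" %in% names(records))
  groups <- unique(records$group)
  if (length(groups) < 2L) stop("need >= 2 non-empty groups", call. = FALSE)
  if (sum(records$event) < 1L) stop("need at least one event", call. = FALSE)
  sd_ <- survival::survdiff(
    survival::Surv(time, event) ~ group, data = records)
  df <- length(sd_$n) - 1L
  list(statistic = unname(sd_$chisq), df = df,
       p = pchisq(sd_$chisq, df, lower.tail = FALSE),
       observed = unname(sd_$obs), expected = unname(sd_$exp))
}

#' Response-rate contrast between treatment arms
#'
#' Objective response rates per arm with a chi-square homogeneity test
#' (no continuity correction); when any expected cell count falls below 5
#' the exact Fisher test is used instead.
#'
#' @param responders,total integer vectors, one entry per arm.
#' @param arm optional arm labels.
#' @return A list: `orr` (named per-arm rates), `method` (`"chisq"` or
#'   `"fisher"`), `statistic` (chi-square only), `p`.
#' @export
response_test <- function(responders, total, arm = NULL) {
  stopifnot(length(responders) == length(total))
  if (any(total <= 0)) stop("each arm needs a positive total", call. = FALSE)
  if (any(responders < 0) || any(responders > total)) {
    stop("responders must lie in [0, total]", call. = FALSE)
  }
  if (is.null(arm)) arm <- sprintf("arm%d", seq_along(total))
  tab <- cbind(responders = responders, non = total - responders)
  rownames(tab) <- arm
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    ft <- fisher.test(tab)
    out <- list(method = "fisher", statistic = NA_real_, p = ft$p.value)
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    out <- list(method = "chisq", statistic = unname(ct$statistic),
                p = ct$p.value)
  }
  c(list(orr = setNames(responders / total, arm)), out)
}
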