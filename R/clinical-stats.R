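#' Label patients under a trial response grouping
#'
#' Three binary groupings of best RECIST response are supported:
#' * `ORR` (overall response): CR or PR versus SD or PD;
#' * `CBR` (clinical benefit): CR, PR, or SD lasting more than 6
#'   months, versus SD of 6 months or less, or PD (the 6-month boundary
#'   is strict: SD with PFS exactly 6.0 months is negative);
#' * `LTR` (long-term responder): PFS equal to or greater than twice
#'   the cohort median PFS (inclusive).
#'
#' Not-evaluable (NE) patients get a missing label under ORR and CBR;
#' LTR is defined from PFS alone, so NE patients are labelled.  The LTR
#' threshold uses the cohort's own Kaplan-Meier median PFS unless
#' `median_pfs` pins it to a fixed value.
#'
#' @param clinical A `clinical_table` ([read_clinical_table()]).
#' @param grouping One of `"ORR"`, `"CBR"`, `"LTR"`.
#' @param median_pfs Optional fixed median PFS in months for the LTR
#'   threshold; default is the Kaplan-Meier median of the cohort.
#' @param cbr_months CBR duration boundary in months (default 6).
#' @return A tibble with `patient_id` and logical `label` (`NA` =
#'   not evaluable for this grouping), with the grouping name and any
#'   threshold recorded as attributes.
#' @export
group_patients <- function(clinical, grouping = c("ORR", "CBR", "LTR"),
                           median_pfs = NULL, cbr_months = 6) {
  grouping <- match.arg(grouping)
  cl <- tibble::as_tibble(clinical)
  resp <- cl$best_response
  label <- switch(
    grouping,
    ORR = dplyr::case_when(
      resp %in% c("CR", "PR") ~ TRUE,
      resp %in% c("SD", "PD") ~ FALSE,
      TRUE ~ NA
    ),
    CBR = dplyr::case_when(
      resp %in% c("CR", "PR") ~ TRUE,
      resp == "SD" & cl$pfs_months > cbr_months ~ TRUE,
      resp == "SD" ~ FALSE,
      resp == "PD" ~ FALSE,
      TRUE ~ NA
    ),
    LTR = {
      if (is.null(median_pfs)) {
        median_pfs <- glance(km_fit(cl$pfs_months, cl$pfs_event))$median
      }
      if (is.na(median_pfs)) {
        stop("cohort median PFS is not resolvable (too much censoring); ",
             "supply `median_pfs`", call. = FALSE)
      }
      cl$pfs_months >= 2 * median_pfs
    }
  )
  out <- tibble::tibble(patient_id = cl$patient_id, label = label)
  attr(out, "grouping") <- grouping
  if (grouping == "LTR") attr(out, "median_pfs") <- median_pfs
  out
}

#' Exact binomial rate estimate
#'
#' Rate as a percentage with a two-sided Clopper-Pearson (exact
#' binomial, beta-quantile) confidence interval, the standard
#' presentation for trial response rates.  Zero successes give a lower
#' bound of 0 and full successes an upper bound of 100.
#'
#' @param n_pos Number of successes.
#' @param n_total Denominator (positive).
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row tibble: `n_pos`, `n_total`, `rate`, `conf_low`,
#'   `conf_high`, all rates in percent.
#' @examples
#' response_rate(7, 73)   # 9.6% (95% CI 3.9-18.8)
#' @export
response_rate <- function(n_pos, n_total, conf_level = 0.95) {
  if (n_total <= 0 || n_pos < 0 || n_pos > n_total ||
      n_pos != round(n_pos) || n_total != round(n_total)) {
    stop("need integer counts with 0 <= n_pos <= n_total and n_total > 0",
         call. = FALSE)
  }
  ci <- stats::binom.test(n_pos, n_total,
                          conf.level = conf_level)$conf.int
  tibble::tibble(
    n_pos = as.integer(n_pos), n_total = as.integer(n_total),
    rate = 100 * n_pos / n_total,
    conf_low = 100 * ci[1], conf_high = 100 * ci[2]
  )
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Two-sided rank-sum (Mann-Whitney) comparison of two independent
#' groups.  With 12 or fewer observations in total and no ties the
#' exact permutation distribution of the rank sum is used; otherwise
#' the normal approximation with tie and continuity correction.
#'
#' @param x,y Numeric vectors, each with at least one non-missing
#'   value.
#' @return A one-row tibble: `statistic` (Mann-Whitney U for the first
#'   group), `p_value`, `method` (`"exact"` or `"normal_approx"`).
#' @export
wilcoxon_rank_sum <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) {
    stop("both groups need at least one non-missing value", call. = FALSE)
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && length(x) + length(y) <= 12
  res <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  )
  tibble::tibble(
    statistic = unname(res$statistic),
    p_value = min(1, res$p.value),
    method = if (exact) "exact" else "normal_approx"
  )
}

#' Cohen's d standardized mean difference
#'
#' `(mean(x) - mean(y))` divided by the pooled standard deviation with
#' `(n1 - 1) + (n2 - 1)` weighting.  A pooled SD of zero makes the
#' effect size undefined; `NA` is returned with a warning.
#'
#' @param x,y Numeric vectors with at least 2 non-missing values each.
#' @return Numeric scalar (positive when `x` has the larger mean).
#' @export
cohens_d <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 2 || n2 < 2) {
    stop("Cohen's d needs at least 2 values per group", call. = FALSE)
  }
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
    (n1 + n2 - 2)
  if (sp2 == 0) {
    warning("pooled standard deviation is zero; Cohen's d undefined",
            call. = FALSE)
    return(NA_real_)
  }
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Kaplan-Meier fit for one group
#'
#' Product-limit estimate of the survivor function with log-log
#' (Greenwood-based) confidence intervals.  The median is the earliest
#' time at which the estimate drops to 0.5 or below; with too much
#' censoring it is undefined and reported as `NA`.
#'
#' @param times Non-negative event/censoring times.
#' @param events Logical (or 0/1) event indicators.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `km_fit` wrapping the
#'   [survival::survfit()] fit; use [tidy()] for the curve,
#'   [glance()] for the median and its CI, and [ggplot2::autoplot()]
#'   to plot.
#' @export
km_fit <- function(times, events, conf_level = 0.95) {
  stopifnot(length(times) == length(events))
  events <- as.logical(events)
  if (any(is.na(times)) || any(times < 0)) {
    stop("times must be non-negative and non-missing", call. = FALSE)
  }
  fit <- survival::survfit(
    survival::Surv(times, events) ~ 1,
    conf.type = "log-log", conf.int = conf_level
  )
  tab <- summary(fit)$table
  # median per the earliest-crossing definition: the first time at
  # which the estimate drops to 0.5 or below (survfit's table instead
  # averages the bracketing times when the curve sits exactly at 0.5)
  crossed <- fit$surv <= 0.5
  med <- if (any(crossed)) min(fit$time[crossed]) else NA_real_
  out <- list(
    fit = fit,
    n = length(times),
    n_events = sum(events),
    median = med,
    median_conf_low = unname(tab[grep("LCL", names(tab))]),
    median_conf_high = unname(tab[grep("UCL", names(tab))]),
    conf_level = conf_level
  )
  class(out) <- "km_fit"
  out
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf(
    "<km_fit> n = %d, events = %d, median = %s (%.0f%% CI %s, %s)\n",
    x$n, x$n_events, format(round(x$median, 2)), 100 * x$conf_level,
    format(round(x$median_conf_low, 2)),
    format(round(x$median_conf_high, 2))))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
#' @method tidy km_fit
#' @rdname km_fit
#' @param x A `km_fit` object.
#' @param ... Unused.
tidy.km_fit <- function(x, ...) {
  f <- x$fit
  tibble::tibble(
    time = f$time, n_risk = f$n.risk, n_event = f$n.event,
    n_censor = f$n.censor, estimate = f$surv,
    conf_low = f$lower, conf_high = f$upper
  )
}

#' @export
#' @method glance km_fit
#' @rdname km_fit
glance.km_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, events = x$n_events, median = x$median,
    median_conf_low = x$median_conf_low,
    median_conf_high = x$median_conf_high
  )
}

#' @export
#' @method autoplot km_fit
#' @rdname km_fit
#' @param object A `km_fit` object.
autoplot.km_fit <- function(object, ...) {
  d <- tidy.km_fit(object)
  d0 <- tibble::tibble(time = 0, estimate = 1, conf_low = 1, conf_high = 1)
  d <- dplyr::bind_rows(d0, d)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$estimate)) +
    ggplot2::geom_step() +
    ggplot2::geom_step(ggplot2::aes(y = .data$conf_low), linetype = "dashed",
                       alpha = 0.5) +
    ggplot2::geom_step(ggplot2::aes(y = .data$conf_high), linetype = "dashed",
                       alpha = 0.5) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability") +
    ggplot2::ylim(0, 1)
}

#' Log-rank comparison of survival between groups
#'
#' Standard log-rank chi-square with hypergeometric variance, on
#' `k - 1` degrees of freedom for `k` groups.
#'
#' @param times Non-negative times.
#' @param events Logical event indicators.
#' @param group Group membership (factor-like, at least 2 levels with
#'   data).
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(times, events, group) {
  group <- as.factor(as.character(group))
  if (nlevels(droplevels(group)) < 2) {
    stop("log-rank test needs at least 2 groups", call. = FALSE)
  }
  sd <- survival::survdiff(
    survival::Surv(times, as.logical(events)) ~ group
  )
  df <- length(sd$n) - 1
  tibble::tibble(
    statistic = unname(sd$chisq), df = df,
    p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE)
  )
}
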