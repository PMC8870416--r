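#' Scan GI parameters against response groupings and survival
#'
#' Runs the cohort association layer: every GI parameter is compared
#' between the positive and negative arms of every response grouping
#' with a two-sided Wilcoxon rank-sum test and a Cohen's d effect size,
#' and (optionally) each parameter is median-split into strata whose
#' PFS curves are compared by the log-rank test.  Raw p values are
#' reported alongside Benjamini-Hochberg adjusted values computed over
#' the whole scan; nothing is filtered on significance.
#'
#' Patients with a missing grouping label (for example NE patients
#' under ORR/CBR) are excluded from that grouping's test.  Pairs with
#' fewer than `min_group` patients in either arm, or a degenerate
#' single-stratum categorization, are skipped with a message.
#'
#' @param gi Cohort GI table: a `sample` column plus one numeric column
#'   per parameter (stacked [compute_gi_vector()] rows).
#' @param clinical A `clinical_table`; `patient_id` must match
#'   `gi$sample`.
#' @param groupings Response groupings to test (subset of
#'   `c("ORR", "CBR", "LTR")`).
#' @param extra_groups Optional data frame of additional binary
#'   groupings: a `patient_id` column plus one logical column per
#'   grouping (e.g. an `hrd` column from [hrd_status()]).
#' @param parameters Parameter columns to scan (default: every numeric
#'   column of `gi` except `sample`).
#' @param median_pfs Optional pinned median PFS for the LTR grouping.
#' @param survival Also run the median-split log-rank scan on PFS
#'   (default TRUE).
#' @param min_group Minimum patients per arm (default 2).
#' @return A tibble of class `association_scan`: `parameter`,
#'   `grouping`, `test`, `n_pos`, `n_neg`, `median_pos`, `median_neg`,
#'   `statistic`, `p_value`, `cohens_d`, `direction`, `p_adj`.
#' @export
association_scan <- function(gi, clinical,
                             groupings = c("ORR", "CBR", "LTR"),
                             extra_groups = NULL, parameters = NULL,
                             median_pfs = NULL, survival = TRUE,
                             min_group = 2) {
  gi <- tibble::as_tibble(gi)
  cl <- tibble::as_tibble(clinical)
  if (is.null(parameters)) {
    parameters <- names(gi)[vapply(gi, is.numeric, logical(1))]
    parameters <- setdiff(parameters, "sample")
  }
  dat <- dplyr::inner_join(gi, cl, by = c(sample = "patient_id"))
  if (nrow(dat) == 0) {
    stop("no overlap between gi$sample and clinical$patient_id",
         call. = FALSE)
  }

  labels <- list()
  for (g in groupings) {
    lab <- group_patients(cl, g, median_pfs = median_pfs)
    labels[[g]] <- lab$label[match(dat$sample, lab$patient_id)]
  }
  if (!is.null(extra_groups)) {
    eg <- tibble::as_tibble(extra_groups)
    id_col <- intersect(c("patient_id", "sample"), names(eg))[1]
    if (is.na(id_col)) {
      stop("extra_groups needs a patient_id or sample column",
           call. = FALSE)
    }
    for (g in setdiff(names(eg), id_col)) {
      labels[[g]] <- as.logical(eg[[g]])[match(dat$sample, eg[[id_col]])]
    }
  }

  rows <- list()
  for (g in names(labels)) {
    lab <- labels[[g]]
    for (p in parameters) {
      v <- dat[[p]]
      ok <- !is.na(lab) & !is.na(v)
      pos <- v[ok & lab]
      neg <- v[ok & !lab]
      if (length(pos) < min_group || length(neg) < min_group) {
        message(sprintf("skipping %s x %s: fewer than %d per arm",
                        p, g, min_group))
        next
      }
      w <- wilcoxon_rank_sum(pos, neg)
      d <- suppressWarnings(cohens_d(pos, neg))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        parameter = p, grouping = g, test = "rank_sum",
        n_pos = length(pos), n_neg = length(neg),
        median_pos = stats::median(pos), median_neg = stats::median(neg),
        statistic = w$statistic, p_value = w$p_value, cohens_d = d,
        direction = dplyr::case_when(
          is.na(d) | d == 0 ~ "none", d > 0 ~ "higher_in_positive",
          TRUE ~ "lower_in_positive")
      )
    }
  }

  if (isTRUE(survival)) {
    for (p in parameters) {
      v <- dat[[p]]
      ok <- !is.na(v)
      if (sum(ok) < 2 * min_group) next
      cats <- categorize(v[ok], "median")$category
      if (nlevels(droplevels(cats)) < 2 ||
          min(table(droplevels(cats))) < min_group) {
        message(sprintf(
          "skipping %s x PFS: degenerate median categorization", p))
        next
      }
      lr <- logrank_test(dat$pfs_months[ok], dat$pfs_event[ok], cats)
      tab <- table(cats)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        parameter = p, grouping = "PFS", test = "logrank",
        n_pos = unname(tab["high"]), n_neg = unname(tab["low"]),
        median_pos = NA_real_, median_neg = NA_real_,
        statistic = lr$statistic, p_value = lr$p_value,
        cohens_d = NA_real_, direction = NA_character_
      )
    }
  }

  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    stop("no testable parameter x grouping pair", call. = FALSE)
  }
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  class(out) <- c("association_scan", class(out))
  out
}

#' Write an association scan report
#' @param scan An `association_scan` tibble.
#' @param path Output TSV path.
#' @export
write_association_report <- function(scan, path) {
  readr::write_tsv(tibble::as_tibble(scan), path, progress = FALSE)
  invisible(path)
}

#' @export
#' @method autoplot association_scan
#' @rdname association_scan
#' @param object An `association_scan` tibble.
#' @param ... Unused.
autoplot.association_scan <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(
    d, ggplot2::aes(x = -log10(.data$p_value), y = .data$parameter,
                    colour = .data$grouping)
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = -log10(0.05), linetype = "dashed",
                        alpha = 0.5) +
    ggplot2::labs(x = expression(-log[10](p)), y = NULL,
                  colour = "Grouping")
}

#' Box plot of one GI parameter across a binary grouping
#'
#' @param gi Cohort GI table.
#' @param labels A tibble from [group_patients()] (or any
#'   `patient_id`/`label` pair).
#' @param parameter Parameter column name to plot.
#' @return A ggplot object.
#' @export
plot_gi_by_group <- function(gi, labels, parameter) {
  d <- dplyr::inner_join(tibble::as_tibble(gi),
                         tibble::as_tibble(labels),
                         by = c(sample = "patient_id"))
  d <- d[!is.na(d$label), ]
  d$group <- ifelse(d$label, "positive", "negative")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group,
                                  y = .data[[parameter]])) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = parameter)
}
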