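#' Names and definitions of the GI parameters
#'
#' Returns the data dictionary for the genomic-instability parameter
#' vector: the unfiltered event tier (counts, mean length, altered
#' length, percent of genome), the same tier restricted to events that
#' survive the BAF-borderline filter, the gain and loss breakdowns, and
#' the LOH span statistics including the long-LOH (>10 Mb and >15 Mb)
#' subsets.  Percentages are over the total length of the genome model.
#'
#' @return A tibble with columns `parameter`, `unit`, `description`.
#' @export
gi_parameter_dictionary <- function() {
  tibble::tribble(
    ~parameter, ~unit, ~description,
    "n_events", "count", "copy-number events (gains + losses)",
    "mean_event_length", "bp", "mean length per event (0 when no events)",
    "altered_length", "bp", "summed length of all events",
    "pct_genome_altered", "%", "altered_length as % of genome",
    "n_events_baf", "count", "events after BAF-borderline filter",
    "mean_event_length_baf", "bp", "mean event length, BAF-filtered tier",
    "altered_length_baf", "bp", "summed event length, BAF-filtered tier",
    "pct_genome_altered_baf", "%", "BAF-filtered altered length as % of genome",
    "n_gains", "count", "gain events",
    "gain_length", "bp", "summed gain length",
    "pct_genome_gains", "%", "gain length as % of genome",
    "n_gains_baf", "count", "gain events, BAF-filtered tier",
    "gain_length_baf", "bp", "summed gain length, BAF-filtered tier",
    "pct_genome_gains_baf", "%", "BAF-filtered gain length as % of genome",
    "n_losses", "count", "loss events",
    "loss_length", "bp", "summed loss length",
    "pct_genome_losses", "%", "loss length as % of genome",
    "n_loh", "count", "LOH segments",
    "loh_length", "bp", "summed LOH length",
    "pct_genome_loh", "%", "LOH length as % of genome",
    "n_loh_15mb", "count", "LOH segments longer than 15 Mb",
    "loh_length_15mb", "bp", "summed length of LOH > 15 Mb",
    "pct_genome_loh_15mb", "%", "LOH > 15 Mb length as % of genome",
    "n_loh_10mb", "count", "LOH segments longer than 10 Mb",
    "loh_length_10mb", "bp", "summed length of LOH > 10 Mb",
    "pct_genome_loh_10mb", "%", "LOH > 10 Mb length as % of genome"
  )
}

#' Compute the genomic-instability parameter vector for one sample
#'
#' Summarises a sample's filtered copy-number events, its
#' BAF-borderline-filtered events, and its LOH segments into the named
#' instability parameters listed by [gi_parameter_dictionary()].
#' Counts are event counts, lengths summed bp, percentages
#' `100 * length / genome_total_length(genome)`, and mean event length
#' is `altered_length / n_events` with the zero-event case defined as 0
#' so cohort tables stay total and sortable.
#'
#' @param events A `cn_event_set` ([call_events()]).
#' @param events_baf A `cn_event_set` after [baf_borderline_filter()].
#' @param loh A `loh_segments` tibble ([call_loh()]).
#' @param genome The [genome_model()] shared by all inputs; a mismatch
#'   between input genomes is an error.
#' @return A one-row tibble: `sample` followed by one column per GI
#'   parameter.
#' @export
compute_gi_vector <- function(events, events_baf, loh, genome) {
  stopifnot(inherits(events, "cn_event_set"),
            inherits(events_baf, "cn_event_set"),
            inherits(loh, "loh_segments"),
            inherits(genome, "genome_model"))
  for (obj in list(events, events_baf, loh)) {
    g <- attr(obj, "genome")
    if (!is.null(g) && !identical(tibble::as_tibble(g),
                                  tibble::as_tibble(genome))) {
      stop("inputs were computed against a different genome model",
           call. = FALSE)
    }
  }
  total <- genome_total_length(genome)
  pct <- function(len) 100 * len / total
  tier <- function(ev) {
    n <- nrow(ev)
    len <- sum(ev$length)
    list(n = n, mean = if (n == 0) 0 else len / n, len = len, pct = pct(len))
  }
  all_t <- tier(events)
  baf_t <- tier(events_baf)
  gain_t <- tier(events[events$state == "gain", ])
  gain_b <- tier(events_baf[events_baf$state == "gain", ])
  loss_t <- tier(events[events$state == "loss", ])
  loh15 <- long_loh_events(loh, 15e6)
  loh10 <- long_loh_events(loh, 10e6)
  tibble::tibble(
    sample = attr(events, "sample_id") %||% NA_character_,
    n_events = all_t$n, mean_event_length = all_t$mean,
    altered_length = all_t$len, pct_genome_altered = all_t$pct,
    n_events_baf = baf_t$n, mean_event_length_baf = baf_t$mean,
    altered_length_baf = baf_t$len, pct_genome_altered_baf = baf_t$pct,
    n_gains = gain_t$n, gain_length = gain_t$len,
    pct_genome_gains = gain_t$pct,
    n_gains_baf = gain_b$n, gain_length_baf = gain_b$len,
    pct_genome_gains_baf = gain_b$pct,
    n_losses = loss_t$n, loss_length = loss_t$len,
    pct_genome_losses = loss_t$pct,
    n_loh = nrow(loh), loh_length = sum(loh$length),
    pct_genome_loh = pct(sum(loh$length)),
    n_loh_15mb = nrow(loh15), loh_length_15mb = sum(loh15$length),
    pct_genome_loh_15mb = pct(sum(loh15$length)),
    n_loh_10mb = nrow(loh10), loh_length_10mb = sum(loh10$length),
    pct_genome_loh_10mb = pct(sum(loh10$length))
  )
}

#' Write a cohort GI table
#' @param gi Tibble of stacked [compute_gi_vector()] rows.
#' @param path Output TSV path.
#' @export
write_gi_table <- function(gi, path) {
  readr::write_tsv(tibble::as_tibble(gi), path, progress = FALSE)
  invisible(path)
}

#' Categorize a continuous parameter by its median or quartiles
#'
#' The median scheme splits at the cohort median: values at or below
#' the median are `"low"`, values above are `"high"`.  The quartile
#' scheme bins at Q1/Q2/Q3 (linear interpolation between order
#' statistics, `stats::quantile()` type 7) with right-closed cuts, so a
#' value exactly at a cut falls in the lower bin.  Missing values get a
#' missing label.  When every value is identical the split is
#' degenerate: all labels fall in the lowest bin and a warning is
#' raised.
#'
#' @param values Numeric vector (one value per sample).
#' @param scheme `"median"` or `"quartile"`.
#' @return A tibble of class `gi_categories` with columns `value` and
#'   `category` (factor: low/high or Q1-Q4), carrying the cut points as
#'   an attribute.
#' @export
categorize <- function(values, scheme = c("median", "quartile")) {
  scheme <- match.arg(scheme)
  values <- as.numeric(values)
  ok <- !is.na(values)
  need <- if (scheme == "median") 2L else 4L
  if (sum(ok) < need) {
    stop(sprintf("need at least %d non-missing values for the %s scheme",
                 need, scheme), call. = FALSE)
  }
  if (length(unique(values[ok])) == 1L) {
    warning("all values identical: degenerate categorization", call. = FALSE)
  }
  if (scheme == "median") {
    cuts <- stats::median(values[ok])
    labels <- c("low", "high")
    cat_idx <- ifelse(values <= cuts, 1L, 2L)
  } else {
    cuts <- stats::quantile(values[ok], probs = c(0.25, 0.5, 0.75),
                            names = FALSE, type = 7)
    labels <- c("Q1", "Q2", "Q3", "Q4")
    cat_idx <- 1L + (values > cuts[1]) + (values > cuts[2]) +
      (values > cuts[3])
  }
  out <- tibble::tibble(
    value = values,
    category = factor(labels[cat_idx], levels = labels)
  )
  attr(out, "scheme") <- scheme
  attr(out, "cuts") <- cuts
  class(out) <- c("gi_categories", class(out))
  out
}
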