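#' Purity-adjusted tumor copy number from a log2 ratio
#'
#' Observed depth ratios from an impure tumor sample are a mixture of
#' tumor and diploid normal cells.  Under the standard two-component
#' model the observed ratio is `p * n_t / 2 + (1 - p)` for tumor copy
#' number `n_t` and purity `p`; inverting gives
#' `n_t = (2 * 2^log2 - 2 * (1 - p)) / p`, clamped at zero.  A neutral
#' signal (`log2 = 0`) maps to copy number 2 at every purity, and at
#' purity 1 the adjustment reduces to `2 * 2^log2`.
#'
#' @param log2_ratio Numeric vector of log2 depth ratios.
#' @param purity Tumor cell fraction in (0, 1].
#' @return Adjusted tumor copy number, same length as `log2_ratio`.
#' @examples
#' purity_adjust(0, 1)      # 2: diploid
#' purity_adjust(-1, 0.5)   # 0: homozygous loss diluted to ratio 0.5
#' @export
purity_adjust <- function(log2_ratio, purity) {
  check_purity(purity)
  pmax(0, (2 * 2^log2_ratio - 2 * (1 - purity)) / purity)
}

#' Call copy-number events from a segment profile
#'
#' Applies the event-calling cascade: (1) segments with a recorded
#' p-value above the significance threshold are dropped (segments with
#' no p-value pass); (2) surviving segments are purity-adjusted and
#' classified as gain, loss or neutral against the copy-number
#' thresholds; (3) adjacent same-state events on a chromosome separated
#' by at most `merge_gap` bp are merged, so that fragments of one
#' biological alteration count once; (4) events shorter than
#' `min_length` are removed as probable technical artifacts.  The merge
#' runs before the length filter, so short fragments that together
#' exceed the minimum length survive as one event.
#'
#' @param profile A [segment_profile()].
#' @param gain_threshold Adjusted copy number at or above which a
#'   segment is a gain (default 2.5, the midpoint between 2 and 3).
#' @param loss_threshold Adjusted copy number at or below which a
#'   segment is a loss (default 1.5).
#' @param significance Per-segment p-value cutoff (default 0.001).
#' @param min_length Minimum event length in bp after merging
#'   (default 1e6: the 1 Mb artifact filter).
#' @param merge Merge adjacent same-state events before the length
#'   filter (default TRUE); with FALSE every qualifying segment is its
#'   own event.
#' @param merge_gap Maximum gap in bp between events that still merge
#'   (default 0: only touching events merge).
#'
#' @return A tibble of class `cn_event_set` with columns `chrom`,
#'   `start`, `end`, `state`, `cn`, `mean_baf`, `length`, carrying the
#'   sample id, genome and filter provenance as attributes.
#' @export
call_events <- function(profile, gain_threshold = 2.5, loss_threshold = 1.5,
                        significance = 0.001, min_length = 1e6,
                        merge = TRUE, merge_gap = 0) {
  stopifnot(inherits(profile, "segment_profile"))
  if (loss_threshold >= gain_threshold) {
    stop("loss_threshold must be below gain_threshold", call. = FALSE)
  }
  genome <- attr(profile, "genome")
  purity <- attr(profile, "purity")

  seg <- tibble::as_tibble(profile)
  seg <- seg[is.na(seg$p_value) | seg$p_value <= significance, ]
  seg$cn <- purity_adjust(seg$log2_ratio, purity)
  seg$state <- dplyr::case_when(
    seg$cn >= gain_threshold ~ "gain",
    seg$cn <= loss_threshold ~ "loss",
    TRUE ~ "neutral"
  )
  ev <- seg[seg$state != "neutral",
            c("chrom", "start", "end", "state", "cn", "mean_baf")]
  if (merge && nrow(ev) > 1) {
    ev <- merge_adjacent_events(ev, genome, merge_gap)
  }
  ev$length <- ev$end - ev$start
  ev <- ev[ev$length >= min_length, ]
  new_event_set(
    ev,
    sample_id = attr(profile, "sample_id"), genome = genome,
    provenance = list(
      significance = significance, min_length = min_length,
      gain_threshold = gain_threshold, loss_threshold = loss_threshold,
      merge = merge, merge_gap = merge_gap, purity = purity,
      baf_band = NULL
    )
  )
}

# Merge runs of same-state events whose gap is <= merge_gap.  Copy
# number and BAF of a merged run are length-weighted means over the
# contributing events (BAF over those with a value).
merge_adjacent_events <- function(ev, genome, merge_gap) {
  ord <- order(chrom_rank(ev$chrom, genome), ev$start)
  ev <- ev[ord, ]
  n <- nrow(ev)
  new_run <- c(TRUE, ev$chrom[-1] != ev$chrom[-n] |
                 ev$state[-1] != ev$state[-n] |
                 ev$start[-1] - ev$end[-n] > merge_gap)
  run <- cumsum(new_run)
  len <- ev$end - ev$start
  first <- which(new_run)
  last <- c(first[-1] - 1L, n)
  wmean_by <- function(x) {
    w <- ifelse(is.na(x), 0, len)
    num <- rowsum(ifelse(is.na(x), 0, x) * w, run, reorder = TRUE)[, 1]
    den <- rowsum(w, run, reorder = TRUE)[, 1]
    unname(ifelse(den > 0, num / den, NA_real_))
  }
  # runs are contiguous in sorted order: span = first start to last end
  quick_tbl(
    chrom = ev$chrom[first],
    start = ev$start[first],
    end = ev$end[last],
    state = ev$state[first],
    cn = wmean_by(ev$cn),
    mean_baf = wmean_by(ev$mean_baf)
  )
}

new_event_set <- function(ev, sample_id, genome, provenance) {
  ev <- tibble::as_tibble(ev)
  if (!"length" %in% names(ev)) ev$length <- ev$end - ev$start
  ev <- ev[, c("chrom", "start", "end", "state", "cn", "mean_baf", "length")]
  attr(ev, "sample_id") <- sample_id
  attr(ev, "genome") <- genome
  attr(ev, "provenance") <- provenance
  class(ev) <- c("cn_event_set", class(ev))
  ev
}

#' @export
print.cn_event_set <- function(x, ...) {
  cat(sprintf(
    "<cn_event_set> sample %s: %d events (%d gain, %d loss), %.1f Mb total\n",
    attr(x, "sample_id"), nrow(x), sum(x$state == "gain"),
    sum(x$state == "loss"), sum(x$length) / 1e6))
  NextMethod()
}

#' Remove BAF-borderline events
#'
#' Events whose mean B-allele frequency sits strictly inside the
#' balanced band (default 0.3-0.7, open interval) show no allelic
#' imbalance and are treated as borderline calls.  Events with no BAF
#' value are kept: absence of evidence is not evidence of balance.
#' Bounds are exclusive, so an event at exactly 0.3 or 0.7 counts as
#' imbalanced and is kept.
#'
#' @param events A `cn_event_set` from [call_events()].
#' @param band Length-2 numeric, the open balanced-BAF interval.
#' @return A `cn_event_set` restricted to events outside the band, with
#'   the band recorded in the provenance attribute.
#' @export
baf_borderline_filter <- function(events, band = c(0.3, 0.7)) {
  stopifnot(inherits(events, "cn_event_set"))
  if (length(band) != 2 || band[1] >= band[2]) {
    stop("band must be (low, high) with low < high", call. = FALSE)
  }
  keep <- is.na(events$mean_baf) |
    events$mean_baf <= band[1] | events$mean_baf >= band[2]
  prov <- attr(events, "provenance")
  prov$baf_band <- band
  new_event_set(events[keep, ], attr(events, "sample_id"),
                attr(events, "genome"), prov)
}

#' Write copy-number events as BED
#'
#' The name field carries the event state and the score the adjusted
#' copy number times 100, rounded to an integer.
#'
#' @param events A `cn_event_set`.
#' @param path Output path.
#' @export
write_events_bed <- function(events, path) {
  write_bed(tibble::tibble(
    chrom = events$chrom, start = events$start, end = events$end,
    name = events$state, score = as.integer(round(events$cn * 100))
  ), path)
}
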