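# Independent oracles used to validate the implementation, kept
# deliberately naive: per-basepair tallies, full enumeration, direct
# beta-quantile formulas.

# Per-basepair tally of the GI parameters on a toy genome.  Marks every
# base of every event in integer vectors, then counts.  Only valid for
# genomes small enough to hold per-bp vectors.
oracle_gi_bp <- function(events, events_baf, loh, genome) {
  total <- sum(genome$length)
  mark_len <- function(tab, states = NULL) {
    covered <- 0
    for (ci in seq_len(nrow(genome))) {
      v <- logical(genome$length[ci])
      sel <- tab$chrom == genome$chrom[ci]
      if (!is.null(states)) sel <- sel & tab$state %in% states
      for (i in which(sel)) {
        v[(tab$start[i] + 1):tab$end[i]] <- TRUE
      }
      covered <- covered + sum(v)
    }
    covered
  }
  n_of <- function(tab, states = NULL) {
    if (is.null(states)) nrow(tab) else sum(tab$state %in% states)
  }
  tier <- function(tab) {
    n <- nrow(tab)
    len <- mark_len(tab)
    c(n = n, mean = if (n == 0) 0 else len / n, len = len,
      pct = 100 * len / total)
  }
  a <- tier(events)
  b <- tier(events_baf)
  loh10 <- loh[loh$end - loh$start > 10e6, ]
  loh15 <- loh[loh$end - loh$start > 15e6, ]
  list(
    n_events = a[["n"]], mean_event_length = a[["mean"]],
    altered_length = a[["len"]], pct_genome_altered = a[["pct"]],
    n_events_baf = b[["n"]], mean_event_length_baf = b[["mean"]],
    altered_length_baf = b[["len"]], pct_genome_altered_baf = b[["pct"]],
    n_gains = n_of(events, "gain"),
    gain_length = mark_len(events, "gain"),
    pct_genome_gains = 100 * mark_len(events, "gain") / total,
    n_gains_baf = n_of(events_baf, "gain"),
    gain_length_baf = mark_len(events_baf, "gain"),
    pct_genome_gains_baf = 100 * mark_len(events_baf, "gain") / total,
    n_losses = n_of(events, "loss"),
    loss_length = mark_len(events, "loss"),
    pct_genome_losses = 100 * mark_len(events, "loss") / total,
    n_loh = nrow(loh), loh_length = mark_len(loh),
    pct_genome_loh = 100 * mark_len(loh) / total,
    n_loh_15mb = nrow(loh15), loh_length_15mb = mark_len(loh15),
    pct_genome_loh_15mb = 100 * mark_len(loh15) / total,
    n_loh_10mb = nrow(loh10), loh_length_10mb = mark_len(loh10),
    pct_genome_loh_10mb = 100 * mark_len(loh10) / total
  )
}

# Exact two-sided rank-sum p value by full enumeration of all
# assignments of the pooled observations to the two groups.
oracle_wilcoxon_exact <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  n <- length(pooled)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n, n1)
  u_all <- apply(combos, 2, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  p_lo <- mean(u_all <= u_obs)
  p_hi <- mean(u_all >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Clopper-Pearson bounds straight from the beta-quantile construction.
oracle_clopper_pearson <- function(k, n, conf = 0.95) {
  a <- (1 - conf) / 2
  lo <- if (k == 0) 0 else stats::qbeta(a, k, n - k + 1)
  hi <- if (k == n) 1 else stats::qbeta(1 - a, k + 1, n - k)
  c(lo, hi)
}

# Log-rank chi-square assembled by hand from the per-event-time
# 2 x 2 risk tables (hypergeometric variance).
oracle_logrank <- function(time, event, group) {
  group <- as.integer(as.factor(group))
  stopifnot(all(group %in% 1:2))
  times <- sort(unique(time[event]))
  o_minus_e <- 0
  v <- 0
  for (t in times) {
    at_risk <- time >= t
    n1 <- sum(at_risk & group == 1)
    n2 <- sum(at_risk & group == 2)
    d <- sum(event & time == t)
    d1 <- sum(event & time == t & group == 1)
    nn <- n1 + n2
    if (nn < 2 || d == 0) next
    o_minus_e <- o_minus_e + d1 - d * n1 / nn
    v <- v + d * (n1 / nn) * (n2 / nn) * (nn - d) / (nn - 1)
  }
  chisq <- o_minus_e^2 / v
  c(chisq = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}
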