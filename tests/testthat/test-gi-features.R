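test_that("empty inputs give an all-zero GI vector", {
  gm <- genome_model("chr1", 100e6)
  gi <- compute_gi_vector(make_event_set(gm), make_event_set(gm),
                          make_loh_set(gm), gm)
  vals <- unlist(gi[, setdiff(names(gi), "sample")])
  expect_true(all(vals == 0))
  expect_equal(ncol(gi) - 1, nrow(gi_parameter_dictionary()))
})

test_that("the worked toy genome reproduces the hand-computed vector", {
  gm <- genome_model("chr1", 100e6)
  ev <- make_event_set(gm, c("chr1", "chr1"), c(0, 30e6), c(5e6, 45e6),
                       state = c("gain", "loss"), cn = c(4, 1),
                       mean_baf = c(0.9, 0.1))
  loh <- make_loh_set(gm, c("chr1", "chr1"), c(50e6, 70e6),
                      c(62e6, 90e6))   # 12 and 20 Mb
  gi <- compute_gi_vector(ev, baf_borderline_filter(ev), loh, gm)
  expect_equal(gi$n_events, 2)
  expect_equal(gi$mean_event_length, 10e6)
  expect_equal(gi$altered_length, 20e6)
  expect_equal(gi$pct_genome_altered, 20)
  expect_equal(gi$n_gains, 1)
  expect_equal(gi$gain_length, 5e6)
  expect_equal(gi$pct_genome_gains, 5)
  expect_equal(gi$n_losses, 1)
  expect_equal(gi$loss_length, 15e6)
  expect_equal(gi$pct_genome_losses, 15)
  expect_equal(gi$loh_length, 32e6)
  expect_equal(gi$pct_genome_loh, 32)
  expect_equal(gi$n_loh_10mb, 2)
  expect_equal(gi$loh_length_10mb, 32e6)
  expect_equal(gi$pct_genome_loh_10mb, 32)
  expect_equal(gi$n_loh_15mb, 1)
  expect_equal(gi$loh_length_15mb, 20e6)
  expect_equal(gi$pct_genome_loh_15mb, 20)
  # no BAF removals, so the filtered tier matches the full tier
  expect_equal(gi$n_events_baf, 2)
  expect_equal(gi$altered_length_baf, 20e6)

  # a balanced-BAF gain drops out of the filtered tier only
  ev2 <- make_event_set(gm, c("chr1", "chr1"), c(0, 30e6), c(5e6, 45e6),
                        state = c("gain", "loss"), cn = c(4, 1),
                        mean_baf = c(0.5, 0.1))
  gi2 <- compute_gi_vector(ev2, baf_borderline_filter(ev2), loh, gm)
  expect_equal(gi2$n_events_baf, 1)
  expect_equal(gi2$mean_event_length_baf, 15e6)
  expect_equal(gi2$altered_length_baf, 15e6)
  expect_equal(gi2$pct_genome_altered_baf, 15)
  expect_equal(gi2$n_gains_baf, 0)
  expect_equal(gi2$gain_length_baf, 0)
  expect_equal(gi2$n_gains, 1)
})

test_that("GI vector equals the per-basepair brute-force tally", {
  set.seed(71)
  gm <- toy_genome()
  for (i in 1:100) {
    iv <- random_intervals(gm, n_try = 8)
    if (is.null(iv) || nrow(iv) == 0) next
    n <- nrow(iv)
    ev <- make_event_set(gm, iv$chrom, iv$start, iv$end,
                         state = sample(c("gain", "loss"), n, TRUE),
                         cn = sample(c(1, 4), n, TRUE),
                         mean_baf = ifelse(stats::runif(n) < 0.3, NA,
                                           round(stats::runif(n), 3)))
    ev_baf <- baf_borderline_filter(ev)
    liv <- random_intervals(gm, n_try = 4)
    loh <- if (is.null(liv)) make_loh_set(gm) else {
      make_loh_set(gm, liv$chrom, liv$start, liv$end)
    }
    gi <- compute_gi_vector(ev, ev_baf, loh, gm)
    oracle <- oracle_gi_bp(ev, ev_baf, loh, gm)
    for (p in names(oracle)) {
      expect_equal(gi[[p]], unname(oracle[[p]]), tolerance = 1e-12,
                   label = p)
    }
  }
})

test_that("percentages are invariant under a common genome scaling", {
  gm <- genome_model(c("chr1", "chr2"), c(100e6, 60e6))
  ev <- make_event_set(gm, c("chr1", "chr2"), c(0, 10e6), c(20e6, 40e6),
                       state = c("gain", "loss"), cn = c(4, 1),
                       mean_baf = c(0.9, 0.1))
  loh <- make_loh_set(gm, "chr1", 40e6, 70e6)
  gi <- compute_gi_vector(ev, baf_borderline_filter(ev), loh, gm)
  s <- 4
  gms <- genome_model(c("chr1", "chr2"), c(100e6, 60e6) * s)
  evs <- make_event_set(gms, c("chr1", "chr2"), c(0, 10e6) * s,
                        c(20e6, 40e6) * s,
                        state = c("gain", "loss"), cn = c(4, 1),
                        mean_baf = c(0.9, 0.1))
  lohs <- make_loh_set(gms, "chr1", 40e6 * s, 70e6 * s)
  gis <- compute_gi_vector(evs, baf_borderline_filter(evs), lohs, gms)
  pct_cols <- grep("^pct_", names(gi), value = TRUE)
  # long-LOH thresholds are absolute spans, so compare the scale-free
  # tiers: counts and overall percentages
  for (p in c("pct_genome_altered", "pct_genome_gains",
              "pct_genome_losses", "pct_genome_loh")) {
    expect_equal(gis[[p]], gi[[p]], label = p)
  }
  expect_equal(gis$n_events, gi$n_events)
  expect_equal(gis$n_loh, gi$n_loh)
})

test_that("a genome mismatch between inputs errors", {
  gm <- genome_model("chr1", 100e6)
  other <- genome_model("chr1", 50e6)
  ev <- make_event_set(gm, "chr1", 0, 5e6, "gain", 4, 0.9)
  expect_error(
    compute_gi_vector(ev, baf_borderline_filter(ev),
                      make_loh_set(other), gm),
    "different genome"
  )
})

test_that("median categorization splits at the cohort median", {
  cat1 <- categorize(c(1, 2, 3, 4), "median")
  expect_equal(attr(cat1, "cuts"), 2.5)
  expect_equal(as.character(cat1$category), c("low", "low", "high", "high"))
  expect_warning(flat <- categorize(c(2, 2, 2), "median"), "degenerate")
  expect_equal(as.character(flat$category), rep("low", 3))
  expect_error(categorize(c(1, NA, NA), "median"), "at least 2")
  # missing values keep a missing label
  with_na <- categorize(c(1, 2, NA, 4), "median")
  expect_true(is.na(with_na$category[3]))
})

test_that("quartile categorization uses interpolated right-closed cuts", {
  cat4 <- categorize(1:8, "quartile")
  expect_equal(as.integer(table(cat4$category)), c(2, 2, 2, 2))
  expect_equal(attr(cat4, "cuts"),
               stats::quantile(1:8, c(0.25, 0.5, 0.75), names = FALSE))
  # values exactly at the cuts (2, 3, 4 for 1:5) go to the lower bin
  catc <- categorize(1:5, "quartile")
  expect_equal(as.character(catc$category), c("Q1", "Q1", "Q2", "Q3", "Q4"))
  expect_error(categorize(c(1, 2, 3), "quartile"), "at least 4")
})

test_that("median-scheme imbalance is bounded by the ties at the cut", {
  # without ties at the median an even-sized cohort splits exactly in
  # half; with t tied values the imbalance cannot exceed 2t (the tied
  # block sits entirely in the low bin)
  set.seed(81)
  for (i in 1:20) {
    v <- sample(0:10, 24, replace = TRUE)
    cats <- categorize(v, "median")
    med <- attr(cats, "cuts")
    ties <- sum(v == med)
    tab <- table(cats$category)
    imbalance <- abs(tab[["low"]] - tab[["high"]])
    if (ties == 0) expect_equal(imbalance, 0) else {
      expect_lte(imbalance, 2 * ties)
    }
  }
})
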