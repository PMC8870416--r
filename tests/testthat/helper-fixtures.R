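# Fixture builders shared across the suite.  Everything is generated
# in code; nothing is read from disk except through the package's own
# writers.

toy_genome <- function(lengths = c(chrA = 600e3, chrB = 400e3)) {
  genome_model(names(lengths), unname(lengths))
}

# A segment profile built directly from a compact spec table.
make_profile <- function(genome, chrom, start, end, log2_ratio,
                         mean_baf = NA, p_value = NA, purity = 1,
                         sample_id = "T1") {
  segment_profile(
    tibble::tibble(chrom = chrom, start = start, end = end,
                   log2_ratio = log2_ratio, mean_baf = mean_baf,
                   p_value = p_value),
    sample_id = sample_id, genome = genome, purity = purity
  )
}

# Event sets / LOH sets assembled without going through the callers,
# for feeding compute_gi_vector directly.
make_event_set <- function(genome, chrom = character(), start = numeric(),
                           end = numeric(), state = character(),
                           cn = numeric(), mean_baf = NA_real_,
                           sample_id = "T1") {
  ev <- tibble::tibble(chrom = chrom, start = start, end = end,
                       state = state,
                       cn = if (length(cn)) cn else numeric(),
                       mean_baf = rep_len(mean_baf, length(chrom)))
  hrdgi:::new_event_set(ev, sample_id = sample_id, genome = genome,
                        provenance = list())
}

make_loh_set <- function(genome, chrom = character(), start = numeric(),
                         end = numeric(), sample_id = "T1") {
  out <- tibble::tibble(chrom = chrom, start = start, end = end,
                        length = end - start,
                        n_snps = rep(100L, length(chrom)),
                        baf_dev = rep(0.4, length(chrom)))
  attr(out, "sample_id") <- sample_id
  attr(out, "genome") <- genome
  class(out) <- c("loh_segments", class(out))
  out
}

# Random non-overlapping intervals on a genome: draws candidate
# intervals and keeps the non-overlapping prefix.
random_intervals <- function(genome, n_try = 10, max_len = 50e3) {
  out <- NULL
  for (i in seq_len(n_try)) {
    ci <- sample.int(nrow(genome), 1)
    len <- sample.int(max_len, 1)
    if (len >= genome$length[ci]) next
    s <- sample.int(genome$length[ci] - len, 1)
    cand <- tibble::tibble(chrom = genome$chrom[ci], start = s,
                           end = s + len)
    clash <- !is.null(out) && any(
      out$chrom == cand$chrom & out$start < cand$end &
        cand$start < out$end
    )
    if (!clash) out <- rbind(out, cand)
  }
  out
}

# SNP table built in code (positions 0-based already).
make_snp_sites <- function(genome, chrom, pos, geno_rows, tumor_baf) {
  geno <- do.call(rbind, geno_rows)
  hrdgi:::new_snp_sites(chrom, pos, geno, tumor_baf, genome,
                        panel_size = ncol(geno))
}

# Clinical table mirroring the published cohort's printed counts:
# 73 patients, 1 CR + 6 PR + 46 SD + 15 PD + 5 NE, all progression
# events observed, ordered PFS with the 37th value at 4.54 months and
# 12 patients at or above twice that.
printed_count_clinical <- function() {
  n <- 73
  pfs <- c(seq(0.5, 4.53, length.out = 36),            # below the median
           4.54,                                       # the KM median
           seq(4.6, 8.9, length.out = 24),             # mid-range
           c(9.08, 10, 11, 12, 12.5, 13.3,             # long-term tail,
             13.3, 14, 16, 18, 21, 24))                # median 13.3
  stopifnot(length(pfs) == n, sum(pfs >= 2 * 4.54) == 12,
            stats::median(pfs[pfs >= 2 * 4.54]) == 13.3)
  best <- c("CR", rep("PR", 6), rep("SD", 46), rep("PD", 15),
            rep("NE", 5))
  # responders among the longest PFS, as observed in trials
  best <- best[order(match(best, c("PD", "SD", "NE", "PR", "CR")))]
  tibble::tibble(
    patient_id = sprintf("PT%02d", seq_len(n)),
    tumor_type = rep(c("ovarian", "endometrial", "breast"),
                     c(46, 26, 1)),
    histology = "unspecified",
    prior_lines = rep(c(1L, 2L, 3L, 4L), length.out = n),
    best_response = best,
    pfs_months = pfs,
    pfs_event = TRUE,
    os_months = pfs + 6,
    os_event = rep(c(TRUE, FALSE), length.out = n)
  ) -> cl
  class(cl) <- c("clinical_table", class(cl))
  cl
}

# Variant table with ten qualifying HRR variants across a 57-sample
# cohort (genes as reported for this panel), everything else silent.
printed_count_variants <- function() {
  samples <- sprintf("S%02d", 1:57)
  hrr_hits <- c("BRCA1", "BRCA1", "BRCA1", "BRCA2", "ATM", "ATM",
                "ATR", "NBN", "SLX4", "WRN")
  v <- tibble::tibble(
    sample = samples[1:10],
    gene = hrr_hits,
    coverage = 250,
    vaf = 0.35,
    classification = "P",
    sift = "pathogenic",
    polyphen = "pathogenic",
    path_prediction = NA
  )
  # non-HRR background in other samples: must not flip HRD status
  bg <- tibble::tibble(
    sample = samples[11:40],
    gene = "TP53", coverage = 300, vaf = 0.4,
    classification = "P", sift = "pathogenic",
    polyphen = "pathogenic", path_prediction = NA
  )
  out <- rbind(v, bg)
  class(out) <- c("variant_table", class(out))
  list(variants = out, samples = samples)
}

simple_clinical <- function(best, pfs, event = TRUE) {
  n <- length(best)
  cl <- tibble::tibble(
    patient_id = sprintf("P%d", seq_len(n)), tumor_type = "ovarian",
    histology = "HGS", prior_lines = 2L, best_response = best,
    pfs_months = pfs, pfs_event = rep_len(event, n),
    os_months = pfs + 1, os_event = rep_len(event, n)
  )
  class(cl) <- c("clinical_table", class(cl))
  cl
}

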