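het5 <- function(n) replicate(n, rep("het", 5), simplify = FALSE)

test_that("the heterozygosity mask applies the panel majority rule", {
  gm <- genome_model("chr1", 1e6)
  geno <- list(
    rep("het", 5),                                  # 5/5 het: in
    c("het", "het", "hom-ref", "hom-alt", "hom-ref"),  # 2/5: out
    c("het", "het", "het", "hom-ref", "hom-ref"),   # 3/5: in
    c("het", "het", "het", "het", NA)               # missing: out
  )
  sites <- make_snp_sites(gm, rep("chr1", 4), c(100, 200, 300, 400),
                          geno, rep(NA_real_, 4))
  mask <- build_het_mask(sites, min_het_controls = 3)
  expect_equal(mask$pos, c(100, 300))
  expect_error(build_het_mask(sites, min_het_controls = 6),
               "between 1 and the panel size")
})

test_that("raising min_het_controls never grows the mask", {
  gm <- genome_model("chr1", 1e6)
  set.seed(41)
  geno <- replicate(200, sample(c("het", "hom-ref", "hom-alt", NA), 5,
                                replace = TRUE,
                                prob = c(0.5, 0.2, 0.2, 0.1)),
                    simplify = FALSE)
  sites <- make_snp_sites(gm, rep("chr1", 200), seq(1000, 200000, 1000),
                          geno, rep(NA_real_, 200))
  sizes <- vapply(1:5, function(k) {
    nrow(build_het_mask(sites, min_het_controls = k))
  }, integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("LOH is called from folded BAF over masked SNPs", {
  gm <- genome_model("chr1", 60e6)
  prof <- make_profile(gm, "chr1", c(0, 10e6), c(10e6, 60e6),
                       log2_ratio = c(0, 0))
  pos <- seq(1e5, 9.9e6, length.out = 50)
  all_pos <- c(pos, seq(10.1e6, 59e6, length.out = 100))
  baf_rest <- rep(0.5, 100)

  run <- function(baf_tract, min_snps = 10) {
    sites <- make_snp_sites(gm, rep("chr1", 150), all_pos,
                            het5(150), c(baf_tract, baf_rest))
    mask <- build_het_mask(sites)
    call_loh(prof, sites, mask, min_snps = min_snps)
  }

  hom_shift <- run(rep(0.95, 50))
  expect_equal(nrow(hom_shift), 1)
  expect_equal(hom_shift$start, 0)
  expect_equal(hom_shift$end, 10e6)
  expect_equal(hom_shift$baf_dev, 0.45)

  # retained heterozygosity is not LOH
  expect_equal(nrow(run(rep(0.5, 50))), 0)

  # folding: per-SNP loss of either parental allele still registers
  expect_equal(nrow(run(rep(c(0.05, 0.95), 25))), 1)

  # informativeness gate: below min_snps nothing is called
  few <- make_snp_sites(gm, rep("chr1", 105),
                        c(pos[1:5], seq(10.1e6, 59e6, length.out = 100)),
                        het5(105), c(rep(0.95, 5), baf_rest))
  mask <- build_het_mask(few)
  expect_equal(nrow(call_loh(prof, few, mask)), 0)

  # purity dilution: a clonal one-copy loss at purity 0.4 has BAF
  # (0.4 * 1 + 0.6) / (0.4 * 1 + 1.2) = 0.625, inside the band
  diluted <- run(rep(0.625, 50))
  expect_equal(nrow(diluted), 0)
})

test_that("uncovered chromosomes are tiled so cnLOH is still found", {
  gm <- genome_model(c("chr1", "chr2"), c(30e6, 40e6))
  prof <- make_profile(gm, "chr1", 0, 30e6, 0)   # nothing on chr2
  pos2 <- seq(1e5, 39.9e6, by = 2e5)
  baf2 <- ifelse(pos2 < 12e6, 0.92, 0.5)
  pos1 <- seq(1e5, 29.9e6, by = 2e5)
  sites <- make_snp_sites(
    gm, c(rep("chr1", length(pos1)), rep("chr2", length(pos2))),
    c(pos1, pos2), het5(length(pos1) + length(pos2)),
    c(rep(0.5, length(pos1)), baf2)
  )
  mask <- build_het_mask(sites)
  loh <- call_loh(prof, sites, mask)
  expect_equal(loh$chrom, "chr2")
  expect_equal(loh$start, 0)
  expect_equal(loh$end, 10e6)    # tract recovered at tile resolution
})

test_that("raising min_snps never grows the LOH call set", {
  gm <- genome_model("chr1", 60e6)
  set.seed(51)
  for (i in 1:10) {
    cuts <- sort(sample(seq(1e6, 59e6, by = 1e6), 4))
    prof <- make_profile(gm, "chr1", c(0, cuts), c(cuts, 60e6),
                         log2_ratio = rep(0, 5))
    pos <- seq(1e5, 59.9e6, length.out = 300)
    baf <- ifelse(stats::runif(300) < 0.4, 0.95,
                  stats::runif(300, 0.4, 0.6))
    sites <- make_snp_sites(gm, rep("chr1", 300), pos, het5(300), baf)
    mask <- build_het_mask(sites)
    counts <- vapply(c(5, 10, 20, 40), function(ms) {
      nrow(call_loh(prof, sites, mask, min_snps = ms))
    }, integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("long-LOH selection is a strict threshold and monotone", {
  gm <- genome_model("chr1", 100e6)
  loh <- make_loh_set(gm, rep("chr1", 3), c(0, 20e6, 40e6),
                      c(9e6, 32e6, 60e6))   # 9, 12, 20 Mb
  over10 <- long_loh_events(loh, 10e6)
  expect_equal(over10$length, c(12e6, 20e6))
  over15 <- long_loh_events(loh, 15e6)
  expect_equal(over15$length, 20e6)
  expect_equal(nrow(long_loh_events(make_loh_set(gm), 10e6)), 0)

  set.seed(61)
  for (i in 1:50) {
    n <- sample(0:8, 1)
    start <- sort(sample(seq(0, 80e6, by = 1e6), n))
    len <- sample(seq(1e6, 19e6, by = 1e6), n, replace = TRUE)
    loh <- make_loh_set(gm, rep("chr1", n), start, pmin(start + len, 100e6))
    a <- long_loh_events(loh, 15e6)
    b <- long_loh_events(loh, 10e6)
    expect_lte(nrow(a), nrow(b))
    expect_lte(sum(a$length), sum(b$length))
    key <- paste(a$start, a$end)
    expect_true(all(key %in% paste(b$start, b$end)))
  }
})
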