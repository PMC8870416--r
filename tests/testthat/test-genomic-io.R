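test_that("genome model validates names and lengths", {
  gm <- genome_model(c("chr1", "chr2"), c(100, 200))
  expect_equal(genome_total_length(gm), 300)
  expect_error(genome_model(c("chr1", "chr1"), c(1, 2)), "duplicated")
  expect_error(genome_model("chr1", 0), "positive")
  expect_error(genome_model(character(), numeric()), "at least one")
})

test_that("segment files convert 1-based inclusive to internal 0-based", {
  gm <- genome_model("chr1", 5e6)
  path <- withr::local_tempfile(fileext = ".seg")
  readr::write_tsv(tibble::tibble(
    sample = "T1", chrom = "chr1",
    start = c(1, 1000001), end = c(1000000, 2000000),
    log2_ratio = c(0, 0.8)
  ), path)
  prof <- read_segments(path, gm)
  expect_s3_class(prof, "segment_profile")
  expect_equal(prof$start, c(0, 1000000))
  expect_equal(prof$end, c(1000000, 2000000))
  expect_equal(attr(prof, "sample_id"), "T1")
})

test_that("overlapping, out-of-bounds and unknown-chromosome segments error", {
  gm <- genome_model("chr1", 5e6)
  write_seg <- function(start, end, chrom = "chr1") {
    path <- withr::local_tempfile(fileext = ".seg", .local_envir = parent.frame())
    readr::write_tsv(tibble::tibble(
      sample = "T1", chrom = chrom, start = start, end = end,
      log2_ratio = 0
    ), path)
    path
  }
  expect_error(read_segments(write_seg(c(1, 500000), c(1000000, 1500000)), gm),
               "overlap")
  expect_error(read_segments(write_seg(1, 6e6), gm), "bounds")
  expect_error(read_segments(write_seg(1, 100, chrom = "chrX"), gm),
               "unknown chromosome")
})

test_that("segment read/write round trip is the identity", {
  set.seed(11)
  gm <- genome_model(c("chr1", "chr2"), c(2e6, 1e6))
  for (rep in 1:10) {
    iv <- random_intervals(gm, n_try = 8)
    prof <- make_profile(
      gm, iv$chrom, iv$start, iv$end,
      log2_ratio = round(stats::rnorm(nrow(iv)), 4),
      mean_baf = ifelse(stats::runif(nrow(iv)) < 0.3, NA,
                        round(stats::runif(nrow(iv)), 4)),
      p_value = round(stats::runif(nrow(iv)), 5)
    )
    path <- withr::local_tempfile(fileext = ".seg")
    write_segments(prof, path)
    back <- read_segments(path, gm)
    expect_equal(tibble::as_tibble(back), tibble::as_tibble(prof))
  }
})

test_that("SNP tables enforce the panel size and chromosome bounds", {
  gm <- genome_model("chr1", 1e6)
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- tibble::tibble(
    chrom = "chr1", pos = c(100, 200),
    ctrl1 = c("het", "hom-ref"), ctrl2 = "het", ctrl3 = "het",
    ctrl4 = c("missing", "het"), ctrl5 = "hom-alt"
  )
  readr::write_tsv(tab, path)
  sites <- read_snp_table(path, gm, panel_size = 5)
  expect_equal(nrow(sites), 2)
  expect_equal(sites$pos, c(99, 199))            # 1-based file, 0-based internal
  expect_true(is.na(sites$ctrl4[1]))
  expect_error(read_snp_table(path, gm, panel_size = 4), "expected 4")
  bad <- tab
  bad$pos[1] <- 2e6
  readr::write_tsv(bad, path)
  expect_error(read_snp_table(path, gm, panel_size = 5), "bounds")
})

test_that("clinical tables validate responses and report row errors", {
  ok <- tibble::tibble(
    patient_id = "P1", tumor_type = "ovarian", histology = "HGS",
    prior_lines = 3, best_response = "CR", pfs_months = 13.3,
    pfs_event = TRUE, os_months = 20, os_event = FALSE
  )
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(ok, path)
  cl <- read_clinical_table(path)
  expect_equal(cl$best_response, "CR")
  expect_equal(cl$pfs_months, 13.3)

  bad <- ok
  bad$best_response <- "XX"
  readr::write_csv(bad, path)
  expect_error(read_clinical_table(path), "unknown best_response.*row 1")

  bad <- ok
  bad$pfs_months <- -1
  readr::write_csv(bad, path)
  expect_error(read_clinical_table(path), "pfs_months")

  readr::write_csv(ok[0, ], path)
  expect_warning(empty <- read_clinical_table(path), "empty")
  expect_equal(nrow(empty), 0)
})

test_that("variant and clinical tables round trip through their writers", {
  v <- printed_count_variants()$variants
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(v, path)
  back <- read_variant_table(path)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(v),
               ignore_attr = TRUE)

  cl <- printed_count_clinical()
  cpath <- withr::local_tempfile(fileext = ".csv")
  write_clinical_table(cl, cpath)
  back <- read_clinical_table(cpath)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(cl),
               ignore_attr = TRUE)
})

test_that("BED intervals are 0-based half-open and bounds-checked", {
  gm <- genome_model("chr1", 1e6)
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(tibble::tibble(chrom = "chr1", start = 0, end = 100,
                           name = "geneA"), path)
  bed <- read_bed(path, gm)
  expect_equal(bed$start, 0)
  expect_equal(bed$end, 100)
  expect_equal(bed$name, "geneA")
  write_bed(tibble::tibble(chrom = "chr1", start = 0, end = 2e6,
                           name = "bad"), path)
  expect_error(read_bed(path, gm), "bounds")
})
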