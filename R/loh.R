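#' Build a constitutive heterozygosity mask from a panel of normals
#'
#' LOH can only be read off SNPs that are heterozygous in the germline.
#' Without a matched normal, constitutively heterozygous sites are
#' approximated by the control panel: a site enters the mask when at
#' least `min_het_controls` controls are heterozygous and no control
#' genotype is missing at the site (missing calls never count toward
#' the heterozygote tally).
#'
#' @param sites A `snp_sites` tibble (see [read_snp_table()]).
#' @param min_het_controls Minimum heterozygous controls (default 3 of
#'   a 5-normal panel: a majority rule robust to single-control
#'   genotyping noise).
#' @return A tibble of class `het_mask` with columns `chrom`, `pos`,
#'   positions strictly increasing within each chromosome.
#' @export
build_het_mask <- function(sites, min_het_controls = 3) {
  stopifnot(inherits(sites, "snp_sites"))
  panel_size <- attr(sites, "panel_size")
  if (min_het_controls < 1 || min_het_controls > panel_size) {
    stop("min_het_controls must be between 1 and the panel size",
         call. = FALSE)
  }
  ctrl_cols <- grep("^ctrl", names(sites), value = TRUE)
  geno <- as.matrix(tibble::as_tibble(sites)[, ctrl_cols])
  n_het <- rowSums(geno == "het", na.rm = TRUE)
  any_missing <- rowSums(is.na(geno)) > 0
  keep <- !any_missing & n_het >= min_het_controls
  out <- tibble::tibble(chrom = sites$chrom[keep], pos = sites$pos[keep])
  attr(out, "min_het_controls") <- as.integer(min_het_controls)
  attr(out, "genome") <- attr(sites, "genome")
  class(out) <- c("het_mask", class(out))
  out
}

#' Write a heterozygosity mask as a two-column TSV
#' @param mask A `het_mask`.
#' @param path Output path (positions written 1-based).
#' @export
write_het_mask <- function(mask, path) {
  readr::write_tsv(
    tibble::tibble(chrom = mask$chrom, pos = format_bp(mask$pos + 1)),
    path, progress = FALSE
  )
  invisible(path)
}

#' Call LOH segments from tumor BAF over the heterozygosity mask
#'
#' Evaluates allelic imbalance interval by interval.  The intervals are
#' the sample's copy-number segments; genomic spans not covered by any
#' segment (including whole chromosomes without segments) are windowed
#' into `tile_width` tiles so copy-neutral LOH in unsegmented regions
#' remains detectable.  Within each interval the tumor BAFs at masked
#' SNPs are folded about 0.5 (`max(b, 1 - b)`, removing the arbitrary
#' choice of which parental allele is lost) and the interval is called
#' LOH when it holds at least `min_snps` informative SNPs and the
#' median folded BAF falls outside the open balanced band.  Adjacent
#' called intervals merge, and the same minimum-length artifact filter
#' used for copy-number events applies last.
#'
#' Note the purity sensitivity: a fully clonal LOH tract at tumor
#' purity `p` has expected BAF `(p + (1 - p)) / (p + 2 (1 - p))` on the
#' major allele; below roughly `p = 0.46` this drops back inside the
#' 0.3-0.7 band and the tract is no longer separable from balance.
#'
#' @param profile A [segment_profile()] supplying the intervals.
#' @param sites A `snp_sites` tibble with `tumor_baf` for this sample.
#' @param mask A [build_het_mask()] result.
#' @param baf_band Open balanced-BAF interval (default `c(0.3, 0.7)`,
#'   shared with [baf_borderline_filter()]).
#' @param min_snps Minimum informative SNPs per interval (default 10).
#' @param min_length Minimum LOH segment length after merging (default
#'   1e6 bp).
#' @param tile_width Window size for spans without copy-number segments
#'   (default 10e6 bp).
#' @return A tibble of class `loh_segments` with columns `chrom`,
#'   `start`, `end`, `length`, `n_snps`, `baf_dev` (median folded BAF
#'   deviation from 0.5, in [0, 0.5]).
#' @export
call_loh <- function(profile, sites, mask, baf_band = c(0.3, 0.7),
                     min_snps = 10, min_length = 1e6, tile_width = 10e6) {
  stopifnot(inherits(profile, "segment_profile"),
            inherits(sites, "snp_sites"), inherits(mask, "het_mask"))
  if (length(baf_band) != 2 || baf_band[1] >= baf_band[2]) {
    stop("baf_band must be (low, high) with low < high", call. = FALSE)
  }
  genome <- attr(profile, "genome")

  intervals <- loh_intervals(profile, genome, tile_width)

  # informative sites: masked positions with a tumor BAF value
  # (numeric chrom-rank keying avoids string matching on large tables)
  mask_key <- chrom_rank(mask$chrom, genome, "mask site") * 2^40 + mask$pos
  site_key <- chrom_rank(sites$chrom, genome, "SNP site") * 2^40 + sites$pos
  keep <- !is.na(sites$tumor_baf) & site_key %in% mask_key
  snp <- quick_tbl(chrom = sites$chrom[keep], pos = sites$pos[keep],
                   tumor_baf = sites$tumor_baf[keep])
  snp$fold <- pmax(snp$tumor_baf, 1 - snp$tumor_baf)

  iv_chrom <- intervals$chrom
  iv_start <- intervals$start
  iv_end <- intervals$end
  c_chrom <- character(0)
  c_start <- numeric(0)
  c_end <- numeric(0)
  c_n <- integer(0)
  c_dev <- numeric(0)
  for (cc in unique(iv_chrom)) {
    sel_iv <- which(iv_chrom == cc)
    sel_sp <- which(snp$chrom == cc)
    if (length(sel_iv) == 0 || length(sel_sp) == 0) next
    pos <- snp$pos[sel_sp]
    fold <- snp$fold[sel_sp]
    o <- order(pos)
    pos <- pos[o]
    fold <- fold[o]
    hit <- findInterval(pos, iv_start[sel_iv])  # sorted, non-overlapping
    ok <- hit >= 1 & pos < iv_end[sel_iv][pmax(hit, 1)]
    if (!any(ok)) next
    grp <- split(fold[ok], hit[ok])
    idx <- as.integer(names(grp))
    med <- vapply(grp, stats::median, numeric(1))
    n <- lengths(grp)
    is_loh <- n >= min_snps & (med <= baf_band[1] | med >= baf_band[2])
    if (!any(is_loh)) next
    c_chrom <- c(c_chrom, rep(cc, sum(is_loh)))
    c_start <- c(c_start, iv_start[sel_iv][idx[is_loh]])
    c_end <- c(c_end, iv_end[sel_iv][idx[is_loh]])
    c_n <- c(c_n, as.integer(unname(n[is_loh])))
    c_dev <- c(c_dev, unname(abs(med[is_loh] - 0.5)))
  }
  out <- quick_tbl(chrom = c_chrom, start = c_start, end = c_end,
                   n_snps = c_n, baf_dev = c_dev)
  if (nrow(out) == 0) {
    out <- tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), n_snps = integer(),
                          baf_dev = numeric())
  } else {
    out <- merge_loh_segments(out, genome)
  }
  out$length <- out$end - out$start
  out <- out[out$length >= min_length,
             c("chrom", "start", "end", "length", "n_snps", "baf_dev")]
  attr(out, "sample_id") <- attr(profile, "sample_id")
  attr(out, "genome") <- genome
  attr(out, "params") <- list(baf_band = baf_band, min_snps = min_snps,
                              min_length = min_length,
                              tile_width = tile_width)
  class(out) <- c("loh_segments", class(out))
  out
}

# Intervals over which LOH is evaluated: the profile's segments plus
# tiled windows over every uncovered span.
loh_intervals <- function(profile, genome, tile_width) {
  chrom <- character(0)
  start <- numeric(0)
  end <- numeric(0)
  for (ci in seq_along(genome$chrom)) {
    cc <- genome$chrom[ci]
    len <- genome$length[ci]
    sel <- profile$chrom == cc
    s_start <- sort(profile$start[sel])
    s_end <- sort(profile$end[sel])
    bounds <- c(0, rbind(s_start, s_end), len)
    gs <- bounds[seq(1, length(bounds) - 1, by = 2)]
    ge <- bounds[seq(2, length(bounds), by = 2)]
    keep <- ge > gs
    tiles <- tile_spans(gs[keep], ge[keep], tile_width)
    c_start <- c(s_start, tiles$start)
    c_end <- c(s_end, tiles$end)
    o <- order(c_start)
    chrom <- c(chrom, rep(cc, length(c_start)))
    start <- c(start, c_start[o])
    end <- c(end, c_end[o])
  }
  quick_tbl(chrom = chrom, start = start, end = end)
}

tile_spans <- function(start, end, width) {
  ts <- numeric(0)
  te <- numeric(0)
  for (i in seq_along(start)) {
    cuts <- seq(start[i], end[i], by = width)
    if (cuts[length(cuts)] < end[i]) cuts <- c(cuts, end[i])
    ts <- c(ts, cuts[-length(cuts)])
    te <- c(te, cuts[-1])
  }
  list(start = ts, end = te)
}

merge_loh_segments <- function(x, genome) {
  x <- x[order(chrom_rank(x$chrom, genome), x$start), ]
  n <- nrow(x)
  if (n <= 1) return(x)
  new_run <- c(TRUE, x$chrom[-1] != x$chrom[-n] | x$start[-1] > x$end[-n])
  run <- cumsum(new_run)
  len <- x$end - x$start
  first <- which(new_run)
  last <- c(first[-1] - 1L, n)
  quick_tbl(
    chrom = x$chrom[first],
    start = x$start[first],
    end = x$end[last],
    n_snps = as.integer(unname(rowsum(as.numeric(x$n_snps), run)[, 1])),
    baf_dev = unname(rowsum(x$baf_dev * len, run)[, 1] /
                       rowsum(len, run)[, 1])
  )
}

#' Long LOH events above a span threshold
#'
#' Large LOH tracts (conventionally those longer than 10 or 15 Mb) are
#' the span statistics used as an HRD signature; this selects the
#' subset of segments strictly longer than the threshold.
#'
#' @param loh A `loh_segments` tibble from [call_loh()].
#' @param span_threshold Length threshold in bp (strictly greater
#'   than), e.g. `10e6` or `15e6`.
#' @return The qualifying subset, same class and attributes.
#' @export
long_loh_events <- function(loh, span_threshold) {
  stopifnot(inherits(loh, "loh_segments"), is.numeric(span_threshold),
            span_threshold >= 0)
  out <- loh[loh$length > span_threshold, ]
  attributes_keep(out, loh)
}

attributes_keep <- function(out, template) {
  for (a in setdiff(names(attributes(template)),
                    c("row.names", "names", "dim", "dimnames"))) {
    attr(out, a) <- attr(template, a)
  }
  out
}

#' Write LOH segments as BED
#' @param loh A `loh_segments` tibble.
#' @param path Output path.
#' @export
write_loh_bed <- function(loh, path) {
  write_bed(tibble::tibble(
    chrom = loh$chrom, start = loh$start, end = loh$end,
    name = sprintf("loh_dev%.2f", loh$baf_dev),
    score = loh$n_snps
  ), path)
}
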