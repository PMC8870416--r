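#' Build a segment profile
#'
#' A segment profile is one sample's segmented copy-number landscape:
#' non-overlapping genomic intervals annotated with a log2 tumor/normal
#' depth ratio, an optional mean B-allele frequency (BAF), an optional
#' per-segment significance p-value, and the sample's tumor purity.
#' Coordinates are 0-based half-open internally; the on-disk SEG dialect
#' is 1-based inclusive (see [read_segments()]).
#'
#' @param segments A data frame with columns `chrom`, `start`, `end`,
#'   `log2_ratio` and optionally `n_snps`, `p_value`, `mean_baf`
#'   (0-based half-open coordinates).
#' @param sample_id Sample identifier.
#' @param genome A [genome_model()] the intervals must fall inside.
#' @param purity Tumor cell fraction in (0, 1].
#'
#' @return A tibble of class `segment_profile`, sorted by genome order,
#'   with `sample_id`, `genome` and `purity` attached as attributes.
#' @export
segment_profile <- function(segments, sample_id, genome, purity = 1) {
  stopifnot(inherits(genome, "genome_model"))
  check_purity(purity)
  req <- c("chrom", "start", "end", "log2_ratio")
  missing_cols <- setdiff(req, names(segments))
  if (length(missing_cols) > 0) {
    stop("segment table lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  seg <- tibble::as_tibble(segments)
  for (opt in c("n_snps", "p_value", "mean_baf")) {
    if (!opt %in% names(seg)) seg[[opt]] <- NA_real_
  }
  seg <- seg[, c("chrom", "start", "end", "log2_ratio", "n_snps",
                 "p_value", "mean_baf")]
  seg$chrom <- as.character(seg$chrom)
  for (col in c("start", "end", "log2_ratio", "n_snps", "p_value",
                "mean_baf")) {
    seg[[col]] <- as.numeric(seg[[col]])
  }
  if (nrow(seg) > 0) {
    check_intervals_in_genome(seg$chrom, seg$start, seg$end, genome,
                              context = "segment")
    bad_baf <- !is.na(seg$mean_baf) & (seg$mean_baf < 0 | seg$mean_baf > 1)
    if (any(bad_baf)) stop("mean_baf outside [0, 1]", call. = FALSE)
    bad_p <- !is.na(seg$p_value) & (seg$p_value < 0 | seg$p_value > 1)
    if (any(bad_p)) stop("p_value outside [0, 1]", call. = FALSE)
    seg <- seg[order(chrom_rank(seg$chrom, genome), seg$start), ]
    overlap <- with(seg, chrom[-1] == chrom[-nrow(seg)] &
                      start[-1] < end[-nrow(seg)])
    if (nrow(seg) > 1 && any(overlap)) {
      i <- which(overlap)[1L]
      stop(sprintf(
        "overlapping segments on %s: [%.0f, %.0f) and [%.0f, %.0f)",
        seg$chrom[i], seg$start[i], seg$end[i], seg$start[i + 1],
        seg$end[i + 1]
      ), call. = FALSE)
    }
  }
  attr(seg, "sample_id") <- as.character(sample_id)
  attr(seg, "genome") <- genome
  attr(seg, "purity") <- purity
  class(seg) <- c("segment_profile", class(seg))
  seg
}

check_purity <- function(purity) {
  if (!is.numeric(purity) || length(purity) != 1L || is.na(purity) ||
      purity <= 0 || purity > 1) {
    stop("purity must be a single number in (0, 1]", call. = FALSE)
  }
  invisible(purity)
}

#' @export
print.segment_profile <- function(x, ...) {
  cat(sprintf("<segment_profile> sample %s: %d segments, purity %.2f\n",
              attr(x, "sample_id"), nrow(x), attr(x, "purity")))
  NextMethod()
}

#' Read a SEG-style segment file
#'
#' Reads a tab-separated segment table as written by common copy-number
#' segmentation tools: one row per segment with 1-based inclusive
#' coordinates, a log2 ratio, and optional SNP-count, p-value and mean
#' BAF columns.  Coordinates are converted to the package's internal
#' 0-based half-open convention; [write_segments()] converts back, so a
#' read/write round trip is the identity.
#'
#' Recognised column names (case-insensitive): `sample`/`ID`;
#' `chrom`/`chromosome`; `start`/`loc.start`; `end`/`loc.end`;
#' `log2`/`log2_ratio`/`seg.mean`; `n_snps`/`num.mark`/`probes`;
#' `p_value`/`p.value`; `baf`/`mean_baf`.
#'
#' @param path Path to the TSV file.
#' @param genome A [genome_model()]; segments on chromosomes the model
#'   does not contain, or outside chromosome bounds, are an error.
#' @param purity Tumor purity for the sample, in (0, 1].
#' @param sample_id Overrides the sample column (required when the file
#'   has none).
#' @return A [segment_profile()].
#' @export
read_segments <- function(path, genome, purity = 1, sample_id = NULL) {
  tab <- readr::read_tsv(path, col_types = readr::cols(),
                         progress = FALSE)
  nm <- tolower(names(tab))
  pick <- function(...) {
    hit <- match(c(...), nm)
    hit <- hit[!is.na(hit)]
    if (length(hit) == 0) NULL else tab[[hit[1L]]]
  }
  chrom <- pick("chrom", "chromosome", "chr")
  start1 <- pick("start", "loc.start")
  end1 <- pick("end", "loc.end")
  log2r <- pick("log2", "log2_ratio", "seg.mean")
  if (is.null(chrom) || is.null(start1) || is.null(end1) || is.null(log2r)) {
    stop("segment file must name chromosome, start, end and log2 columns",
         call. = FALSE)
  }
  if (is.null(sample_id)) {
    smp <- pick("sample", "id", "sample_id")
    if (is.null(smp)) {
      stop("no sample column in file; supply `sample_id`", call. = FALSE)
    }
    if (length(unique(smp)) > 1) {
      stop("file contains several samples; read them separately",
           call. = FALSE)
    }
    sample_id <- smp[1L]
  }
  segment_profile(
    tibble::tibble(
      chrom = as.character(chrom),
      start = as.numeric(start1) - 1,     # 1-based inclusive -> 0-based
      end = as.numeric(end1),             # inclusive end -> half-open end
      log2_ratio = as.numeric(log2r),
      n_snps = as.numeric(pick("n_snps", "num.mark", "probes") %||% NA),
      p_value = as.numeric(pick("p_value", "p.value") %||% NA),
      mean_baf = as.numeric(pick("baf", "mean_baf") %||% NA)
    ),
    sample_id = sample_id, genome = genome, purity = purity
  )
}

#' Write a segment profile to a SEG-style TSV
#'
#' @param profile A [segment_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(profile, path) {
  stopifnot(inherits(profile, "segment_profile"))
  out <- tibble::tibble(
    sample = attr(profile, "sample_id"),
    chrom = profile$chrom,
    start = format_bp(profile$start + 1),   # back to 1-based inclusive
    end = format_bp(profile$end),
    n_snps = profile$n_snps,
    log2_ratio = profile$log2_ratio,
    p_value = profile$p_value,
    mean_baf = profile$mean_baf
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

format_bp <- function(x) sprintf("%.0f", x)

`%||%` <- function(a, b) if (is.null(a)) b else a
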