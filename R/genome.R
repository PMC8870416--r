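#' Construct a genome model
#'
#' A genome model is the coordinate system every other object in the
#' package lives in: an ordered set of chromosomes with their lengths in
#' base pairs.  All genome-wide percentages (percent of genome altered,
#' percent under LOH, ...) use the total length of this model as their
#' denominator.
#'
#' @param chrom Character vector of chromosome names, in the order they
#'   should sort.  Names must be unique.
#' @param length Integer-ish vector of chromosome lengths in bp, strictly
#'   positive, same length as `chrom`.
#' @param has_sex Logical flag recording whether sex chromosomes are part
#'   of the model.  The shipped defaults are autosome-only, so percentage
#'   denominators are autosomal.
#'
#' @return A tibble of class `genome_model` with columns `chrom` and
#'   `length`, carrying the `has_sex` flag as an attribute.
#' @examples
#' gm <- genome_model(c("chr1", "chr2"), c(50e6, 40e6))
#' genome_total_length(gm)
#' @export
genome_model <- function(chrom, length, has_sex = FALSE) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (base::length(chrom) != base::length(length)) {
    stop("`chrom` and `length` must have the same length", call. = FALSE)
  }
  if (base::length(chrom) == 0L) {
    stop("a genome model needs at least one chromosome", call. = FALSE)
  }
  if (anyDuplicated(chrom)) {
    stop("duplicated chromosome names: ",
         paste(unique(chrom[duplicated(chrom)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(length)) || any(length <= 0)) {
    stop("chromosome lengths must be finite and strictly positive",
         call. = FALSE)
  }
  out <- tibble::tibble(chrom = chrom, length = length)
  attr(out, "has_sex") <- isTRUE(has_sex)
  class(out) <- c("genome_model", class(out))
  out
}

#' Total genome length of a model
#'
#' @param genome A [genome_model()].
#' @return Total length in bp (numeric scalar).
#' @export
genome_total_length <- function(genome) {
  stopifnot(inherits(genome, "genome_model"))
  sum(genome$length)
}

#' Read a two-column chromosome-sizes table
#'
#' @param path TSV with columns `chrom` and `length` (header required).
#' @inheritParams genome_model
#' @return A [genome_model()].
#' @export
read_genome_sizes <- function(path, has_sex = FALSE) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(),
    length = readr::col_double()
  ))
  genome_model(tab$chrom, tab$length, has_sex = has_sex)
}

#' Default autosomal genome model
#'
#' Autosomes 1-22 with GRCh38 lengths, read from the sizes table shipped
#' with the package so an alternative build can be substituted with
#' [read_genome_sizes()].  `scale` divides every length, which is how the
#' cohort simulator obtains its reduced, fast-to-simulate genome while
#' keeping per-chromosome proportions.
#'
#' @param scale Positive divisor applied to every chromosome length.
#' @return A [genome_model()].
#' @export
default_genome <- function(scale = 1) {
  stopifnot(is.numeric(scale), length(scale) == 1L, scale > 0)
  path <- system.file("extdata", "hg38_autosomes.tsv", package = "hrdgi",
                      mustWork = TRUE)
  gm <- read_genome_sizes(path)
  if (scale != 1) gm <- genome_model(gm$chrom, round(gm$length / scale))
  gm
}

# Map chromosome names to their rank in the genome model; errors on
# names the model does not know.
chrom_rank <- function(chrom, genome, context = "interval") {
  idx <- match(chrom, genome$chrom)
  if (anyNA(idx)) {
    stop("unknown chromosome(s) for this genome model in ", context, ": ",
         paste(unique(chrom[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  idx
}

# Validate 0-based half-open intervals against the genome model.
check_intervals_in_genome <- function(chrom, start, end, genome,
                                      context = "interval") {
  idx <- chrom_rank(chrom, genome, context)
  if (any(start < 0) || any(end > genome$length[idx]) || any(start >= end)) {
    bad <- which(start < 0 | end > genome$length[idx] | start >= end)[1L]
    stop(sprintf(
      "%s %s:%.0f-%.0f is invalid or outside the chromosome bounds [0, %.0f)",
      context, chrom[bad], start[bad], end[bad], genome$length[idx[bad]]
    ), call. = FALSE)
  }
  invisible(idx)
}

# Fast tibble construction for hot paths: skips tibble()'s quosure
# machinery; callers guarantee equal-length columns.
quick_tbl <- function(...) {
  l <- list(...)
  tibble::new_tibble(l, nrow = if (length(l)) length(l[[1]]) else 0L)
}
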