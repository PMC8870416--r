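#' The 35-gene DNA-repair panel
#'
#' Gene symbols covered by the targeted panel the variant table is
#' expected to come from: HRR-pathway genes plus mismatch-repair and
#' other DNA-damage-response genes.
#'
#' @return Character vector of 35 gene symbols.
#' @export
panel_genes <- function() {
  c(
    "BRCA1", "BRCA2", "BARD1", "BRIP1", "CHEK1", "CHEK2", "FAM175A",
    "NBN", "PALB2", "ATM", "MRE11A", "RAD51B", "RAD51C", "RAD51D",
    "RAD54L", "FANCI", "FANCM", "FANCA", "ERCC1", "ERCC2", "ERCC6",
    "RECQL", "XRCC4", "HELQ", "SLX4", "WRN", "ATR", "PTEN", "CCNE1",
    "EMSY", "TP53", "MLH1", "MSH2", "MSH6", "PMS2"
  )
}

#' Default HRR gene set used for HRD status
#'
#' The mutational HRD surrogate counts qualifying variants only in
#' homologous-recombination-repair genes.  The default set is the panel
#' minus the mismatch-repair genes (MLH1, MSH2, MSH6, PMS2), TP53,
#' CCNE1, EMSY and PTEN, which sit on the panel for other purposes.
#' The set is configuration, not code: pass your own vector to
#' [hrd_status()] to change it.
#'
#' @return Character vector of gene symbols.
#' @export
default_hrr_genes <- function() {
  setdiff(panel_genes(),
          c("TP53", "MLH1", "MSH2", "MSH6", "PMS2", "CCNE1", "EMSY",
            "PTEN"))
}

#' Qualify panel variants
#'
#' A variant qualifies as potentially pathogenic when it clears the
#' technical gates - coverage at least `min_coverage` reads and VAF
#' strictly greater than `min_vaf` - and is either classified
#' pathogenic (P) or likely pathogenic (LP), or is a VUS with a
#' pathogenic upstream prediction, or is a VUS called pathogenic by
#' both in-silico predictors (SIFT and PolyPhen together; one alone is
#' not enough).
#'
#' @param variants A `variant_table` ([read_variant_table()]) or any
#'   data frame with the same columns.
#' @param min_coverage Minimum read coverage (default 100, inclusive).
#' @param min_vaf Minimum variant allele fraction (default 0.05,
#'   exclusive: a VAF of exactly 5% does not qualify).
#' @return The input with logical `qualifies` and character `rule`
#'   columns appended (`rule` is `NA` for non-qualifying variants, else
#'   `"P/LP"`, `"VUS_prediction"` or `"VUS_sift_polyphen"`).
#' @export
qualify_variants <- function(variants, min_coverage = 100, min_vaf = 0.05) {
  v <- tibble::as_tibble(variants)
  tech <- v$coverage >= min_coverage & v$vaf > min_vaf
  plp <- v$classification %in% c("P", "LP")
  vus_pred <- v$classification == "VUS" &
    !is.na(v$path_prediction) & v$path_prediction
  vus_insilico <- v$classification == "VUS" &
    !is.na(v$sift) & v$sift == "pathogenic" &
    !is.na(v$polyphen) & v$polyphen == "pathogenic"
  v$qualifies <- tech & (plp | vus_pred | vus_insilico)
  v$rule <- dplyr::case_when(
    !v$qualifies ~ NA_character_,
    plp ~ "P/LP",
    vus_pred ~ "VUS_prediction",
    TRUE ~ "VUS_sift_polyphen"
  )
  v
}

#' Per-sample mutational HRD status
#'
#' A sample is HRD-positive when it carries at least one qualifying
#' variant (see [qualify_variants()]) in a gene from the HRR set.
#' Variants in genes outside the 35-gene panel are ignored with a
#' warning.
#'
#' @param variants A `variant_table` covering one or more samples.
#' @param samples Optional character vector of sample ids to report
#'   (samples with no variant rows are then reported HRD-negative).
#' @param hrr_genes The HRR gene set (default [default_hrr_genes()]).
#' @inheritParams qualify_variants
#' @return A tibble with one row per sample: `sample`, `hrd`,
#'   `n_qualifying`, `genes` (comma-separated qualifying HRR genes).
#' @export
hrd_status <- function(variants, samples = NULL,
                       hrr_genes = default_hrr_genes(),
                       min_coverage = 100, min_vaf = 0.05) {
  v <- qualify_variants(variants, min_coverage, min_vaf)
  off_panel <- !v$gene %in% panel_genes()
  if (any(off_panel)) {
    warning("ignoring variant(s) in gene(s) outside the panel: ",
            paste(unique(v$gene[off_panel]), collapse = ", "),
            call. = FALSE)
    v <- v[!off_panel, ]
  }
  if (is.null(samples)) samples <- sort(unique(v$sample))
  hit <- v[v$qualifies & v$gene %in% hrr_genes, ]
  per <- dplyr::summarise(
    dplyr::group_by(hit, sample),
    n_qualifying = dplyr::n(),
    genes = paste(sort(unique(gene)), collapse = ","),
    .groups = "drop"
  )
  out <- tibble::tibble(sample = as.character(samples))
  out <- dplyr::left_join(out, per, by = "sample")
  out$n_qualifying[is.na(out$n_qualifying)] <- 0L
  out$genes[is.na(out$genes)] <- ""
  out$hrd <- out$n_qualifying > 0
  out[, c("sample", "hrd", "n_qualifying", "genes")]
}

#' Gene-level copy-number calls from a segment profile
#'
#' Assigns each gene interval the length-weighted mean purity-adjusted
#' copy number of the segments overlapping it, then calls `amplified`
#' at or above `amp_threshold`, `deleted` at or below `del_threshold`,
#' otherwise `neutral`.  Genes with no overlapping segment are
#' `neutral` with `no_data = TRUE`.
#'
#' @param profile A [segment_profile()].
#' @param genes Tibble of gene intervals from [read_bed()] (`chrom`,
#'   `start`, `end`, `name` = gene symbol).  Approximate GRCh38
#'   intervals for the classically copy-number-driven panel genes
#'   (CCNE1, PTEN, EMSY) ship in
#'   `system.file("extdata", "gene_panel_grch38.bed", package = "hrdgi")`.
#' @param amp_threshold Adjusted CN for an amplification call
#'   (default 5).
#' @param del_threshold Adjusted CN for a deletion call (default 1).
#' @return A tibble: `gene`, `cn`, `call`, `no_data`.
#' @export
gene_cn_call <- function(profile, genes, amp_threshold = 5,
                         del_threshold = 1) {
  stopifnot(inherits(profile, "segment_profile"))
  if (!"name" %in% names(genes) || anyNA(genes[["name"]])) {
    stop("gene intervals must carry gene symbols in the BED name field",
         call. = FALSE)
  }
  purity <- attr(profile, "purity")
  seg <- tibble::as_tibble(profile)
  seg$cn <- purity_adjust(seg$log2_ratio, purity)
  out <- purrr::pmap_dfr(
    genes[, c("chrom", "start", "end", "name")],
    function(chrom, start, end, name) {
      s <- seg[seg$chrom == chrom & seg$end > start & seg$start < end, ]
      if (nrow(s) == 0) {
        return(tibble::tibble(gene = name, cn = NA_real_,
                              call = "neutral", no_data = TRUE))
      }
      w <- pmin(s$end, end) - pmax(s$start, start)
      cn <- sum(s$cn * w) / sum(w)
      call <- if (cn >= amp_threshold) "amplified"
        else if (cn <= del_threshold) "deleted" else "neutral"
      tibble::tibble(gene = name, cn = cn, call = call, no_data = FALSE)
    }
  )
  out
}
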