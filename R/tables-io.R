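#' Read a SNP table with control-panel genotypes
#'
#' The SNP table carries the backbone SNPs used for BAF-based LOH
#' detection: one row per site with its position, the genotype of each
#' control in the panel of normals, and optionally the tumor BAF for the
#' sample under analysis.  Positions are 1-based in the file and 0-based
#' internally.
#'
#' @param path TSV with columns `chrom`, `pos`, one genotype column per
#'   control (named `ctrl1`, `ctrl2`, ... or anything starting with
#'   `ctrl`), and optionally `tumor_baf`.
#' @param genome A [genome_model()].
#' @param panel_size Expected number of control genotype columns; a
#'   mismatch is an error.
#' @return A tibble of class `snp_sites`, sorted by genome order, with
#'   genotype columns coded as `"hom-ref"`, `"het"`, `"hom-alt"` or `NA`
#'   (missing).
#' @export
read_snp_table <- function(path, genome, panel_size = 5) {
  tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (!all(c("chrom", "pos") %in% names(tab))) {
    stop("SNP table needs `chrom` and `pos` columns", call. = FALSE)
  }
  ctrl_cols <- grep("^ctrl", names(tab), value = TRUE)
  if (length(ctrl_cols) != panel_size) {
    stop(sprintf(
      "expected %d control genotype columns (panel_size), found %d",
      panel_size, length(ctrl_cols)
    ), call. = FALSE)
  }
  out <- tibble::tibble(
    chrom = as.character(tab$chrom),
    pos = as.numeric(tab$pos) - 1
  )
  for (cc in ctrl_cols) out[[cc]] <- decode_genotype(tab[[cc]])
  out$tumor_baf <- if ("tumor_baf" %in% names(tab)) {
    as.numeric(tab$tumor_baf)
  } else {
    NA_real_
  }
  if (any(!is.na(out$tumor_baf) &
          (out$tumor_baf < 0 | out$tumor_baf > 1))) {
    stop("tumor_baf outside [0, 1]", call. = FALSE)
  }
  idx <- chrom_rank(out$chrom, genome, "SNP site")
  if (any(out$pos < 0 | out$pos >= genome$length[idx])) {
    bad <- which(out$pos < 0 | out$pos >= genome$length[idx])[1L]
    stop(sprintf("SNP site %s:%.0f outside chromosome bounds",
                 out$chrom[bad], out$pos[bad]), call. = FALSE)
  }
  out <- out[order(idx, out$pos), ]
  attr(out, "panel_size") <- as.integer(panel_size)
  attr(out, "genome") <- genome
  class(out) <- c("snp_sites", class(out))
  out
}

decode_genotype <- function(x) {
  x <- tolower(trimws(as.character(x)))
  map <- c(
    "hom-ref" = "hom-ref", "0/0" = "hom-ref", "aa" = "hom-ref",
    "het" = "het", "0/1" = "het", "ab" = "het",
    "hom-alt" = "hom-alt", "1/1" = "hom-alt", "bb" = "hom-alt"
  )
  out <- unname(map[x])
  unknown <- !is.na(x) & x != "" & x != "missing" & x != "./." & is.na(out)
  if (any(unknown)) {
    stop("unrecognised genotype code(s): ",
         paste(utils::head(unique(x[unknown]), 3), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Write a SNP table
#'
#' @param sites A `snp_sites` tibble from [read_snp_table()] or the
#'   cohort simulator.
#' @param path Output TSV path (positions written 1-based).
#' @export
write_snp_table <- function(sites, path) {
  out <- tibble::as_tibble(sites)
  out$pos <- format_bp(out$pos + 1)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

response_levels <- c("CR", "PR", "SD", "PD", "NE")
tumor_type_levels <- c("ovarian", "endometrial", "breast")

#' Read a clinical table
#'
#' One row per patient with tumor type, prior treatment lines, best
#' RECIST response (`CR`, `PR`, `SD`, `PD`, or `NE` for not evaluable),
#' and right-censored progression-free and overall survival in months.
#' All validation failures are collected and reported together with
#' their row numbers.
#'
#' @param path CSV with columns `patient_id`, `tumor_type`, `histology`,
#'   `prior_lines`, `best_response`, `pfs_months`, `pfs_event`,
#'   `os_months`, `os_event`.
#' @return A tibble of class `clinical_table`.
#' @export
read_clinical_table <- function(path) {
  tab <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  if (nrow(tab) == 0) {
    warning("clinical table is empty", call. = FALSE)
    tab <- tibble::tibble(
      patient_id = character(), tumor_type = character(),
      histology = character(), prior_lines = integer(),
      best_response = character(), pfs_months = numeric(),
      pfs_event = logical(), os_months = numeric(), os_event = logical()
    )
    class(tab) <- c("clinical_table", class(tab))
    return(tab)
  }
  req <- c("patient_id", "tumor_type", "prior_lines", "best_response",
           "pfs_months", "pfs_event", "os_months", "os_event")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols) > 0) {
    stop("clinical table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"histology" %in% names(tab)) tab$histology <- NA_character_
  out <- tibble::tibble(
    patient_id = as.character(tab$patient_id),
    tumor_type = as.character(tab$tumor_type),
    histology = as.character(tab$histology),
    prior_lines = as.integer(tab$prior_lines),
    best_response = toupper(as.character(tab$best_response)),
    pfs_months = as.numeric(tab$pfs_months),
    pfs_event = as.logical(tab$pfs_event),
    os_months = as.numeric(tab$os_months),
    os_event = as.logical(tab$os_event)
  )
  problems <- character()
  note <- function(rows, what) {
    if (length(rows) > 0) {
      problems <<- c(problems, sprintf(
        "%s (row %s)", what, paste(rows, collapse = ", ")))
    }
  }
  note(which(!out$best_response %in% response_levels),
       "unknown best_response code")
  note(which(!out$tumor_type %in% tumor_type_levels), "unknown tumor_type")
  note(which(is.na(out$pfs_months) | out$pfs_months < 0 |
               !is.finite(out$pfs_months)), "pfs_months negative or missing")
  note(which(is.na(out$os_months) | out$os_months < 0 |
               !is.finite(out$os_months)), "os_months negative or missing")
  note(which(is.na(out$pfs_event)), "pfs_event not interpretable as logical")
  note(which(is.na(out$os_event)), "os_event not interpretable as logical")
  note(which(is.na(out$prior_lines) | out$prior_lines < 0),
       "prior_lines negative or missing")
  if (length(problems) > 0) {
    stop("invalid clinical record(s):\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  class(out) <- c("clinical_table", class(out))
  out
}

#' Write a clinical table
#' @param clinical A `clinical_table`.
#' @param path Output CSV path.
#' @export
write_clinical_table <- function(clinical, path) {
  readr::write_csv(tibble::as_tibble(clinical), path, progress = FALSE)
  invisible(path)
}

variant_classes <- c("P", "LP", "VUS", "benign", "other")

#' Read a curated panel variant table
#'
#' The variant input is a post-annotation TSV (not a VCF): one row per
#' called variant with its gene symbol, read coverage, variant allele
#' fraction, clinical classification and in-silico predictor calls.
#'
#' @param path TSV with columns `sample`, `gene`, `coverage`, `vaf`,
#'   `classification` (`P`, `LP`, `VUS`, `benign`, `other`), `sift`
#'   (`pathogenic`/`tolerated`/blank), `polyphen`
#'   (`pathogenic`/`benign`/blank), and optionally `path_prediction`
#'   (logical: an upstream aggregate pathogenicity prediction for VUS).
#' @return A tibble of class `variant_table`.
#' @export
read_variant_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  req <- c("sample", "gene", "coverage", "vaf", "classification")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols) > 0) {
    stop("variant table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    sample = as.character(tab$sample),
    gene = as.character(tab$gene),
    coverage = as.numeric(tab$coverage),
    vaf = as.numeric(tab$vaf),
    classification = as.character(tab$classification),
    sift = decode_predictor(tab[["sift"]], c("pathogenic", "tolerated")),
    polyphen = decode_predictor(tab[["polyphen"]], c("pathogenic", "benign")),
    path_prediction = if ("path_prediction" %in% names(tab)) {
      as.logical(tab$path_prediction)
    } else {
      NA
    }
  )
  if (any(!out$classification %in% variant_classes)) {
    stop("unknown classification code(s): ",
         paste(unique(setdiff(out$classification, variant_classes)),
               collapse = ", "), call. = FALSE)
  }
  if (any(is.na(out$vaf) | out$vaf < 0 | out$vaf > 1)) {
    stop("vaf must be in [0, 1]", call. = FALSE)
  }
  if (any(is.na(out$coverage) | out$coverage < 0)) {
    stop("coverage must be non-negative", call. = FALSE)
  }
  class(out) <- c("variant_table", class(out))
  out
}

decode_predictor <- function(x, allowed) {
  if (is.null(x)) return(NA_character_)
  x <- tolower(trimws(as.character(x)))
  x[x == "" | x == "missing"] <- NA_character_
  bad <- !is.na(x) & !x %in% allowed
  if (any(bad)) {
    stop("unknown predictor call(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  x
}

#' Write a variant table
#' @param variants A `variant_table`.
#' @param path Output TSV path.
#' @export
write_variant_table <- function(variants, path) {
  readr::write_tsv(tibble::as_tibble(variants), path, progress = FALSE)
  invisible(path)
}

#' Read a BED interval file
#'
#' BED is 0-based half-open on disk, matching the internal convention,
#' so no coordinate shift is applied.
#'
#' @param path BED3+ file (chrom, start, end, optional name), no header.
#' @param genome A [genome_model()] for bounds checking.
#' @return Tibble with `chrom`, `start`, `end`, `name`.
#' @export
read_bed <- function(path, genome) {
  tab <- readr::read_tsv(path, col_names = FALSE,
                         col_types = readr::cols(), progress = FALSE)
  if (ncol(tab) < 3) stop("BED file needs at least 3 columns", call. = FALSE)
  out <- tibble::tibble(
    chrom = as.character(tab[[1]]),
    start = as.numeric(tab[[2]]),
    end = as.numeric(tab[[3]]),
    name = if (ncol(tab) >= 4) as.character(tab[[4]]) else NA_character_
  )
  check_intervals_in_genome(out$chrom, out$start, out$end, genome,
                            context = "BED interval")
  out
}

#' Write intervals as BED
#'
#' @param x Data frame with `chrom`, `start`, `end` and optionally
#'   `name` and `score` columns (0-based half-open).
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  cols <- list(x$chrom, format_bp(x$start), format_bp(x$end))
  if ("name" %in% names(x)) {
    cols <- c(cols, list(x[["name"]]))
    if ("score" %in% names(x)) cols <- c(cols, list(x[["score"]]))
  }
  out <- tibble::as_tibble(stats::setNames(cols, paste0("V", seq_along(cols))))
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
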