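#' Run the GI feature pipeline for one sample
#'
#' Chains the per-sample steps: significance/purity-aware event calling
#' with the 1 Mb artifact filter, the BAF-borderline filter, LOH
#' calling over the heterozygosity mask, and the GI parameter vector.
#'
#' @param profile A [segment_profile()].
#' @param sites The sample's `snp_sites` (control genotypes + tumor
#'   BAF).
#' @param mask A [build_het_mask()] result (built once per cohort from
#'   the shared control panel).
#' @param gain_threshold,loss_threshold,significance,min_length
#'   Event-calling thresholds, see [call_events()].
#' @param baf_band Balanced-BAF band shared by the borderline filter
#'   and LOH calling.
#' @param min_snps Minimum informative SNPs per LOH interval.
#' @return A list: `events`, `events_baf`, `loh`, `gi` (one-row
#'   tibble).
#' @export
gi_sample <- function(profile, sites, mask,
                      gain_threshold = 2.5, loss_threshold = 1.5,
                      significance = 0.001, min_length = 1e6,
                      baf_band = c(0.3, 0.7), min_snps = 10) {
  events <- call_events(profile, gain_threshold = gain_threshold,
                        loss_threshold = loss_threshold,
                        significance = significance,
                        min_length = min_length)
  events_baf <- baf_borderline_filter(events, band = baf_band)
  loh <- call_loh(profile, sites, mask, baf_band = baf_band,
                  min_snps = min_snps, min_length = min_length)
  gi <- compute_gi_vector(events, events_baf, loh,
                          attr(profile, "genome"))
  list(events = events, events_baf = events_baf, loh = loh, gi = gi)
}

#' Cohort GI table
#'
#' Runs [gi_sample()] over a cohort.  The heterozygosity mask is built
#' from the first sample's control genotypes (the panel of normals is
#' shared across samples) unless supplied.
#'
#' @param profiles Named list of [segment_profile()]s.
#' @param sites Named list of `snp_sites`, aligned with `profiles`.
#' @param mask Optional pre-built [build_het_mask()].
#' @param min_het_controls Passed to [build_het_mask()] when `mask` is
#'   NULL.
#' @param ... Passed to [gi_sample()].
#' @return A tibble with one GI-vector row per sample.
#' @export
gi_cohort <- function(profiles, sites, mask = NULL,
                      min_het_controls = 3, ...) {
  stopifnot(length(profiles) == length(sites))
  if (is.null(mask)) {
    mask <- build_het_mask(sites[[1]], min_het_controls = min_het_controls)
  }
  dplyr::bind_rows(lapply(seq_along(profiles), function(i) {
    gi_sample(profiles[[i]], sites[[i]], mask, ...)$gi
  }))
}

#' Default pipeline run configuration
#'
#' The single auditable home of every threshold the pipeline applies:
#' per-segment significance 0.001; minimum event/LOH length 1 Mb; the
#' 0.3-0.7 balanced-BAF band; gain/loss calling at adjusted copy number
#' 2.5/1.5; variant gates at 100x coverage and 5% VAF; long-LOH spans
#' at 10 and 15 Mb.  Values loaded from a YAML file override these
#' defaults; unknown keys are rejected.
#'
#' @return A nested list of class `run_config`.
#' @export
default_run_config <- function() {
  cfg <- list(
    paths = list(
      segments_dir = NULL, snp_dir = NULL, variants = NULL,
      clinical = NULL, genome_sizes = NULL, gene_bed = NULL,
      purity_table = NULL, gi_table = NULL, hrd_table = NULL
    ),
    thresholds = list(
      significance = 0.001, min_length = 1e6,
      baf_band_low = 0.3, baf_band_high = 0.7,
      gain_cn = 2.5, loss_cn = 1.5,
      min_coverage = 100, min_vaf = 0.05,
      loh_span_short = 10e6, loh_span_long = 15e6,
      min_snps = 10, min_het_controls = 3,
      panel_size = 5
    ),
    hrr_genes = default_hrr_genes(),
    grouping = list(median_pfs = NULL, cbr_months = 6),
    simulate = list(n_patients = 60),
    seed = 1
  )
  class(cfg) <- "run_config"
  cfg
}

#' Read and validate a YAML run configuration
#'
#' @param path YAML file with any subset of the keys of
#'   [default_run_config()]; unknown keys at any level are an error and
#'   named in the message.
#' @return A `run_config` with file values overriding the defaults.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- unclass(default_run_config())
  merged <- merge_config(cfg, user, prefix = character())
  validate_run_config(merged)
  class(merged) <- "run_config"
  merged
}

merge_config <- function(base, user, prefix) {
  if (!is.list(user)) return(user)
  unknown <- setdiff(names(user), names(base))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ",
         paste(paste(c(prefix, ""), collapse = "."), unknown,
               sep = "", collapse = ", "),
         call. = FALSE)
  }
  for (k in names(user)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(user[[k]]) &&
                     !is.null(names(base[[k]]))) {
      merge_config(base[[k]], user[[k]], c(prefix, k))
    } else {
      user[[k]]
    }
  }
  base
}

validate_run_config <- function(cfg) {
  th <- cfg$thresholds
  check <- function(ok, what) {
    if (!ok) stop("invalid config value: ", what, call. = FALSE)
  }
  check(th$significance > 0 && th$significance <= 1,
        "thresholds.significance must be in (0, 1]")
  check(th$min_length >= 0, "thresholds.min_length must be >= 0")
  check(th$baf_band_low < th$baf_band_high &&
          th$baf_band_low >= 0 && th$baf_band_high <= 1,
        "thresholds.baf_band must satisfy 0 <= low < high <= 1")
  check(th$loss_cn < th$gain_cn,
        "thresholds.loss_cn must be below thresholds.gain_cn")
  check(th$min_coverage >= 0, "thresholds.min_coverage must be >= 0")
  check(th$min_vaf >= 0 && th$min_vaf < 1,
        "thresholds.min_vaf must be in [0, 1)")
  check(th$loh_span_short <= th$loh_span_long,
        "thresholds.loh_span_short must not exceed loh_span_long")
  check(th$min_snps >= 1, "thresholds.min_snps must be >= 1")
  check(th$min_het_controls >= 1 &&
          th$min_het_controls <= th$panel_size,
        "thresholds.min_het_controls must be between 1 and panel_size")
  invisible(cfg)
}

#' Run a pipeline subcommand
#'
#' Thin orchestration over the package functions: each subcommand
#' reads its inputs per the config, writes its outputs under
#' `out_dir`, and drops a `manifest_<subcommand>.json` recording the
#' resolved configuration, the seed, the package version and an MD5
#' hash over the produced files, so that two runs on identical inputs
#' and config can be verified identical by their output hashes.
#'
#' Subcommands: `"simulate"` (write a synthetic cohort),
#' `"gi-features"` (segments + SNPs to cohort GI table), `"hrd"`
#' (variant table to HRD status report), `"associate"` (GI + clinical
#' + HRD to association report), `"report"` (cohort summary: response
#' rates with exact CIs, KM medians, top associations).
#'
#' @param subcommand One of simulate, gi-features, hrd, associate,
#'   report.
#' @param config A `run_config` ([default_run_config()],
#'   [read_run_config()]).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a named list of the files written.
#' @export
run_pipeline <- function(subcommand = c("simulate", "gi-features", "hrd",
                                        "associate", "report"),
                         config = default_run_config(), out_dir) {
  subcommand <- match.arg(subcommand)
  validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  th <- config$thresholds
  files <- switch(
    subcommand,
    "simulate" = {
      cfg <- simulation_config(n_patients = config$simulate$n_patients)
      simulate_cohort(cfg, seed = config$seed, dir = out_dir)
      list(cohort = out_dir)
    },
    "gi-features" = {
      genome <- require_path(config, "genome_sizes", read_genome_sizes)
      seg_files <- list.files(config$paths$segments_dir,
                              pattern = "\\.seg$", full.names = TRUE)
      if (length(seg_files) == 0) {
        stop("no .seg files in ", config$paths$segments_dir,
             call. = FALSE)
      }
      purity <- read_purity_table(config)
      ids <- sub("\\.seg$", "", basename(seg_files))
      profiles <- lapply(seq_along(seg_files), function(i) {
        read_segments(seg_files[i], genome,
                      purity = purity[ids[i]] %|NA|% 1,
                      sample_id = ids[i])
      })
      sites <- lapply(ids, function(id) {
        read_snp_table(file.path(config$paths$snp_dir,
                                 paste0(id, ".tsv")),
                       genome, panel_size = th$panel_size)
      })
      gi <- gi_cohort(
        profiles, sites, min_het_controls = th$min_het_controls,
        gain_threshold = th$gain_cn, loss_threshold = th$loss_cn,
        significance = th$significance, min_length = th$min_length,
        baf_band = c(th$baf_band_low, th$baf_band_high),
        min_snps = th$min_snps
      )
      gi_path <- file.path(out_dir, "gi_features.tsv")
      write_gi_table(gi, gi_path)
      dict_path <- file.path(out_dir, "gi_dictionary.tsv")
      readr::write_tsv(gi_parameter_dictionary(), dict_path,
                       progress = FALSE)
      list(gi = gi_path, dictionary = dict_path)
    },
    "hrd" = {
      variants <- read_variant_table(require_file(config, "variants"))
      hrd <- hrd_status(variants, hrr_genes = config$hrr_genes,
                        min_coverage = th$min_coverage,
                        min_vaf = th$min_vaf)
      hrd_path <- file.path(out_dir, "hrd_status.tsv")
      readr::write_tsv(hrd, hrd_path, progress = FALSE)
      genes_path <- file.path(out_dir, "hrr_gene_set.txt")
      writeLines(config$hrr_genes, genes_path)
      list(hrd = hrd_path, hrr_genes = genes_path)
    },
    "associate" = {
      gi <- readr::read_tsv(require_file(config, "gi_table"),
                            col_types = readr::cols(), progress = FALSE)
      clinical <- read_clinical_table(require_file(config, "clinical"))
      extra <- NULL
      if (!is.null(config$paths$hrd_table) &&
          file.exists(config$paths$hrd_table)) {
        hrd <- readr::read_tsv(config$paths$hrd_table,
                               col_types = readr::cols(),
                               progress = FALSE)
        extra <- tibble::tibble(patient_id = hrd$sample, hrd = hrd$hrd)
      }
      scan <- association_scan(gi, clinical, extra_groups = extra,
                               median_pfs = config$grouping$median_pfs)
      scan_path <- file.path(out_dir, "associations.tsv")
      write_association_report(scan, scan_path)
      list(associations = scan_path)
    },
    "report" = {
      clinical <- read_clinical_table(require_file(config, "clinical"))
      report <- cohort_report(clinical,
                              median_pfs = config$grouping$median_pfs,
                              cbr_months = config$grouping$cbr_months)
      rep_path <- file.path(out_dir, "cohort_report.tsv")
      readr::write_tsv(report, rep_path, progress = FALSE)
      print_cohort_report(report)
      list(report = rep_path)
    }
  )
  manifest <- list(
    subcommand = subcommand,
    package_version = as.character(utils::packageVersion("hrdgi")),
    seed = config$seed,
    config = unclass(config),
    outputs = output_hashes(out_dir, subcommand),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  man_path <- file.path(out_dir,
                        paste0("manifest_", subcommand, ".json"))
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(c(files, manifest = man_path))
}

`%|NA|%` <- function(a, b) if (length(a) != 1 || is.na(a)) b else a

require_file <- function(config, key) {
  p <- config$paths[[key]]
  if (is.null(p) || !file.exists(p)) {
    stop("required input missing: paths.", key,
         if (!is.null(p)) paste0(" (", p, " not found)"), call. = FALSE)
  }
  p
}

require_path <- function(config, key, reader) {
  reader(require_file(config, key))
}

read_purity_table <- function(config) {
  p <- config$paths$purity_table
  if (is.null(p)) return(stats::setNames(numeric(0), character(0)))
  tab <- readr::read_tsv(p, col_types = readr::cols(), progress = FALSE)
  stats::setNames(as.numeric(tab$purity), as.character(tab$sample))
}

output_hashes <- function(out_dir, subcommand) {
  fs <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  fs <- fs[!grepl("^manifest_", basename(fs))]
  h <- tools::md5sum(fs)
  as.list(stats::setNames(unname(h), basename(fs)))
}

#' Summarise a cohort's response and survival
#'
#' Intention-to-treat rates (NE patients stay in the denominator) with
#' exact Clopper-Pearson intervals for ORR, DCR, CBR and LTR, plus the
#' Kaplan-Meier medians for PFS and OS.
#'
#' @param clinical A `clinical_table`.
#' @param median_pfs Optional pinned median PFS for the LTR threshold.
#' @param cbr_months CBR duration boundary (default 6).
#' @return A tibble with one row per summary quantity.
#' @export
cohort_report <- function(clinical, median_pfs = NULL, cbr_months = 6) {
  cl <- tibble::as_tibble(clinical)
  n <- nrow(cl)
  orr <- group_patients(cl, "ORR")
  cbr <- group_patients(cl, "CBR", cbr_months = cbr_months)
  ltr <- group_patients(cl, "LTR", median_pfs = median_pfs)
  dcr_pos <- sum(cl$best_response %in% c("CR", "PR", "SD"))
  rate_row <- function(name, n_pos) {
    r <- response_rate(n_pos, n)
    tibble::tibble(quantity = name, value = r$rate,
                   conf_low = r$conf_low, conf_high = r$conf_high,
                   n = n)
  }
  km_pfs <- glance(km_fit(cl$pfs_months, cl$pfs_event))
  km_os <- glance(km_fit(cl$os_months, cl$os_event))
  dplyr::bind_rows(
    rate_row("orr_pct", sum(orr$label, na.rm = TRUE)),
    rate_row("dcr_pct", dcr_pos),
    rate_row("cbr_pct", sum(cbr$label, na.rm = TRUE)),
    rate_row("ltr_pct", sum(ltr$label, na.rm = TRUE)),
    rate_row("ne_pct", sum(cl$best_response == "NE")),
    tibble::tibble(quantity = "median_pfs_months", value = km_pfs$median,
                   conf_low = km_pfs$median_conf_low,
                   conf_high = km_pfs$median_conf_high, n = n),
    tibble::tibble(quantity = "median_os_months", value = km_os$median,
                   conf_low = km_os$median_conf_low,
                   conf_high = km_os$median_conf_high, n = n)
  )
}

print_cohort_report <- function(report) {
  cat("cohort summary\n")
  for (i in seq_len(nrow(report))) {
    cat(sprintf("  %-18s %6.1f  (95%% CI %.1f, %.1f)\n",
                report$quantity[i], report$value[i],
                report$conf_low[i], report$conf_high[i]))
  }
  invisible(report)
}
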