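#' Configuration for the synthetic-cohort generator
#'
#' Defines the generative model the validation cohorts are drawn from.
#' Each patient has a latent instability level `theta ~ Uniform(0, 1)`
#' driving a Poisson number of copy-number/LOH events with rate
#' `lambda0 + lambda1 * theta`, log-normal event lengths, and a purity
#' drawn uniformly from `purity_range` that dilutes both the log2 and
#' BAF signals through the standard two-component tumor/normal mixture.
#' Clinical response is Bernoulli with logit
#' `response_beta[1] + response_beta[2] * z` where `z` is the
#' standardized engineered event count, and PFS is exponential with log
#' hazard `pfs_gamma[1] - pfs_gamma[2] * z`, censored uniformly on
#' `(0, censor_max)` months.  The probability of carrying a qualifying
#' HRR-gene variant is logistic in `theta`.
#'
#' The default genome is the autosomal model at 1/10 scale with one SNP
#' per 20 kb, preserving the full-genome SNP density (about 147,000
#' SNPs over 2.9 Gb) while keeping a cohort simulation fast.
#'
#' @param n_patients Cohort size.
#' @param genome A [genome_model()] to simulate on.
#' @param snp_spacing Distance between backbone SNPs in bp.
#' @param panel_size Number of control normals.
#' @param het_prob Per-site heterozygosity probability (controls and
#'   tumor germline alike).
#' @param geno_missing_prob Per-genotype missingness probability.
#' @param lambda0,lambda1 Event-count rate intercept and slope in
#'   `theta`.
#' @param event_length_meanlog,event_length_sdlog Log-normal event
#'   length parameters (defaults: median 8 Mb, sdlog 0.8).
#' @param type_probs Probabilities of gain / loss / copy-neutral LOH
#'   event types (must sum to 1).
#' @param purity_range Uniform purity bounds.
#' @param baf_sd,log2_sd Gaussian noise SDs on per-SNP BAF and
#'   per-segment log2 ratio.
#' @param response_beta Logistic response link `(intercept, slope)` on
#'   the standardized event count.
#' @param pfs_gamma,os_gamma Exponential log-hazard `(intercept,
#'   slope)` for PFS and OS in months.
#' @param censor_max Upper bound of the uniform PFS censoring time.
#' @param ne_prob Probability a patient is not evaluable (NE).
#' @param hrr_beta Logistic link `(intercept, slope)` in `theta` for
#'   carrying a qualifying HRR variant.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 60,
                              genome = default_genome(scale = 10),
                              snp_spacing = 20000,
                              panel_size = 5,
                              het_prob = 0.4,
                              geno_missing_prob = 0.002,
                              lambda0 = 2, lambda1 = 18,
                              event_length_meanlog = log(8e6),
                              event_length_sdlog = 0.8,
                              type_probs = c(gain = 0.4, loss = 0.4,
                                             cnloh = 0.2),
                              purity_range = c(0.3, 0.9),
                              baf_sd = 0.03, log2_sd = 0.1,
                              response_beta = c(-2.2, 1.0),
                              pfs_gamma = c(log(1 / 4.5), 0.5),
                              os_gamma = c(log(1 / 15), 0.3),
                              censor_max = 24,
                              ne_prob = 0.07,
                              hrr_beta = c(-2.2, 1.5)) {
  stopifnot(inherits(genome, "genome_model"))
  if (abs(sum(type_probs) - 1) > 1e-8 || any(type_probs < 0)) {
    stop("type_probs must be non-negative and sum to 1", call. = FALSE)
  }
  if (lambda0 < 0 || lambda1 < 0 || lambda0 + lambda1 <= 0) {
    stop("event rate must be positive", call. = FALSE)
  }
  stopifnot(
    n_patients >= 1, snp_spacing > 0, panel_size >= 1,
    het_prob > 0, het_prob < 1, geno_missing_prob >= 0,
    geno_missing_prob < 1,
    length(purity_range) == 2, purity_range[1] > 0,
    purity_range[2] <= 1, purity_range[1] <= purity_range[2],
    baf_sd >= 0, log2_sd >= 0, censor_max > 0,
    ne_prob >= 0, ne_prob < 1,
    length(response_beta) == 2, length(pfs_gamma) == 2,
    length(os_gamma) == 2, length(hrr_beta) == 2
  )
  cfg <- as.list(environment())
  # the SNP backbone is deterministic given genome and spacing; built
  # once here so per-sample simulation does not reconstruct it
  cfg$backbone <- snp_backbone(genome, snp_spacing)
  class(cfg) <- "simulation_config"
  cfg
}

# Allele pairs (major, minor) by event type; gains are 3 copies (2,1)
# or, less often, 4 copies (3,1).
draw_event_states <- function(k, type_probs) {
  type <- sample(names(type_probs), k, replace = TRUE, prob = type_probs)
  four <- type == "gain" & stats::runif(k) < 0.3
  quick_tbl(
    type = type,
    a = dplyr::case_when(type == "loss" ~ 1, type == "cnloh" ~ 2,
                         four ~ 3, TRUE ~ 2),
    b = dplyr::case_when(type == "loss" ~ 0, type == "cnloh" ~ 0,
                         TRUE ~ 1)
  )
}

# Place k events of the given lengths without overlap, longest first.
# Each event goes into a free gap chosen with probability proportional
# to the number of admissible start positions; an event no gap can hold
# is redrawn from the length distribution a limited number of times.
place_events <- function(lengths, cfg) {
  f_chrom <- cfg$genome$chrom
  f_start <- rep(0, length(f_chrom))
  f_end <- cfg$genome$length
  lengths <- sort(lengths, decreasing = TRUE)
  k <- length(lengths)
  e_chrom <- character(k)
  e_start <- numeric(k)
  e_end <- numeric(k)
  for (i in seq_len(k)) {
    len <- round(lengths[i])
    redraws <- 0L
    repeat {
      slack <- f_end - f_start - len
      if (any(slack >= 0)) break
      redraws <- redraws + 1L
      if (redraws > 1000L) {
        stop("genome too small for the requested events; reduce the ",
             "event rate or lengths, or enlarge the genome",
             call. = FALSE)
      }
      len <- round(stats::rlnorm(1, cfg$event_length_meanlog,
                                 cfg$event_length_sdlog))
    }
    w <- pmax(0, slack + 1)
    g <- sample.int(length(f_chrom), 1, prob = w)
    s <- f_start[g] + floor(stats::runif(1) * (slack[g] + 1))
    e_chrom[i] <- f_chrom[g]
    e_start[i] <- s
    e_end[i] <- s + len
    f_chrom <- c(f_chrom, f_chrom[g])
    f_start <- c(f_start, s + len)
    f_end <- c(f_end, f_end[g])
    f_end[g] <- s
    keep <- f_end > f_start
    f_chrom <- f_chrom[keep]
    f_start <- f_start[keep]
    f_end <- f_end[keep]
  }
  quick_tbl(chrom = e_chrom, start = e_start, end = e_end)
}

#' Simulate one tumor profile with ground truth
#'
#' Draws an engineered event set for a patient with instability level
#' `theta`, then renders it at the given purity: per-segment log2
#' ratios follow `log2((p * n + 2 (1 - p)) / 2)` plus Gaussian noise,
#' and the tumor BAF of a germline-heterozygous SNP inside an event
#' with allele copies `(a, b)` has mean
#' `(p * b + (1 - p)) / (p * (a + b) + 2 (1 - p))` (the B allele
#' assigned to the major or minor copy with equal probability) plus
#' noise, clamped to `[0, 1]`.  Tumor BAF is reported only at sites
#' heterozygous in the tumor germline; neutral genome between events is
#' emitted as copy-neutral segments.  Uses the current RNG state; seed
#' upstream for reproducibility.
#'
#' @param cfg A [simulation_config()].
#' @param theta Instability level in `[0, 1]`.
#' @param purity Tumor purity in (0, 1].
#' @param sample_id Sample identifier.
#' @return A list: `profile` (a [segment_profile()]), `sites` (a
#'   `snp_sites` tibble with control genotypes and tumor BAF), and
#'   `truth` (engineered events with their true states).
#' @export
simulate_profile <- function(cfg, theta, purity, sample_id = "S1") {
  stopifnot(inherits(cfg, "simulation_config"),
            theta >= 0, theta <= 1)
  check_purity(purity)
  genome <- cfg$genome
  k <- stats::rpois(1, cfg$lambda0 + cfg$lambda1 * theta)
  if (k > 0) {
    ev <- place_events(
      stats::rlnorm(k, cfg$event_length_meanlog, cfg$event_length_sdlog),
      cfg
    )
    ev <- dplyr::bind_cols(ev, draw_event_states(nrow(ev), cfg$type_probs))
    ev$cn <- ev$a + ev$b
    ev <- ev[order(chrom_rank(ev$chrom, genome), ev$start), ]
  } else {
    ev <- tibble::tibble(chrom = character(), start = numeric(),
                         end = numeric(), type = character(),
                         a = numeric(), b = numeric(), cn = numeric())
  }

  # SNP backbone with control genotypes and tumor germline
  snp <- cfg$backbone
  n_snp <- length(snp$pos)
  geno <- matrix(
    sample(c("het", "hom-ref", "hom-alt"), n_snp * cfg$panel_size,
           replace = TRUE,
           prob = c(cfg$het_prob, (1 - cfg$het_prob) / 2,
                    (1 - cfg$het_prob) / 2)),
    nrow = n_snp
  )
  if (cfg$geno_missing_prob > 0) {
    geno[stats::runif(length(geno)) < cfg$geno_missing_prob] <- NA
  }
  tumor_het <- stats::runif(n_snp) < cfg$het_prob

  # per-SNP allele copies from the overlapping event (neutral: 1 + 1)
  a <- rep(1, n_snp)
  b <- rep(1, n_snp)
  if (nrow(ev) > 0) {
    ev_ci <- chrom_rank(ev$chrom, genome)
    for (i in seq_len(nrow(ev))) {
      in_ev <- snp$chrom_idx == ev_ci[i] & snp$pos >= ev$start[i] &
        snp$pos < ev$end[i]
      a[in_ev] <- ev$a[i]
      b[in_ev] <- ev$b[i]
    }
  }
  swap <- stats::runif(n_snp) < 0.5
  bb <- ifelse(swap, a, b)
  tot <- a + b
  baf_mean <- (purity * bb + (1 - purity)) /
    (purity * tot + 2 * (1 - purity))
  tumor_baf <- ifelse(
    tumor_het,
    pmin(1, pmax(0, baf_mean + stats::rnorm(n_snp, 0, cfg$baf_sd))),
    NA_real_
  )

  sites <- new_snp_sites(snp$chrom, snp$pos, geno, tumor_baf, genome,
                         cfg$panel_size)

  # segment table: events plus neutral genome between them
  seg <- build_segment_table(ev, genome)
  seg$log2_ratio <- log2((purity * seg$cn + 2 * (1 - purity)) / 2) +
    stats::rnorm(nrow(seg), 0, cfg$log2_sd)
  seg$p_value <- ifelse(seg$is_event,
                        stats::runif(nrow(seg), 0, 5e-4),
                        stats::runif(nrow(seg), 0.2, 1))
  snp_sum <- segment_snp_summary(seg, sites)
  seg$mean_baf <- snp_sum$mean_baf
  seg$n_snps <- snp_sum$n_snps
  profile <- segment_profile(
    seg[, c("chrom", "start", "end", "log2_ratio", "n_snps", "p_value",
            "mean_baf")],
    sample_id = sample_id, genome = genome, purity = purity
  )
  list(
    profile = profile, sites = sites,
    truth = list(theta = theta, purity = purity, n_events = k,
                 events = ev)
  )
}

snp_backbone <- function(genome, spacing) {
  half <- floor(spacing / 2)
  n_per <- pmax(0, floor((genome$length - 1 - half) / spacing) + 1)
  pos <- half + (sequence(n_per) - 1) * spacing
  list(chrom = rep(genome$chrom, n_per), pos = pos,
       chrom_idx = rep(seq_along(genome$chrom), n_per))
}

new_snp_sites <- function(chrom, pos, geno, tumor_baf, genome,
                          panel_size) {
  out <- quick_tbl(chrom = chrom, pos = pos)
  for (j in seq_len(panel_size)) out[[paste0("ctrl", j)]] <- geno[, j]
  out$tumor_baf <- tumor_baf
  attr(out, "panel_size") <- as.integer(panel_size)
  attr(out, "genome") <- genome
  class(out) <- c("snp_sites", class(out))
  out
}

build_segment_table <- function(ev, genome) {
  chrom <- character(0)
  start <- numeric(0)
  end <- numeric(0)
  cn <- numeric(0)
  is_event <- logical(0)
  for (ci in seq_len(nrow(genome))) {
    cc <- genome$chrom[ci]
    len <- genome$length[ci]
    sel <- ev$chrom == cc
    e_start <- ev$start[sel]
    e_end <- ev$end[sel]
    bounds <- c(0, rbind(e_start, e_end), len)
    gs <- bounds[seq(1, length(bounds) - 1, by = 2)]
    ge <- bounds[seq(2, length(bounds), by = 2)]
    keep <- ge > gs
    c_start <- c(gs[keep], e_start)
    c_end <- c(ge[keep], e_end)
    c_cn <- c(rep(2, sum(keep)), ev$cn[sel])
    c_evt <- c(rep(FALSE, sum(keep)), rep(TRUE, length(e_start)))
    o <- order(c_start)
    chrom <- c(chrom, rep(cc, length(c_start)))
    start <- c(start, c_start[o])
    end <- c(end, c_end[o])
    cn <- c(cn, c_cn[o])
    is_event <- c(is_event, c_evt[o])
  }
  quick_tbl(chrom = chrom, start = start, end = end, cn = cn,
                 is_event = is_event)
}

# Assign SNPs to segments (sorted, non-overlapping per chromosome)
# and return per-segment summaries.  Vectorized via findInterval.
segment_snp_summary <- function(seg, sites) {
  chroms <- unique(seg$chrom)
  seg_id <- vector("list", length(chroms))
  fold <- vector("list", length(chroms))
  all_id <- vector("list", length(chroms))
  for (j in seq_along(chroms)) {
    cc <- chroms[j]
    iv <- which(seg$chrom == cc)
    iv <- iv[order(seg$start[iv])]
    sp <- which(sites$chrom == cc)
    if (length(sp) == 0) next
    hit <- findInterval(sites$pos[sp], seg$start[iv])
    ok <- hit >= 1 & sites$pos[sp] < seg$end[iv][pmax(hit, 1)]
    all_id[[j]] <- iv[hit[ok]]
    has_baf <- ok & !is.na(sites$tumor_baf[sp])
    seg_id[[j]] <- iv[hit[has_baf]]
    b <- sites$tumor_baf[sp][has_baf]
    fold[[j]] <- pmax(b, 1 - b)
  }
  seg_id <- unlist(seg_id)
  fold <- unlist(fold)
  all_id <- unlist(all_id)
  baf <- rep(NA_real_, nrow(seg))
  if (length(seg_id) > 0) {
    m <- rowsum(fold, seg_id)[, 1] / tabulate(seg_id, nrow(seg))[
      sort(unique(seg_id))]
    baf[sort(unique(seg_id))] <- m
  }
  n <- integer(nrow(seg))
  if (length(all_id) > 0) n <- tabulate(all_id, nrow(seg))
  list(mean_baf = baf, n_snps = n)
}

#' Simulate a full synthetic cohort
#'
#' Generates `cfg$n_patients` tumor profiles with shared control-panel
#' genotypes per patient, a panel variant table, and a clinical table
#' whose response and survival are linked to instability through the
#' configured effect sizes.  Deterministic given `seed`.  With `dir`
#' set, everything is also written in the dialects the package readers
#' consume: `segments/<id>.seg`, `snps/<id>.tsv`, `variants.tsv`,
#' `clinical.csv`, and the ground truth under `truth/`.
#'
#' @param cfg A [simulation_config()].
#' @param seed Integer seed.
#' @param dir Optional output directory.
#' @return A list of class `synthetic_cohort`: `profiles` and `sites`
#'   (named lists per patient), `variants`, `clinical`, `truth` (per
#'   patient table plus engineered event list), and `cfg`.
#' @export
simulate_cohort <- function(cfg, seed = 1, dir = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(seed)
  n <- cfg$n_patients
  ids <- sprintf("P%03d", seq_len(n))
  theta <- stats::runif(n)
  purity <- stats::runif(n, cfg$purity_range[1], cfg$purity_range[2])

  profiles <- vector("list", n)
  sites <- vector("list", n)
  truth_events <- vector("list", n)
  k <- integer(n)
  for (i in seq_len(n)) {
    sim <- simulate_profile(cfg, theta[i], purity[i], sample_id = ids[i])
    profiles[[i]] <- sim$profile
    sites[[i]] <- sim$sites
    k[i] <- sim$truth$n_events
    te <- sim$truth$events
    if (nrow(te) > 0) te$sample <- ids[i]
    truth_events[[i]] <- te
  }
  names(profiles) <- names(sites) <- ids

  z <- if (stats::sd(k) > 0) (k - mean(k)) / stats::sd(k) else rep(0, n)

  # clinical outcomes from the configured links
  p_resp <- stats::plogis(cfg$response_beta[1] + cfg$response_beta[2] * z)
  responder <- stats::runif(n) < p_resp
  ne <- stats::runif(n) < cfg$ne_prob
  best <- ifelse(
    ne, "NE",
    ifelse(responder,
           ifelse(stats::runif(n) < 1 / 7, "CR", "PR"),
           ifelse(stats::runif(n) < 0.7, "SD", "PD"))
  )
  t_pfs <- stats::rexp(n, rate = exp(cfg$pfs_gamma[1] - cfg$pfs_gamma[2] * z))
  c_pfs <- stats::runif(n, 0, cfg$censor_max)
  t_os <- stats::rexp(n, rate = exp(cfg$os_gamma[1] - cfg$os_gamma[2] * z))
  c_os <- stats::runif(n, 0, 1.5 * cfg$censor_max)
  tumor_type <- sample(c("ovarian", "endometrial", "breast"), n,
                       replace = TRUE, prob = c(0.63, 0.356, 0.014))
  clinical <- tibble::tibble(
    patient_id = ids,
    tumor_type = tumor_type,
    histology = ifelse(tumor_type == "ovarian", "HGS",
                       ifelse(tumor_type == "endometrial",
                              "endometrioid", "TNBC")),
    prior_lines = sample(0:6, n, replace = TRUE,
                         prob = c(0.08, 0.12, 0.18, 0.25, 0.20, 0.12,
                                  0.05)),
    best_response = best,
    pfs_months = round(pmin(t_pfs, c_pfs), 3),
    pfs_event = t_pfs <= c_pfs,
    os_months = round(pmin(t_os, c_os), 3),
    os_event = t_os <= c_os
  )
  class(clinical) <- c("clinical_table", class(clinical))

  variants <- simulate_variants(ids, theta, cfg)

  truth <- list(
    patients = tibble::tibble(sample = ids, theta = theta,
                              purity = purity, n_events_true = k,
                              z_gi = z, p_response = p_resp),
    events = dplyr::bind_rows(truth_events)
  )
  out <- list(profiles = profiles, sites = sites, variants = variants,
              clinical = clinical, truth = truth, cfg = cfg)
  class(out) <- "synthetic_cohort"
  if (!is.null(dir)) write_cohort(out, dir)
  out
}

simulate_variants <- function(ids, theta, cfg) {
  n <- length(ids)
  p_hrr <- stats::plogis(cfg$hrr_beta[1] + cfg$hrr_beta[2] * theta)
  has_hrr <- stats::runif(n) < p_hrr
  has_tp53 <- stats::runif(n) < 0.6
  has_noise <- stats::runif(n) < 0.3
  rows <- list()
  add <- function(sample, gene, coverage, vaf, classification, sift,
                  polyphen, path_prediction) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      sample = sample, gene = gene, coverage = coverage, vaf = vaf,
      classification = classification, sift = sift, polyphen = polyphen,
      path_prediction = path_prediction
    )
  }
  hrr <- default_hrr_genes()
  for (i in seq_len(n)) {
    if (has_hrr[i]) {
      add(ids[i], sample(hrr, 1), round(stats::runif(1, 150, 600)),
          round(stats::runif(1, 0.1, 0.6), 3),
          sample(c("P", "LP"), 1, prob = c(0.6, 0.4)),
          "pathogenic", "pathogenic", NA)
    }
    if (has_tp53[i]) {
      add(ids[i], "TP53", round(stats::runif(1, 150, 600)),
          round(stats::runif(1, 0.2, 0.8), 3), "P",
          "pathogenic", "pathogenic", NA)
    }
    if (has_noise[i]) {
      # sub-threshold noise call: low coverage or borderline VAF VUS
      low_cov <- stats::runif(1) < 0.5
      add(ids[i], sample(panel_genes(), 1),
          if (low_cov) round(stats::runif(1, 20, 99)) else
            round(stats::runif(1, 150, 600)),
          if (low_cov) round(stats::runif(1, 0.1, 0.4), 3) else
            round(stats::runif(1, 0.01, 0.05), 3),
          "VUS", "tolerated", "benign", FALSE)
    }
  }
  v <- dplyr::bind_rows(rows)
  if (nrow(v) == 0) {
    v <- tibble::tibble(sample = character(), gene = character(),
                        coverage = numeric(), vaf = numeric(),
                        classification = character(), sift = character(),
                        polyphen = character(), path_prediction = logical())
  }
  class(v) <- c("variant_table", class(v))
  v
}

write_cohort <- function(cohort, dir) {
  for (sub in c("segments", "snps", "truth")) {
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  }
  for (id in names(cohort$profiles)) {
    write_segments(cohort$profiles[[id]],
                   file.path(dir, "segments", paste0(id, ".seg")))
    write_snp_table(cohort$sites[[id]],
                    file.path(dir, "snps", paste0(id, ".tsv")))
  }
  write_variant_table(cohort$variants, file.path(dir, "variants.tsv"))
  write_clinical_table(cohort$clinical, file.path(dir, "clinical.csv"))
  readr::write_tsv(cohort$truth$patients,
                   file.path(dir, "truth", "patients.tsv"),
                   progress = FALSE)
  readr::write_tsv(cohort$truth$events,
                   file.path(dir, "truth", "events.tsv"), progress = FALSE)
  gm <- tibble::as_tibble(cohort$cfg$genome)
  readr::write_tsv(gm, file.path(dir, "genome_sizes.tsv"),
                   progress = FALSE)
  invisible(dir)
}
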