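#' Configuration for the synthetic multi-region cohort generator
#'
#' Bundles and validates every tunable of [simulate_cohort()]. The defaults
#' describe a multi-region NSCLC-like RRBS cohort: 20 patients with three
#' tumor regions and one adjacent-normal sample each, 50,000 CpGs at 30x
#' mean coverage, purity drawn uniformly from 0.3-0.9, and 2% of CpGs
#' planted as differentially methylated with effect size 0.3.
#'
#' @param n_patients Number of patients.
#' @param regions_per_patient Tumor regions sampled per patient.
#' @param n_cpgs Number of CpG sites.
#' @param n_genes Number of genes (each with a strand-aware promoter).
#' @param purity_range Range of tumor purity, drawn uniformly per patient.
#' @param coverage_mean Mean reads per CpG (Poisson).
#' @param dmp_fraction Fraction of CpGs planted as DMPs.
#' @param dmp_effect_size Planted tumor-normal methylation difference
#'   (must be >= 0.2, the effect-size floor the downstream caller assumes).
#' @param fraction_regulatory Fraction of planted promoter hyper-DMP CpGs
#'   whose hypermethylation causally reduces cognate-gene expression.
#' @param regulatory_expression_drop Multiplicative expression drop applied
#'   when a regulatory CpG is hypermethylated in a sample.
#' @param clonal_fraction Fraction of planted events present in all regions
#'   of a carrier patient; the rest are subclonal (strict subset of regions).
#' @param dmp_patient_fraction Probability that a given patient carries a
#'   planted event at all (default 1: every patient carries every planted
#'   DMP). Values below 1 create between-tumor variation in promoter
#'   hypermethylation, as needed e.g. to learn expression thresholds that
#'   separate hypermethylated from non-hypermethylated tumors.
#' @param n_amplicons Number of oncogene amplicons to plant.
#' @param amplicon_span_bp Maximum oncogene-passenger distance (default
#'   20 Mb); the amplified segment covers the oncogene +/- this span.
#' @param n_mrmn_genes Genes planted with regulatory-selective
#'   hypermethylation (regulatory CpG events at `mrmn_reg_rate` per sample,
#'   nonregulatory at `mrmn_nonreg_rate`), emulating selection for
#'   functional promoter silencing.
#' @param mrmn_reg_rate,mrmn_nonreg_rate Hypermethylation event rates for
#'   the two classes in planted selection genes: regulatory CpGs follow a
#'   latent per-sample silencing event at rate `mrmn_reg_rate` (which also
#'   drives the expression drop), nonregulatory CpGs are hypermethylated
#'   independently at `mrmn_nonreg_rate`.
#' @param mrmn_fraction_regulatory Fraction of a selection gene's promoter
#'   CpGs that are regulatory (independent of `fraction_regulatory`, which
#'   governs ordinary planted promoters).
#' @param cpg_participation Probability that a CpG of an ordinary planted
#'   hyper promoter participates in the gene's event in a given patient;
#'   below 1, per-CpG hypermethylation patterns vary within a promoter as
#'   they do in real tumors.
#' @param expression_sd Lognormal expression noise (natural-log sd).
#' @param expression_cn_scaling If `TRUE` (default), tumor expression scales
#'   with the bulk-averaged gene dosage at the TSS; set `FALSE` for a pure
#'   methylation-expression model with lognormal noise only.
#' @param patient_effect_sd Per-(CpG, patient) tumor-compartment rate noise:
#'   the patient-specific methylation signature.
#' @param region_effect_sd Per-(CpG, region) tumor-compartment rate noise.
#' @param cn_probs Probabilities of tumor total copy number 1, 2, 3 and 4
#'   for background copy-number segments. The default mixes losses, neutral
#'   and gained segments; a diploid-dominant vector (e.g.
#'   `c(0.02, 0.94, 0.03, 0.01)`) suits analyses that condition on planted
#'   focal amplifications.
#' @param reads_per_locus Epiallele reads simulated per promoter and sample.
#' @param cpgs_per_read CpG states per simulated epiallele read.
#' @param seed Mandatory integer seed; identical configurations and seeds
#'   give byte-identical cohorts.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_patients = 20,
                       regions_per_patient = 3,
                       n_cpgs = 50000,
                       n_genes = 1000,
                       purity_range = c(0.3, 0.9),
                       coverage_mean = 30,
                       dmp_fraction = 0.02,
                       dmp_effect_size = 0.3,
                       fraction_regulatory = 0.5,
                       regulatory_expression_drop = 0.5,
                       clonal_fraction = 0.8,
                       dmp_patient_fraction = 1,
                       n_amplicons = 0,
                       amplicon_span_bp = 2e7,
                       n_mrmn_genes = 0,
                       mrmn_reg_rate = 0.8,
                       mrmn_nonreg_rate = 0.1,
                       mrmn_fraction_regulatory = 0.5,
                       cpg_participation = 0.9,
                       expression_sd = 0.3,
                       expression_cn_scaling = TRUE,
                       patient_effect_sd = 0.05,
                       region_effect_sd = 0.02,
                       cn_probs = c(0.12, 0.64, 0.16, 0.08),
                       reads_per_locus = 50,
                       cpgs_per_read = 4,
                       seed) {
  if (missing(seed) || is.null(seed)) {
    abort("a seed is mandatory for reproducibility", class = "methevolve_config_error")
  }
  fracs <- c(dmp_fraction = dmp_fraction, fraction_regulatory = fraction_regulatory,
             regulatory_expression_drop = regulatory_expression_drop,
             clonal_fraction = clonal_fraction,
             dmp_patient_fraction = dmp_patient_fraction,
             mrmn_reg_rate = mrmn_reg_rate, mrmn_nonreg_rate = mrmn_nonreg_rate,
             mrmn_fraction_regulatory = mrmn_fraction_regulatory,
             cpg_participation = cpg_participation)
  if (any(fracs < 0 | fracs > 1)) {
    abort(sprintf("fraction parameters must lie in [0, 1]; offending: %s",
                  paste(names(fracs)[fracs < 0 | fracs > 1], collapse = ", ")),
          class = "methevolve_config_error")
  }
  if (dmp_effect_size < 0.2) {
    abort("dmp_effect_size must be >= 0.2, the downstream effect-size floor",
          class = "methevolve_config_error")
  }
  if (length(purity_range) != 2 || any(purity_range <= 0 | purity_range > 1) ||
      purity_range[1] > purity_range[2]) {
    abort("purity_range must be an increasing pair within (0, 1]",
          class = "methevolve_config_error")
  }
  if (length(cn_probs) != 4 || any(cn_probs < 0) || sum(cn_probs) <= 0) {
    abort("cn_probs must be 4 non-negative weights for n_t = 1..4",
          class = "methevolve_config_error")
  }
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_patients, "patients x", x$regions_per_patient,
      "regions,", x$n_cpgs, "CpGs,", x$n_genes, "genes, seed", x$seed, "\n")
  invisible(x)
}

# ---- layout ---------------------------------------------------------------

sim_layout <- function(cfg) {
  set.seed(substream_seed(cfg$seed, "layout"))
  n_chroms <- max(5L, cfg$n_amplicons)
  per_chrom <- ceiling(cfg$n_genes / n_chroms)
  spacing <- 400000L
  gene_id <- sprintf("g%04d", seq_len(cfg$n_genes))
  chrom_idx <- rep(seq_len(n_chroms), each = per_chrom)[seq_len(cfg$n_genes)]
  within_idx <- sequence(rle(chrom_idx)$lengths)
  genes <- tibble(
    gene_id = gene_id,
    chrom = paste0("chr", chrom_idx),
    tss = 1000000L + (within_idx - 1L) * spacing,
    strand = rep_len(c("+", "-"), cfg$n_genes)
  )
  promoters <- promoter_windows(genes)

  # per-gene promoter CpG counts vary (Poisson around the mean density);
  # CpGs cluster in a CpG-island-like core around the TSS (mean spacing
  # ~45 bp) as in RRBS data, rather than spreading over the whole window
  k_base <- max(3L, floor(0.6 * cfg$n_cpgs / cfg$n_genes))
  k_gene <- pmax(3L, rpois(cfg$n_genes, k_base))
  prom_pos <- purrr::pmap(
    list(promoters$window_start, promoters$window_end, genes$tss, k_gene),
    function(a, b, tss0, k) {
      island <- max(300L, as.integer(45 * k))
      lo <- max(a, tss0 - island %/% 2)
      hi <- min(b, lo + island)
      sort(sample(seq(lo, hi), k))
    }
  )
  prom_cpgs <- tibble(
    chrom = rep(promoters$chrom, k_gene),
    pos = unlist(prom_pos),
    gene_id = rep(promoters$gene_id, k_gene)
  )
  chrom_span <- promoters |>
    group_by(.data$chrom) |>
    summarise(span = max(.data$window_end) + 1000000L, .groups = "drop")
  draw_inter <- function(n) {
    tibble(chrom = sample(chrom_span$chrom, n, replace = TRUE)) |>
      left_join(chrom_span, by = "chrom") |>
      mutate(pos = floor(runif(n, 1, .data$span)), gene_id = NA_character_) |>
      select(-"span")
  }
  cpgs <- bind_rows(prom_cpgs, draw_inter(max(0L, cfg$n_cpgs - nrow(prom_cpgs)))) |>
    distinct(.data$chrom, .data$pos, .keep_all = TRUE)
  while (nrow(cpgs) < cfg$n_cpgs) {
    cpgs <- bind_rows(cpgs, draw_inter(cfg$n_cpgs - nrow(cpgs))) |>
      distinct(.data$chrom, .data$pos, .keep_all = TRUE)
  }
  cpgs <- cpgs |>
    head(cfg$n_cpgs) |>
    arrange(.data$chrom, .data$pos)
  list(genes = genes, promoters = promoters, cpgs = cpgs,
       chrom_span = chrom_span, n_chroms = n_chroms)
}

# ---- baseline rates and planted events ------------------------------------

sim_rates <- function(cfg, layout) {
  set.seed(substream_seed(cfg$seed, "rates"))
  cpgs <- layout$cpgs
  n <- nrow(cpgs)
  in_prom <- !is.na(cpgs$gene_id)
  # bimodal CpG methylation: modes near 0.05 and 0.95; promoter CpGs mostly
  # unmethylated, intergenic CpGs mostly methylated
  low_mode <- ifelse(in_prom, runif(n) < 0.85, runif(n) < 0.25)
  m_n <- ifelse(low_mode, rbeta(n, 2, 38), rbeta(n, 38, 2))
  cpgs$m_n <- clamp01(m_n, 1e-4)
  cpgs
}

sim_events <- function(cfg, cpgs) {
  set.seed(substream_seed(cfg$seed, "events"))
  n <- nrow(cpgs)
  delta <- cfg$dmp_effect_size
  cpgs$dmp_status <- "none"
  cpgs$clonal <- NA
  cpgs$regulatory <- NA
  cpgs$mrmn_gene <- FALSE

  in_prom <- !is.na(cpgs$gene_id)
  n_dmp <- round(cfg$dmp_fraction * n)
  n_hyper <- round(2 / 3 * n_dmp)
  n_hypo <- n_dmp - n_hyper

  # hyper DMPs are planted at whole promoters so region-level calls (DMRs)
  # have the run structure the caller requires; clonality is a property of
  # the gene-level event and is shared by the promoter's CpGs
  elig_hyper <- in_prom & cpgs$m_n + delta <= 0.98
  pool_counts <- cpgs |>
    filter(elig_hyper) |>
    count(.data$gene_id)
  pool <- sample(pool_counts$gene_id)
  n_take <- sum(cumsum(pool_counts$n[match(pool, pool_counts$gene_id)]) <=
                  max(n_hyper, 0))
  hyper_genes <- sort(pool[seq_len(n_take)])
  hyper_idx <- which(elig_hyper & cpgs$gene_id %in% hyper_genes)
  cpgs$dmp_status[hyper_idx] <- "hyper"
  gene_clonal <- setNames(runif(length(hyper_genes)) < cfg$clonal_fraction,
                          hyper_genes)
  cpgs$clonal[hyper_idx] <- gene_clonal[cpgs$gene_id[hyper_idx]]
  cpgs$regulatory[hyper_idx] <- runif(length(hyper_idx)) < cfg$fraction_regulatory

  elig_hypo <- which(cpgs$dmp_status == "none" & cpgs$m_n - delta >= 0.02)
  hypo_idx <- sort(sample(elig_hypo, min(n_hypo, length(elig_hypo))))
  cpgs$dmp_status[hypo_idx] <- "hypo"
  cpgs$clonal[hypo_idx] <- runif(length(hypo_idx)) < cfg$clonal_fraction

  # selection genes: a latent per-sample silencing event drives both the
  # hypermethylation of the regulatory CpGs and the expression drop;
  # nonregulatory CpGs are hypermethylated independently at a low rate
  if (cfg$n_mrmn_genes > 0) {
    sel_pool <- setdiff(pool_counts$gene_id, hyper_genes)
    sel <- sort(sample(sel_pool, min(cfg$n_mrmn_genes, length(sel_pool))))
    sel_idx <- which(cpgs$gene_id %in% sel & elig_hyper)
    cpgs$dmp_status[sel_idx] <- "hyper"
    cpgs$mrmn_gene[sel_idx] <- TRUE
    cpgs$clonal[sel_idx] <- NA
    cpgs$regulatory[sel_idx] <-
      runif(length(sel_idx)) < cfg$mrmn_fraction_regulatory
  }
  cpgs
}

# strict non-empty subset of region columns
subset_regions <- function(n_regions) {
  size <- if (n_regions <= 2) 1L else sample(seq_len(n_regions - 1), 1)
  sample(n_regions, size)
}

# per-(planted CpG, tumor sample) event presence
sim_event_matrix <- function(cfg, cpgs, tumor_samples) {
  E <- matrix(FALSE, nrow(cpgs), nrow(tumor_samples))
  planted <- which(cpgs$dmp_status != "none")
  if (length(planted) == 0) return(E)
  pats <- unique(tumor_samples$patient_id)

  ordinary_hyper <- !cpgs$mrmn_gene & cpgs$dmp_status == "hyper"
  hyper_genes <- unique(cpgs$gene_id[ordinary_hyper])
  hypo_idx <- which(cpgs$dmp_status == "hypo")
  sel_idx <- which(cpgs$mrmn_gene)
  sel_genes <- unique(cpgs$gene_id[sel_idx])

  for (p in pats) {
    cols <- which(tumor_samples$patient_id == p)
    R <- length(cols)
    # ordinary hyper promoters: one gene-level event per patient (all
    # regions if clonal, a strict subset otherwise); each CpG of the
    # promoter participates in this patient with cpg_participation
    for (g in hyper_genes) {
      if (runif(1) >= cfg$dmp_patient_fraction) next
      rows <- which(ordinary_hyper & cpgs$gene_id == g)
      pattern <- rep(FALSE, R)
      if (cpgs$clonal[rows[1]]) pattern[] <- TRUE
      else if (R >= 2) pattern[subset_regions(R)] <- TRUE
      else pattern[1] <- TRUE
      part <- runif(length(rows)) < cfg$cpg_participation
      if (any(part)) {
        E[rows[part], cols] <- matrix(pattern, sum(part), R, byrow = TRUE)
      }
    }
    # hypo DMPs: independent per CpG
    if (length(hypo_idx) > 0) {
      pres <- matrix(FALSE, length(hypo_idx), R)
      carrier <- runif(length(hypo_idx)) < cfg$dmp_patient_fraction
      clonal <- cpgs$clonal[hypo_idx]
      pres[carrier & clonal, ] <- TRUE
      for (j in which(carrier & !clonal)) {
        if (R >= 2) pres[j, subset_regions(R)] <- TRUE else pres[j, 1] <- TRUE
      }
      E[hypo_idx, cols] <- pres
    }
  }
  # selection genes: latent silencing event per (gene, sample)
  if (length(sel_idx) > 0) {
    for (g in sel_genes) {
      rows <- sel_idx[cpgs$gene_id[sel_idx] == g]
      reg <- cpgs$regulatory[rows]
      S <- runif(nrow(tumor_samples)) < cfg$mrmn_reg_rate
      E[rows[reg], ] <- matrix(S, sum(reg), length(S), byrow = TRUE)
      n_nonreg <- sum(!reg)
      if (n_nonreg > 0) {
        E[rows[!reg], ] <- matrix(
          runif(n_nonreg * nrow(tumor_samples)) < cfg$mrmn_nonreg_rate,
          n_nonreg)
      }
    }
  }
  E
}

# ---- copy number ----------------------------------------------------------

sim_cn <- function(cfg, layout, tumor_samples) {
  set.seed(substream_seed(cfg$seed, "cn"))
  span <- layout$chrom_span
  cn_levels <- c(1L, 2L, 3L, 4L)
  cn_prob <- cfg$cn_probs / sum(cfg$cn_probs)
  pats <- unique(tumor_samples$patient_id)
  seg_list <- vector("list", length(pats))
  names(seg_list) <- pats
  for (p in pats) {
    segs <- purrr::map(seq_len(nrow(span)), function(ci) {
      k <- sample(1:3, 1)
      bp <- sort(sample(seq(2, span$span[ci] - 1), k))
      starts <- c(1L, bp)
      ends <- c(bp - 1L, span$span[ci])
      tibble(chrom = span$chrom[ci], start = as.integer(starts),
             end = as.integer(ends),
             n_t = sample(cn_levels, k + 1, replace = TRUE, prob = cn_prob))
    })
    seg_list[[p]] <- bind_rows(segs)
  }
  out <- purrr::map(seq_len(nrow(tumor_samples)), function(i) {
    s <- tumor_samples[i, ]
    seg <- seg_list[[s$patient_id]]
    # subclonal copy-number change: each segment independently redrawn in
    # ~15% of regions, giving the region-level SCNA heterogeneity
    # multi-region tumors show
    redraw <- runif(nrow(seg)) < 0.15
    if (any(redraw)) {
      seg$n_t[redraw] <- sample(cn_levels, sum(redraw), replace = TRUE,
                                prob = cn_prob)
    }
    mutate(seg, sample_id = s$sample_id, n_n = 2L)
  })
  bind_rows(out) |>
    select(dplyr::all_of(c("sample_id", "chrom", "start", "end", "n_t", "n_n")))
}

# n_t at each CpG for each tumor sample, as a matrix
cn_at_sites <- function(cpgs, segments, sample_ids) {
  M <- matrix(NA_integer_, nrow(cpgs), length(sample_ids))
  colnames(M) <- sample_ids
  for (j in seq_along(sample_ids)) {
    seg <- segments[segments$sample_id == sample_ids[j], ]
    for (ch in unique(cpgs$chrom)) {
      rows <- which(cpgs$chrom == ch)
      sc <- seg[seg$chrom == ch, ]
      sc <- sc[order(sc$start), ]
      if (nrow(sc) == 0) next
      idx <- findInterval(cpgs$pos[rows], sc$start)
      ok <- idx >= 1 & cpgs$pos[rows] <= sc$end[pmax(idx, 1L)]
      M[rows[ok], j] <- sc$n_t[idx[ok]]
    }
  }
  M
}

sample_ploidy <- function(segments) {
  segments |>
    group_by(.data$sample_id) |>
    summarise(
      ploidy = sum(.data$n_t * (.data$end - .data$start + 1)) /
        sum(.data$end - .data$start + 1),
      .groups = "drop"
    )
}

# ---- truth assembly -------------------------------------------------------

#' Generate the latent ground truth of a synthetic cohort
#'
#' Builds everything downstream observables are drawn from: per-CpG normal
#' and tumor-compartment methylation rates, planted DMP events with clonal
#' structure, per-sample purity and copy-number segments, expression models
#' and per-promoter epiallele discordance (PDR). Amplicons can be planted on
#' the returned object with [plant_amplicon_with_compensation()] before
#' drawing observable tables with [draw_cohort()].
#'
#' @param config A [sim_config()].
#' @return An object of class `"methevolve_truth"`.
#' @export
simulate_truth <- function(config) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be created by sim_config()", class = "methevolve_config_error")
  }
  cfg <- config
  layout <- sim_layout(cfg)
  cpgs <- sim_rates(cfg, layout)
  cpgs <- sim_events(cfg, cpgs)

  set.seed(substream_seed(cfg$seed, "samples"))
  pats <- sprintf("P%02d", seq_len(cfg$n_patients))
  purity <- runif(cfg$n_patients, cfg$purity_range[1], cfg$purity_range[2])
  tumor_samples <- tibble(
    sample_id = paste0(rep(pats, each = cfg$regions_per_patient), "-R",
                       rep(seq_len(cfg$regions_per_patient), cfg$n_patients)),
    patient_id = rep(pats, each = cfg$regions_per_patient),
    region_id = paste0("R", rep(seq_len(cfg$regions_per_patient), cfg$n_patients)),
    tissue = "tumor",
    purity = rep(purity, each = cfg$regions_per_patient),
    histology = rep(rep_len(c("LUAD", "LUSC"), cfg$n_patients),
                    each = cfg$regions_per_patient)
  )
  normal_samples <- tibble(
    sample_id = paste0(pats, "-N"),
    patient_id = pats, region_id = "N", tissue = "normal",
    purity = NA_real_,
    histology = rep_len(c("LUAD", "LUSC"), cfg$n_patients)
  )
  segments <- sim_cn(cfg, layout, tumor_samples)
  ploidy <- sample_ploidy(segments)
  tumor_samples <- left_join(tumor_samples, ploidy, by = "sample_id")
  normal_samples$ploidy <- 2
  samples <- bind_rows(tumor_samples, normal_samples) |>
    relocate("sample_id", "patient_id", "region_id", "tissue", "purity",
             "ploidy", "histology")

  set.seed(substream_seed(cfg$seed, "counts"))
  E <- sim_event_matrix(cfg, cpgs, tumor_samples)
  colnames(E) <- tumor_samples$sample_id
  n <- nrow(cpgs)
  ns <- nrow(tumor_samples)
  delta <- cfg$dmp_effect_size
  base_t <- cpgs$m_n
  shift <- ifelse(cpgs$dmp_status == "hyper", delta,
                  ifelse(cpgs$dmp_status == "hypo", -delta, 0))
  m_t <- matrix(base_t, n, ns) + matrix(shift, n, ns) * E
  pat_idx <- match(tumor_samples$patient_id, pats)
  if (cfg$patient_effect_sd > 0) {
    pe <- matrix(rnorm(n * cfg$n_patients, 0, cfg$patient_effect_sd), n)
    m_t <- m_t + pe[, pat_idx]
  }
  if (cfg$region_effect_sd > 0) {
    m_t <- m_t + matrix(rnorm(n * ns, 0, cfg$region_effect_sd), n)
  }
  m_t <- clamp01(m_t, 1e-4)
  colnames(m_t) <- tumor_samples$sample_id

  set.seed(substream_seed(cfg$seed, "expression"))
  base_expr <- exp(rnorm(cfg$n_genes, log(100), 1))
  names(base_expr) <- layout$genes$gene_id

  set.seed(substream_seed(cfg$seed, "pdr"))
  pdr_n <- rbeta(cfg$n_genes, 2, 18)
  pdr_t <- clamp01(pdr_n + runif(cfg$n_genes, 0.05, 0.35))
  pdr <- tibble(gene_id = layout$genes$gene_id, pdr_n = pdr_n, pdr_t = pdr_t)

  truth <- list(
    config = cfg,
    genes = layout$genes,
    promoters = layout$promoters,
    chrom_span = layout$chrom_span,
    cpgs = cpgs,
    events = E,
    m_t = m_t,
    samples = samples,
    segments = segments,
    base_expr = base_expr,
    compensated = matrix(FALSE, cfg$n_genes, ns,
                         dimnames = list(layout$genes$gene_id,
                                         tumor_samples$sample_id)),
    amplicon_open = matrix(FALSE, cfg$n_genes, ns,
                           dimnames = list(layout$genes$gene_id,
                                           tumor_samples$sample_id)),
    pdr = pdr,
    amplicons = tibble(
      amplicon_id = character(), oncogene_id = character(),
      passenger_ids = list(), chrom = character(),
      start = integer(), end = integer(), n_t_amp = integer()
    )
  )
  class(truth) <- "methevolve_truth"
  truth
}

#' @export
print.methevolve_truth <- function(x, ...) {
  cat("<methevolve_truth>", nrow(x$cpgs), "CpGs,",
      sum(x$samples$tissue == "tumor"), "tumor +",
      sum(x$samples$tissue == "normal"), "normal samples,",
      nrow(x$amplicons), "amplicons\n")
  invisible(x)
}

# replace the copy number of `sample_ids` over [start, end] with n_t_amp,
# splitting any overlapping segments
splice_segment <- function(segments, sample_ids, chrom, start, end, n_t_amp) {
  target <- segments$sample_id %in% sample_ids & segments$chrom == chrom
  keep <- segments[!target, ]
  seg <- segments[target, ]
  pieces <- purrr::map(seq_len(nrow(seg)), function(i) {
    s <- seg[i, ]
    if (s$end < start || s$start > end) return(s)
    out <- list()
    if (s$start < start) out <- c(out, list(mutate(s, end = start - 1L)))
    if (s$end > end) out <- c(out, list(mutate(s, start = end + 1L)))
    bind_rows(out)
  })
  amp <- tibble(
    sample_id = sample_ids, chrom = chrom,
    start = as.integer(start), end = as.integer(end),
    n_t = as.integer(n_t_amp), n_n = 2L
  )
  bind_rows(keep, bind_rows(pieces), amp) |>
    arrange(.data$sample_id, .data$chrom, .data$start)
}

#' Plant an amplified oncogene locus with dosage-compensated passengers
#'
#' Overlays an amplified copy-number segment (`n_t_amp`) covering the
#' oncogene and the surrounding span in the amplified samples, and encodes
#' the divergent chromatin response: every co-amplified gene experiences a
#' mild promoter opening (slightly lower methylation, more H3K4me3, less
#' H3K27me3) while the designated compensated passengers close instead --
#' promoter methylation increases by at least 0.2, H3K4me3 drops, H3K27me3
#' rises, and expression is held at baseline rather than scaling with copy
#' number. Oncogene expression scales with `n_t_amp`.
#'
#' @param truth A `"methevolve_truth"` object.
#' @param oncogene_id Gene to amplify.
#' @param passenger_ids Compensated passenger genes; must lie within
#'   `amplicon_span_bp` of the oncogene on the same chromosome.
#' @param n_t_amp Amplified total copy number (default ploidy + 3 = 5).
#' @param amplified_patients Patients whose regions carry the amplification;
#'   default: the first half of patients.
#' @param meth_increase Planted passenger promoter methylation increase
#'   (default 0.3; must be >= 0.2).
#' @return The modified truth object.
#' @export
plant_amplicon_with_compensation <- function(truth, oncogene_id, passenger_ids,
                                             n_t_amp = 5,
                                             amplified_patients = NULL,
                                             meth_increase = 0.3) {
  stopifnot(inherits(truth, "methevolve_truth"))
  if (meth_increase < 0.2) {
    abort("meth_increase must be >= 0.2", class = "methevolve_config_error")
  }
  genes <- truth$genes
  onco <- genes[genes$gene_id == oncogene_id, ]
  if (nrow(onco) != 1) abort(sprintf("unknown oncogene '%s'", oncogene_id))
  pass <- genes[genes$gene_id %in% passenger_ids, ]
  span <- truth$config$amplicon_span_bp
  if (any(pass$chrom != onco$chrom) ||
      any(abs(pass$tss - onco$tss) > span)) {
    abort(sprintf("passengers must lie within %g bp of the oncogene on %s",
                  span, onco$chrom),
          class = "methevolve_range_error")
  }
  tum <- truth$samples[truth$samples$tissue == "tumor", ]
  pats <- unique(tum$patient_id)
  if (is.null(amplified_patients)) {
    amplified_patients <- pats[seq_len(ceiling(length(pats) / 2))]
  }
  amp_samples <- tum$sample_id[tum$patient_id %in% amplified_patients]
  a_start <- max(1L, onco$tss - as.integer(span))
  a_end <- onco$tss + as.integer(span)
  if (length(amp_samples) > 0) {
    truth$segments <- splice_segment(truth$segments, amp_samples, onco$chrom,
                                     a_start, a_end, n_t_amp)
  }
  co_amp <- genes$gene_id[genes$chrom == onco$chrom &
                            genes$tss >= a_start & genes$tss <= a_end]
  amp_cols <- colnames(truth$m_t) %in% amp_samples
  open_rows <- !is.na(truth$cpgs$gene_id) & truth$cpgs$gene_id %in% co_amp
  close_rows <- !is.na(truth$cpgs$gene_id) & truth$cpgs$gene_id %in% passenger_ids
  # locus-wide mild opening, passenger-specific closing
  truth$m_t[open_rows, amp_cols] <- clamp01(
    truth$m_t[open_rows, amp_cols] - 0.03, 1e-4)
  truth$m_t[close_rows, amp_cols] <- clamp01(
    truth$m_t[close_rows, amp_cols] + 0.03 + meth_increase, 1e-4)
  truth$amplicon_open[co_amp, amp_cols] <- TRUE
  truth$compensated[intersect(passenger_ids, rownames(truth$compensated)),
                    amp_cols] <- TRUE
  truth$amplicons <- bind_rows(truth$amplicons, tibble(
    amplicon_id = sprintf("amp%02d", nrow(truth$amplicons) + 1L),
    oncogene_id = oncogene_id,
    passenger_ids = list(passenger_ids),
    chrom = onco$chrom, start = a_start, end = a_end,
    n_t_amp = as.integer(n_t_amp)
  ))
  truth
}

# ---- observable draws -----------------------------------------------------

rpois_min1 <- function(n, lambda) pmax(1L, rpois(n, lambda))

#' Draw the observable cohort tables from a ground truth
#'
#' Samples read counts, expression values and histone signals around the
#' latent truth: bulk tumor methylation counts are binomial around the
#' purity/copy-number mixture of the tumor-compartment and normal rates,
#' normal counts binomial around the normal rate, expression lognormal
#' around the copy-number-scaled (or compensated) mean with regulatory
#' hypermethylation drops applied, and histone window sums Poisson around
#' open/closed promoter levels.
#'
#' @param truth A `"methevolve_truth"` object.
#' @return A list of class `"methevolve_cohort"` with elements `methylation`,
#'   `samples`, `segments`, `expression`, `promoters`, `histone` and `truth`.
#' @export
draw_cohort <- function(truth) {
  stopifnot(inherits(truth, "methevolve_truth"))
  cfg <- truth$config
  set.seed(substream_seed(cfg$seed, "coverage"))
  cpgs <- truth$cpgs
  n <- nrow(cpgs)
  tum <- truth$samples[truth$samples$tissue == "tumor", ]
  nor <- truth$samples[truth$samples$tissue == "normal", ]

  cn <- cn_at_sites(cpgs, truth$segments, tum$sample_id)
  rho <- matrix(tum$purity, n, nrow(tum), byrow = TRUE)
  denom <- cn * rho + 2 * (1 - rho)
  m_b <- (truth$m_t * cn * rho + cpgs$m_n * 2 * (1 - rho)) / denom

  total_t <- matrix(rpois_min1(n * nrow(tum), cfg$coverage_mean), n)
  meth_t <- matrix(rbinom(n * nrow(tum), as.vector(total_t), as.vector(m_b)), n)
  total_n <- matrix(rpois_min1(n * nrow(nor), cfg$coverage_mean), n)
  meth_n <- matrix(rbinom(n * nrow(nor), as.vector(total_n), cpgs$m_n), n)

  meth_long <- bind_rows(
    tibble(
      chrom = rep(cpgs$chrom, nrow(tum)),
      pos = rep(cpgs$pos, nrow(tum)),
      sample_id = rep(tum$sample_id, each = n),
      meth = as.vector(meth_t),
      total = as.vector(total_t)
    ),
    tibble(
      chrom = rep(cpgs$chrom, nrow(nor)),
      pos = rep(cpgs$pos, nrow(nor)),
      sample_id = rep(nor$sample_id, each = n),
      meth = as.vector(meth_n),
      total = as.vector(total_n)
    )
  ) |>
    mutate(rate = .data$meth / .data$total)

  set.seed(substream_seed(cfg$seed, "expression") + 1L)
  genes <- truth$genes
  tss_sites <- tibble(chrom = genes$chrom, pos = genes$tss)
  cn_tss <- cn_at_sites(tss_sites, truth$segments, tum$sample_id)
  rho_g <- matrix(tum$purity, nrow(genes), nrow(tum), byrow = TRUE)
  mult_cn <- (cn_tss * rho_g + 2 * (1 - rho_g)) / 2
  mult_cn[is.na(mult_cn)] <- 1
  if (!isTRUE(cfg$expression_cn_scaling)) mult_cn[] <- 1
  mult_cn[truth$compensated] <- 1  # dosage-compensated: expression at baseline

  # regulatory hypermethylation drop: any regulatory CpG event in the sample
  reg_rows <- which(!is.na(cpgs$regulatory) & cpgs$regulatory)
  drop_mat <- matrix(1, nrow(genes), nrow(tum),
                     dimnames = list(genes$gene_id, tum$sample_id))
  if (length(reg_rows) > 0) {
    ev <- truth$events[reg_rows, , drop = FALSE]
    gid <- cpgs$gene_id[reg_rows]
    for (g in unique(gid)) {
      any_ev <- colSums(ev[gid == g, , drop = FALSE]) > 0
      drop_mat[g, any_ev] <- cfg$regulatory_expression_drop
    }
  }
  mu_t <- truth$base_expr * mult_cn * drop_mat
  expr_t <- mu_t * exp(matrix(rnorm(length(mu_t), 0, cfg$expression_sd),
                              nrow(mu_t)))
  expr_n <- truth$base_expr *
    exp(matrix(rnorm(nrow(genes) * nrow(nor), 0, cfg$expression_sd), nrow(genes)))
  expression <- bind_rows(
    tibble(
      gene_id = rep(genes$gene_id, nrow(tum)),
      sample_id = rep(tum$sample_id, each = nrow(genes)),
      value = as.vector(expr_t)
    ),
    tibble(
      gene_id = rep(genes$gene_id, nrow(nor)),
      sample_id = rep(nor$sample_id, each = nrow(genes)),
      value = as.vector(expr_n)
    )
  )

  set.seed(substream_seed(cfg$seed, "histone"))
  k4_base <- 200; k27_base <- 50
  open <- truth$amplicon_open & !truth$compensated
  closed <- truth$compensated
  k4_mu <- matrix(k4_base, nrow(genes), nrow(tum))
  k27_mu <- matrix(k27_base, nrow(genes), nrow(tum))
  k4_mu[open] <- k4_base * 1.3
  k27_mu[open] <- k27_base * 0.8
  k4_mu[closed] <- k4_base * 0.3
  k27_mu[closed] <- k27_base * 3
  histone_t <- tibble(
    gene_id = rep(rep(genes$gene_id, nrow(tum)), 2),
    sample_id = rep(rep(tum$sample_id, each = nrow(genes)), 2),
    mark = rep(c("H3K4me3", "H3K27me3"), each = nrow(genes) * nrow(tum)),
    window_sum = c(rpois(length(k4_mu), as.vector(k4_mu)),
                   rpois(length(k27_mu), as.vector(k27_mu)))
  )
  # normal reference tracks are deeply sequenced pools, so their window
  # signal carries far less shot noise than a single tumor sample
  depth <- 20
  histone_n <- tibble(
    gene_id = rep(rep(genes$gene_id, nrow(nor)), 2),
    sample_id = rep(rep(nor$sample_id, each = nrow(genes)), 2),
    mark = rep(c("H3K4me3", "H3K27me3"), each = nrow(genes) * nrow(nor)),
    window_sum = c(rpois(nrow(genes) * nrow(nor), depth * k4_base),
                   rpois(nrow(genes) * nrow(nor), depth * k27_base)) / depth
  )

  structure(
    list(
      methylation = meth_long,
      samples = truth$samples,
      segments = truth$segments,
      expression = expression,
      promoters = truth$promoters,
      histone = bind_rows(histone_t, histone_n),
      truth = truth
    ),
    class = "methevolve_cohort"
  )
}

#' @export
print.methevolve_cohort <- function(x, ...) {
  cat("<methevolve_cohort>", format(nrow(x$methylation), big.mark = ","),
      "methylation observations,", nrow(x$samples), "samples,",
      nrow(x$truth$genes), "genes\n")
  invisible(x)
}

#' Simulate a complete synthetic multi-region cohort
#'
#' Convenience wrapper: builds the ground truth with [simulate_truth()],
#' auto-plants `n_amplicons` oncogene amplicons (one per chromosome, each
#' with two compensated passenger genes), and draws the observable tables
#' with [draw_cohort()]. Identical configurations and seeds give identical
#' output.
#'
#' @param config A [sim_config()].
#' @return A `"methevolve_cohort"` list; see [draw_cohort()].
#' @export
simulate_cohort <- function(config) {
  truth <- simulate_truth(config)
  if (config$n_amplicons > 0) {
    set.seed(substream_seed(config$seed, "amplicon"))
    genes <- truth$genes
    chroms <- unique(genes$chrom)[seq_len(config$n_amplicons)]
    for (ch in chroms) {
      g <- genes[genes$chrom == ch, ]
      mid <- g[which.min(abs(g$tss - stats::median(g$tss))), ]
      neighbors <- g$gene_id[g$gene_id != mid$gene_id &
                               abs(g$tss - mid$tss) <= config$amplicon_span_bp]
      pass <- head(neighbors, 2)
      truth <- plant_amplicon_with_compensation(truth, mid$gene_id, pass)
    }
  }
  draw_cohort(truth)
}

#' Simulate read-level epialleles for PDR estimation
#'
#' Draws multi-CpG reads per promoter and sample. For bulk tumor samples
#' each read originates from the tumor compartment with probability
#' \eqn{n_t\rho / (n_t\rho + n_n(1-\rho))} and from the normal compartment
#' otherwise; a compartment read is discordant (mixed M/U states) with
#' probability equal to that compartment's true PDR, so the empirical bulk
#' discordance converges to the forward purity/CN mixture of `pdr_t` and
#' `pdr_n`.
#'
#' @param truth A `"methevolve_truth"` object.
#' @param genes Gene ids to simulate (default: all).
#' @param reads_per_locus Reads per promoter and sample (default from config).
#' @param k CpG states per read (default from config; must be >= 2).
#' @return Tibble with `read_id`, `sample_id`, `gene_id`, `compartment`
#'   (`tumor`/`normal`) and `states` (string of `M`/`U`).
#' @export
simulate_reads_for_pdr <- function(truth, genes = NULL, reads_per_locus = NULL,
                                   k = NULL) {
  stopifnot(inherits(truth, "methevolve_truth"))
  cfg <- truth$config
  reads_per_locus <- reads_per_locus %||% cfg$reads_per_locus
  k <- k %||% cfg$cpgs_per_read
  if (k < 2) {
    abort("reads must span at least 2 CpGs", class = "methevolve_range_error")
  }
  set.seed(substream_seed(cfg$seed, "reads"))
  genes <- genes %||% truth$genes$gene_id
  gdf <- truth$genes[truth$genes$gene_id %in% genes, ]
  samples <- truth$samples
  tum <- samples[samples$tissue == "tumor", ]

  cn_tss <- cn_at_sites(tibble(chrom = gdf$chrom, pos = gdf$tss),
                        truth$segments, tum$sample_id)
  # promoter-level mean methylation per compartment, for concordant reads
  prom_mean_t <- purrr::map(gdf$gene_id, function(g) {
    rows <- which(!is.na(truth$cpgs$gene_id) & truth$cpgs$gene_id == g)
    if (length(rows) == 0) rep(0.1, ncol(truth$m_t))
    else colMeans(truth$m_t[rows, , drop = FALSE])
  })
  prom_mean_n <- purrr::map_dbl(gdf$gene_id, function(g) {
    rows <- which(!is.na(truth$cpgs$gene_id) & truth$cpgs$gene_id == g)
    if (length(rows) == 0) 0.1 else mean(truth$cpgs$m_n[rows])
  })
  pdr <- truth$pdr[match(gdf$gene_id, truth$pdr$gene_id), ]

  # all discordant patterns on k CpGs (both states present)
  pats <- purrr::map_chr(1:(2^k - 2), function(x) {
    bits <- as.integer(intToBits(x))[seq_len(k)]
    paste(ifelse(bits == 1, "M", "U"), collapse = "")
  })

  draw_block <- function(sample_id, w_t, mean_t, mean_n, pdr_t, pdr_n, gene_id) {
    nr <- reads_per_locus
    comp <- runif(nr) < w_t
    disc <- runif(nr) < ifelse(comp, pdr_t, pdr_n)
    all_m <- runif(nr) < ifelse(comp, mean_t, mean_n)
    states <- ifelse(disc, sample(pats, nr, replace = TRUE),
                     ifelse(all_m, strrep("M", k), strrep("U", k)))
    tibble(sample_id = sample_id, gene_id = gene_id,
           compartment = ifelse(comp, "tumor", "normal"), states = states)
  }

  blocks <- vector("list", nrow(gdf) * nrow(samples))
  b <- 1L
  for (gi in seq_len(nrow(gdf))) {
    for (si in seq_len(nrow(samples))) {
      s <- samples[si, ]
      if (s$tissue == "tumor") {
        j <- match(s$sample_id, tum$sample_id)
        nt <- cn_tss[gi, j]
        if (is.na(nt)) nt <- 2L
        w_t <- nt * s$purity / (nt * s$purity + 2 * (1 - s$purity))
        mt <- prom_mean_t[[gi]][j]
        pt <- pdr$pdr_t[gi]
      } else {
        w_t <- 0; mt <- prom_mean_n[gi]; pt <- pdr$pdr_t[gi]
      }
      blocks[[b]] <- draw_block(s$sample_id, w_t, mt, prom_mean_n[gi],
                                pt, pdr$pdr_n[gi], gdf$gene_id[gi])
      b <- b + 1L
    }
  }
  out <- bind_rows(blocks)
  mutate(out, read_id = sprintf("r%07d", row_number()), .before = 1)
}
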