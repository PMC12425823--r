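test_that("identical config and seed give identical cohorts", {
  cfg <- sim_config(n_patients = 2, regions_per_patient = 2, n_cpgs = 500,
                    n_genes = 20, seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$methylation, b$methylation)
  expect_identical(a$expression, b$expression)
  expect_identical(a$segments, b$segments)
  c2 <- simulate_cohort(sim_config(n_patients = 2, regions_per_patient = 2,
                                   n_cpgs = 500, n_genes = 20, seed = 8))
  expect_false(identical(a$methylation$meth, c2$methylation$meth))
})

test_that("cohort dimensions follow the configuration", {
  co <- simulate_cohort(sim_config(n_patients = 2, regions_per_patient = 2,
                                   n_cpgs = 1000, n_genes = 30, seed = 3))
  counts <- dplyr::count(co$methylation, sample_id)
  expect_equal(nrow(counts), 6)  # 4 tumor regions + 2 normals
  expect_true(all(counts$n == 1000))
  expect_equal(sum(co$samples$tissue == "tumor"), 4)
  expect_equal(sum(co$samples$tissue == "normal"), 2)
  expect_equal(dplyr::n_distinct(co$expression$gene_id), 30)
})

test_that("config validation rejects bad fractions, effect sizes and seeds", {
  expect_error(sim_config(dmp_fraction = 1.2, seed = 1),
               class = "methevolve_config_error")
  expect_error(sim_config(dmp_effect_size = 0.1, seed = 1),
               class = "methevolve_config_error")
  expect_error(sim_config(purity_range = c(0.9, 0.3), seed = 1),
               class = "methevolve_config_error")
  expect_error(sim_config(), "seed")
})

test_that("bulk rates converge to the tumor rate in the pure-tumor limit", {
  co <- simulate_cohort(sim_config(
    n_patients = 2, regions_per_patient = 2, n_cpgs = 1500, n_genes = 30,
    purity_range = c(1, 1), coverage_mean = 500,
    patient_effect_sd = 0, region_effect_sd = 0, seed = 5
  ))
  tum <- co$samples$sample_id[co$samples$tissue == "tumor"]
  m <- dplyr::filter(co$methylation, sample_id %in% tum)
  key <- paste(co$truth$cpgs$chrom, co$truth$cpgs$pos)
  idx <- cbind(match(paste(m$chrom, m$pos), key),
               match(m$sample_id, colnames(co$truth$m_t)))
  expect_lt(mean(abs(m$rate - co$truth$m_t[idx])), 0.02)
})

test_that("empirical bulk rates approach the analytic mixture as coverage grows", {
  errs <- purrr::map_dbl(c(30, 100, 500), function(cov) {
    co <- simulate_cohort(sim_config(
      n_patients = 2, regions_per_patient = 2, n_cpgs = 800, n_genes = 20,
      coverage_mean = cov, patient_effect_sd = 0, region_effect_sd = 0,
      seed = 11
    ))
    tr <- co$truth
    tum <- tr$samples[tr$samples$tissue == "tumor", ]
    cn <- methevolve:::cn_at_sites(tr$cpgs, tr$segments, tum$sample_id)
    key <- paste(tr$cpgs$chrom, tr$cpgs$pos)
    m <- dplyr::filter(co$methylation, sample_id %in% tum$sample_id)
    i <- match(paste(m$chrom, m$pos), key)
    j <- match(m$sample_id, tum$sample_id)
    rho <- tum$purity[j]
    mb <- mix_forward(tr$m_t[cbind(i, j)], tr$cpgs$m_n[i], cn[cbind(i, j)],
                      2, rho)
    mean(abs(m$rate - mb))
  })
  expect_true(all(diff(errs) < 0))
})

test_that("clonal events cover all regions and subclonal a strict subset", {
  co <- simulate_cohort(sim_config(
    n_patients = 6, regions_per_patient = 3, n_cpgs = 3000, n_genes = 60,
    dmp_fraction = 0.1, clonal_fraction = 0.5, seed = 9
  ))
  tr <- co$truth
  tum <- tr$samples[tr$samples$tissue == "tumor", ]
  planted <- which(tr$cpgs$dmp_status != "none")
  for (p in unique(tum$patient_id)) {
    cols <- which(tum$patient_id == p)
    pres <- tr$events[planted, cols, drop = FALSE]
    n_reg <- rowSums(pres)
    clonal <- tr$cpgs$clonal[planted]
    # a clonal event, when carried by a patient, is in every region
    expect_true(all(n_reg[clonal & n_reg > 0] == length(cols)))
    expect_true(all(n_reg[!clonal] < length(cols)))
  }
  # subclonal events exist and are non-empty somewhere
  sub <- planted[!tr$cpgs$clonal[planted]]
  expect_gt(length(sub), 0)
  expect_true(any(rowSums(tr$events[sub, , drop = FALSE]) > 0))
})

test_that("amplicon planting encodes compensation and errors beyond the span", {
  cfg <- sim_config(n_patients = 4, regions_per_patient = 2, n_cpgs = 3000,
                    n_genes = 100, dmp_fraction = 0, seed = 15)
  truth <- simulate_truth(cfg)
  g <- truth$genes
  onco <- g$gene_id[10]
  pass <- g$gene_id[12]
  far <- g$gene_id[g$chrom != g$chrom[10]][1]
  expect_error(
    plant_amplicon_with_compensation(truth, onco, far),
    class = "methevolve_range_error"
  )
  planted <- plant_amplicon_with_compensation(truth, onco, pass, n_t_amp = 5)
  amp_samples <- colnames(planted$m_t)[planted$compensated[pass, ]]
  other <- setdiff(colnames(planted$m_t), amp_samples)
  rows <- which(!is.na(planted$cpgs$gene_id) & planted$cpgs$gene_id == pass)
  d_med <- median(planted$m_t[rows, amp_samples]) -
    median(planted$m_t[rows, other])
  expect_gte(d_med, 0.2)
  # oncogene truth expression scales ~ n_t_amp / ploidy in amplified samples
  co <- draw_cohort(planted)
  e <- dplyr::filter(co$expression, gene_id == onco)
  ratio <- mean(e$value[e$sample_id %in% amp_samples]) /
    mean(e$value[e$sample_id %in% other])
  tum <- dplyr::filter(co$samples, tissue == "tumor")
  rho <- mean(tum$purity[tum$sample_id %in% amp_samples])
  expected <- (5 * rho + 2 * (1 - rho)) / 2
  expect_equal(ratio, expected, tolerance = 0.35)
  # no amplified samples: observable tables unchanged
  noop <- plant_amplicon_with_compensation(truth, onco, pass,
                                           amplified_patients = character(0))
  expect_identical(draw_cohort(noop)$methylation, draw_cohort(truth)$methylation)
})

test_that("epiallele reads reproduce compartment and mixture discordance", {
  cfg <- sim_config(n_patients = 3, regions_per_patient = 2, n_cpgs = 800,
                    n_genes = 12, reads_per_locus = 400, seed = 23)
  truth <- simulate_truth(cfg)
  reads <- simulate_reads_for_pdr(truth, genes = truth$genes$gene_id[1:6])
  expect_error(simulate_reads_for_pdr(truth, k = 1),
               class = "methevolve_range_error")

  # tumor-compartment discordance matches the planted PDR_t
  tum_ids <- truth$samples$sample_id[truth$samples$tissue == "tumor"]
  tcomp <- dplyr::filter(reads, compartment == "tumor",
                         sample_id %in% tum_ids)
  pdr_emp <- compute_pdr(tcomp, k = 4)
  merged <- dplyr::inner_join(
    dplyr::summarise(dplyr::group_by(pdr_emp, gene_id),
                     pdr = sum(n_discordant) / sum(n_reads)),
    truth$pdr, by = "gene_id"
  )
  expect_lt(max(abs(merged$pdr - merged$pdr_t)), 0.06)

  # bulk discordance matches the forward purity/CN mixture
  tum <- truth$samples[truth$samples$tissue == "tumor", ]
  cn <- methevolve:::cn_at_sites(
    tibble::tibble(chrom = truth$genes$chrom[1:6], pos = truth$genes$tss[1:6]),
    truth$segments, tum$sample_id
  )
  bulk <- compute_pdr(dplyr::filter(reads, sample_id %in% tum_ids), k = 4)
  bulk$i <- match(bulk$gene_id, truth$genes$gene_id[1:6])
  bulk$j <- match(bulk$sample_id, tum$sample_id)
  expected <- mix_forward(
    truth$pdr$pdr_t[bulk$i], truth$pdr$pdr_n[bulk$i],
    cn[cbind(bulk$i, bulk$j)], 2, tum$purity[bulk$j]
  )
  expect_lt(mean(abs(bulk$pdr - expected)), 0.04)
})
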