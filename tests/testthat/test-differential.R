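test_that("DMP status requires both effect size and significance", {
  # strong counts, tiny effect: ns; strong effect, weak evidence: ns
  d <- manual_deconv_rows(
    meth_b = c(330, 8, 45),
    total_b = c(1000, 20, 50),
    meth_n = c(150, 2, 10),
    total_n = c(1000, 20, 50)
  )
  # deltas: 0.18 (fails size), 0.30 (p too weak), 0.70 (both pass)
  out <- call_dmps(d)
  expect_equal(out$status, c("ns", "ns", "hyper"))
  expect_lt(out$p_value[1], 0.01)   # significant but small effect
  expect_gt(out$p_value[2], 0.01)   # large effect but not significant
})

test_that("the count test matches prop.test and fisher.test oracles", {
  # large counts: z-test branch equals the 1-df chi-squared of prop.test
  p_z <- methevolve:::tumor_normal_count_p(45, 100, 25, 100)
  oracle <- prop.test(c(45, 25), c(100, 100), correct = FALSE)$p.value
  expect_equal(p_z, oracle, tolerance = 1e-9)
  # small expected cells: exact branch equals fisher.test
  p_f <- methevolve:::tumor_normal_count_p(9, 10, 2, 10)
  expect_equal(p_f, fisher.test(matrix(c(9, 1, 2, 8), 2,
                                       byrow = TRUE))$p.value,
               tolerance = 1e-9)
  # vectorized exact path agrees with fisher.test on random tables
  set.seed(4)
  n1 <- sample(8:40, 50, replace = TRUE)
  n2 <- sample(8:40, 50, replace = TRUE)
  x1 <- rbinom(50, n1, runif(50))
  x2 <- rbinom(50, n2, runif(50))
  mine <- methevolve:::fisher_2x2_p(x1, n1, x2, n2)
  ref <- purrr::pmap_dbl(list(x1, n1, x2, n2), function(a, n, b, m) {
    fisher.test(matrix(c(a, n - a, b, m - b), 2, byrow = TRUE))$p.value
  })
  expect_equal(mine, ref, tolerance = 1e-9)
})

test_that("per-sample DMP calls control type I error on a null cohort", {
  co <- simulate_cohort(sim_config(
    n_patients = 4, regions_per_patient = 2, n_cpgs = 6000, n_genes = 100,
    dmp_fraction = 0, patient_effect_sd = 0, region_effect_sd = 0, seed = 51
  ))
  d <- deconvolve_cohort(co$methylation, co$samples, co$segments)
  calls <- call_dmps(d)
  rate <- mean(calls$status != "ns")
  expect_lte(rate, 0.01 + 3 * sqrt(0.01 * 0.99 / nrow(calls)))
})

test_that("the chi-squared/FDR caller is directional with monotone q", {
  d <- manual_deconv_rows(
    meth_b = c(45, 5, 30), total_b = c(50, 50, 60),
    meth_n = c(10, 40, 30), total_n = c(50, 50, 60)
  )
  out <- call_dmps_methsig(d, fdr = 0.15)
  expect_true(out$hyper[1])
  expect_false(out$hyper[2])  # significant but hypomethylated
  expect_false(out$hyper[3])
  expect_true(all(diff(out$q_value[order(out$p_value)]) >= -1e-12))
})

test_that("DMR calling applies the run and total rules", {
  mk <- function(statuses, gap = 50) {
    tibble::tibble(
      chrom = "chr1", pos = seq_along(statuses) * gap,
      sample_id = "S1", status = statuses
    )
  }
  d1 <- call_dmrs(mk(c("hyper", "hyper", "hyper", "hyper", "ns", "hyper")))
  expect_equal(d1$status, "hyper")       # run 4, total 5
  d2 <- call_dmrs(mk(c("hyper", "hyper", "hyper", "ns", "hyper", "hyper")))
  expect_equal(d2$status, "ns")          # total 5 but max run 3
  # chaining: gaps of exactly 100 bp stay in one bin
  d3 <- call_dmrs(tibble::tibble(
    chrom = "chr1", pos = c(100, 150, 200, 260, 320), sample_id = "S1",
    status = "ns"
  ))
  expect_equal(nrow(d3), 1)
  expect_equal(d3$n_cpgs, 5)
})

test_that("DMR calls equal the brute-force oracle on random instances", {
  set.seed(10)
  for (i in 1:40) {
    n <- sample(5:60, 1)
    pos <- sort(sample.int(3000, n))
    status <- sample(c("hyper", "hypo", "ns"), n, replace = TRUE,
                     prob = c(0.4, 0.2, 0.4))
    got <- call_dmrs(tibble::tibble(chrom = "chrX", pos = pos,
                                    sample_id = "S", status = status))
    want <- oracle_dmrs(pos, status)
    expect_equal(nrow(got), nrow(want))
    got <- dplyr::arrange(got, start)
    want <- dplyr::arrange(want, start)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$status %in% c("hyper", "both"), want$hyper)
    expect_equal(got$status %in% c("hypo", "both"), want$hypo)
  }
})

test_that("promoter status comes from DMRs, with missingness preserved", {
  prom <- promoter_windows(tibble::tibble(
    gene_id = c("g1", "g2", "g3"), chrom = "chr1",
    tss = c(10000L, 50000L, 90000L), strand = "+"
  ))
  # g1: qualifying hyper DMR; g2: DMPs but no DMR; g3: no covered CpGs
  meth <- tibble::tibble(
    chrom = "chr1",
    pos = c(seq(9000, 9200, by = 50), seq(48000, 48100, by = 50)),
    sample_id = "S1"
  )
  dmps <- dplyr::mutate(meth,
    status = ifelse(pos < 20000, "hyper", c("hyper", "ns", "hyper")))
  dmrs <- call_dmrs(dmps)
  st <- promoter_methylation_status(dmrs, prom, meth)
  expect_equal(st$status[st$gene_id == "g1"], "hyper")
  expect_equal(st$status[st$gene_id == "g2"], "none")
  expect_false("g3" %in% st$gene_id)  # missing, not "none"
})

test_that("ubiquity distinguishes clonal from subclonal and handles one region", {
  samples <- tibble::tibble(
    sample_id = c("A-R1", "A-R2", "A-R3", "B-R1", "B-R2", "C-R1", "A-N"),
    patient_id = c("A", "A", "A", "B", "B", "C", "A"),
    region_id = c("R1", "R2", "R3", "R1", "R2", "R1", "N"),
    tissue = c(rep("tumor", 6), "normal"),
    purity = c(rep(0.5, 6), NA), ploidy = 2
  )
  events <- tibble::tibble(
    gene_id = "g",
    sample_id = c("A-R1", "A-R2", "A-R3", "B-R1", "B-R2", "C-R1"),
    event = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE)
  )
  ub <- compute_ubiquity(events, samples)
  expect_equal(ub$clonality[ub$patient_id == "A"], "ubiquitous")
  expect_equal(ub$fraction[ub$patient_id == "B"], 0.5)
  expect_equal(ub$clonality[ub$patient_id == "B"], "subclonal")
  expect_true(is.na(ub$clonality[ub$patient_id == "C"]))
  expect_equal(ub$fraction[ub$patient_id == "C"], 1)
})

test_that("DHcR is the hyper fraction of profiled promoter CpGs", {
  prom <- promoter_windows(tibble::tibble(
    gene_id = "g1", chrom = "chr1", tss = 10000L, strand = "+"
  ))
  calls <- tibble::tibble(
    chrom = "chr1", pos = seq(9000, 9000 + 19 * 10, by = 10),
    sample_id = "S1", hyper = rep(c(TRUE, FALSE), c(5, 15))
  )
  dh <- compute_dhcr(calls, prom)
  expect_equal(dh$dhcr, 0.25)
  dh0 <- compute_dhcr(dplyr::mutate(calls, hyper = FALSE), prom)
  expect_equal(dh0$dhcr, 0)
  dh1 <- compute_dhcr(dplyr::mutate(calls, hyper = TRUE), prom)
  expect_equal(dh1$dhcr, 1)
  # invariant to CpG order
  dh_shuf <- compute_dhcr(calls[sample(nrow(calls)), ], prom)
  expect_equal(dh_shuf$dhcr, dh$dhcr)
})

test_that("highest-purity selection is deterministic with lexicographic ties", {
  samples <- tibble::tibble(
    sample_id = c("A-R2", "A-R1", "A-N"),
    patient_id = "A", region_id = c("R2", "R1", "N"),
    tissue = c("tumor", "tumor", "normal"),
    purity = c(0.6, 0.6, NA), ploidy = 2
  )
  expect_equal(highest_purity_samples(samples)$sample_id, "A-R1")
})

test_that("driver ranking recovers genes with excess hypermethylation", {
  set.seed(77)
  n_genes <- 300
  n_samples <- 8
  planted <- paste0("g", 1:15)
  covs <- tibble::tibble(
    gene_id = paste0("g", seq_len(n_genes)),
    pdr = runif(n_genes, 0, 0.4),
    normal_meth = runif(n_genes, 0, 0.3),
    normal_expr = exp(rnorm(n_genes, 4, 1)),
    n_cpgs = sample(10:40, n_genes, replace = TRUE)
  )
  mu <- plogis(-2.2 + 2.5 * covs$pdr + 1.5 * covs$normal_meth)
  phi <- 40
  dhcr <- purrr::map_dfr(seq_len(n_samples), function(s) {
    x <- rbeta(n_genes, mu * phi, (1 - mu) * phi)
    x[covs$gene_id %in% planted] <-
      pmin(1, x[covs$gene_id %in% planted] + 0.3)
    tibble::tibble(gene_id = covs$gene_id, sample_id = paste0("T", s),
                   n_hyper = NA_integer_, n_profiled = covs$n_cpgs, dhcr = x)
  })
  samples <- tibble::tibble(
    sample_id = paste0("T", seq_len(n_samples)),
    patient_id = paste0("P", seq_len(n_samples)),
    region_id = "R1", tissue = "tumor",
    purity = runif(n_samples, 0.5, 0.9), ploidy = 2
  )
  fit <- methsig_rank(dhcr, covs, samples, fdr = 0.1)
  res <- tidy(fit)
  hits <- res$gene_id[res$q < 0.1]
  expect_gte(mean(planted %in% hits), 0.8)
  # covariate-only elevation is explained away, not called
  high_pdr_null <- covs$gene_id[!covs$gene_id %in% planted &
                                  covs$pdr > quantile(covs$pdr, 0.9)]
  expect_lte(mean(high_pdr_null %in% hits), 0.1)
  g <- glance(fit)
  expect_equal(g$n_genes, n_genes)
  expect_equal(g$n_samples, n_samples)
})

test_that("covariate assembly and the median normal reference are consistent", {
  co <- base_cohort()
  ref <- median_normal_reference(co$methylation, co$samples)
  expect_true(all(ref$median_rate >= 0 & ref$median_rate <= 1))
  expect_true(all(abs(ref$meth / ref$total - ref$median_rate) <=
                    0.5 / ref$total + 1e-9))
  covs <- methsig_covariates(NULL, co$methylation, co$samples,
                             co$promoters, co$expression)
  expect_true(all(c("normal_meth", "normal_expr", "n_cpgs") %in% names(covs)))
  expect_true(all(covs$normal_meth >= 0 & covs$normal_meth <= 1))
  expect_gt(nrow(covs), 50)
})
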