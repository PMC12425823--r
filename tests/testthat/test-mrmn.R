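mk_assignments <- function(reg_pos, nonreg_pos, gene = "g1") {
  tibble::tibble(
    gene_id = gene, chrom = "chr1", pos = c(reg_pos, nonreg_pos),
    n_hyper_samples = 1L, n_covered_samples = 6L,
    t_statistic = NA_real_, p_value = 0.5, mean_diff = 0,
    regulatory = rep(c(TRUE, FALSE), c(length(reg_pos), length(nonreg_pos)))
  )
}

mk_events <- function(pos, hyper_per_sample) {
  # hyper_per_sample: named list sample -> logical vector over pos
  purrr::imap_dfr(hyper_per_sample, function(h, s) {
    tibble::tibble(chrom = "chr1", pos = pos, sample_id = s,
                   status = ifelse(h, "hyper", "ns"))
  })
}

test_that("the pseudocounted ratio matches hand evaluation", {
  # one regulatory CpG hyper in 4 of 6 samples, one nonregulatory in 1 of 6:
  # M_R = (4+1)/(6+1), M_N = (1+1)/(6+1), ratio = 5/2
  asg <- mk_assignments(100, 200)
  ev <- mk_events(c(100, 200), list(
    S1 = c(TRUE, TRUE), S2 = c(TRUE, FALSE), S3 = c(TRUE, FALSE),
    S4 = c(TRUE, FALSE), S5 = c(FALSE, FALSE), S6 = c(FALSE, FALSE)
  ))
  rec <- compute_mrmn(asg, ev)
  expect_equal(rec$m_r, 5 / 7)
  expect_equal(rec$m_n_ratio, 2 / 7)
  expect_equal(rec$ratio, 2.5)
})

test_that("balanced and empty event tables give a ratio of one", {
  asg <- mk_assignments(100, 200)
  none <- mk_events(c(100, 200), purrr::map(setNames(1:6, paste0("S", 1:6)),
                                            ~c(FALSE, FALSE)))
  expect_equal(compute_mrmn(asg, none)$ratio, 1)
  half <- mk_events(c(100, 200), list(
    S1 = c(TRUE, TRUE), S2 = c(TRUE, TRUE), S3 = c(TRUE, TRUE),
    S4 = c(FALSE, FALSE), S5 = c(FALSE, FALSE), S6 = c(FALSE, FALSE)
  ))
  expect_equal(compute_mrmn(asg, half)$ratio, 1)
})

test_that("genes lacking one class are non-calculable", {
  asg <- mk_assignments(100, integer(0))
  ev <- mk_events(100, list(S1 = TRUE, S2 = FALSE))
  rec <- compute_mrmn(asg, ev)
  expect_false(rec$calculable)
  expect_true(is.na(rec$ratio))
  out <- test_mrmn_deviation(rec)
  expect_equal(out$class, "non_calculable")
})

test_that("ratio bounds, monotonicity and order invariance hold", {
  set.seed(31)
  for (i in 1:25) {
    nR <- sample(1:30, 1); nN <- sample(1:30, 1)
    hR <- sample(0:nR, 1); hN <- sample(0:nN, 1)
    rec <- tibble::tibble(gene_id = "g", sum_h_r = hR, sum_r = nR,
                          sum_h_n = hN, sum_n = nN, calculable = TRUE) |>
      dplyr::mutate(m_r = (sum_h_r + 1) / (sum_r + 1),
                    m_n_ratio = (sum_h_n + 1) / (sum_n + 1),
                    ratio = m_r / m_n_ratio)
    expect_true(rec$m_r > 0 && rec$m_r <= 1)
    expect_true(rec$m_n_ratio > 0 && rec$m_n_ratio <= 1)
    expect_true(is.finite(rec$ratio) && rec$ratio > 0)
    if (hR < nR) {
      rec2 <- dplyr::mutate(rec, m_r = (sum_h_r + 2) / (sum_r + 1),
                            ratio = m_r / m_n_ratio)
      expect_gt(rec2$ratio, rec$ratio)  # strictly increasing in sum_h_r
    }
  }
  # sample relabeling leaves the ratio unchanged
  asg <- mk_assignments(100, 200)
  ev <- mk_events(c(100, 200), list(
    S1 = c(TRUE, FALSE), S2 = c(FALSE, TRUE), S3 = c(TRUE, TRUE)
  ))
  shuffled <- dplyr::mutate(ev, sample_id = dplyr::recode(
    sample_id, S1 = "S3", S2 = "S1", S3 = "S2"))
  expect_equal(compute_mrmn(asg, ev)$ratio, compute_mrmn(asg, shuffled)$ratio)
})

test_that("the deviation test equals an exact-test oracle and respects nulls", {
  rec <- tibble::tibble(
    gene_id = "g", sum_h_r = 4, sum_r = 6, sum_h_n = 1, sum_n = 6,
    calculable = TRUE, m_r = 5 / 7, m_n_ratio = 2 / 7, ratio = 2.5,
    log2_ratio = log2(2.5), subtype = NA_character_
  )
  out <- test_mrmn_deviation(rec)
  oracle <- fisher.test(matrix(c(4, 2, 1, 5), 2, byrow = TRUE))$p.value
  expect_equal(out$p_value, oracle, tolerance = 1e-12)
  zero <- dplyr::mutate(rec, sum_h_r = 0, sum_h_n = 0, ratio = 1)
  expect_equal(test_mrmn_deviation(zero)$class, "ns")
})

test_that("regulatory assignment is powered at the planted effect size", {
  # drop 50%, lognormal sd 0.3, 10 hyper vs 10 covered samples
  hits <- purrr::map_lgl(1:50, function(s) {
    set.seed(400 + s)
    samples <- paste0("T", 1:20)
    hyper <- samples[1:10]
    dmps <- tibble::tibble(
      chrom = "chr1", pos = 9000, sample_id = samples,
      status = ifelse(samples %in% hyper, "hyper", "ns")
    )
    expr <- tibble::tibble(
      gene_id = "g1", sample_id = samples,
      value = 100 * ifelse(samples %in% hyper, 0.5, 1) * exp(rnorm(20, 0, 0.3))
    )
    prom <- promoter_windows(tibble::tibble(
      gene_id = "g1", chrom = "chr1", tss = 10000L, strand = "+"))
    asg <- assign_cpg_regulatory_status(dmps, expr, prom)
    isTRUE(asg$regulatory)
  })
  expect_gte(mean(hits), 0.95)
})

test_that("identical expression in both groups is nonregulatory", {
  samples <- paste0("T", 1:8)
  dmps <- tibble::tibble(chrom = "chr1", pos = 9000, sample_id = samples,
                         status = rep(c("hyper", "ns"), each = 4))
  expr <- tibble::tibble(gene_id = "g1", sample_id = samples, value = 50)
  prom <- promoter_windows(tibble::tibble(
    gene_id = "g1", chrom = "chr1", tss = 10000L, strand = "+"))
  asg <- assign_cpg_regulatory_status(dmps, expr, prom)
  expect_false(asg$regulatory)
  expect_equal(asg$p_value, 1)
  # too-small groups produce a missing assignment
  dmps1 <- dplyr::mutate(dmps, status = c("hyper", rep("ns", 7)))
  asg1 <- assign_cpg_regulatory_status(dmps1, expr, prom)
  expect_true(is.na(asg1$regulatory))
})

test_that("assignment transfer tabulates direction agreement", {
  disc <- tibble::tibble(
    chrom = "chr1", pos = c(1, 2, 3),
    p_value = c(1e-6, 1e-6, 0.2), mean_diff = c(-1, 1, -1)
  )
  val <- tibble::tibble(chrom = "chr1", pos = c(1, 2, 3),
                        mean_diff = c(-0.5, 0.7, 2))
  rep <- mrmn_transfer_report(disc, val, p_strict = 1e-4)
  expect_equal(sum(rep$confusion), 2)  # third CpG not strictly significant
  expect_equal(rep$confusion["reduced", "reduced"], 1)
  expect_equal(rep$confusion["increased", "increased"], 1)
})
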