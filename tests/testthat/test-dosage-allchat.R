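# shared amplicon cohort for dosage-compensation and chromatin-transition
amplicon_fixture <- function() {
  cached("amplicon", function() {
    cfg <- sim_config(n_patients = 8, regions_per_patient = 3, n_cpgs = 8000,
                      n_genes = 200, dmp_fraction = 0, seed = 131)
    truth <- simulate_truth(cfg)
    g <- truth$genes
    onco <- purrr::map_chr(unique(g$chrom), function(ch) {
      gg <- g[g$chrom == ch, ]
      gg$gene_id[which.min(abs(gg$tss - median(gg$tss)))]
    })
    pass <- purrr::map_chr(seq_along(onco), function(i) {
      gg <- g[g$chrom == unique(g$chrom)[i], ]
      setdiff(gg$gene_id[abs(gg$tss - gg$tss[gg$gene_id == onco[i]]) <= 2e7],
              onco[i])[3]
    })
    for (i in seq_along(onco)) {
      truth <- plant_amplicon_with_compensation(truth, onco[i], pass[i])
    }
    co <- draw_cohort(truth)
    d <- deconvolve_cohort(co$methylation, co$samples, co$segments)
    st <- promoter_methylation_status(call_dmrs(call_dmps(d)), co$promoters, d)
    ev <- classify_gene_events(st, co$segments, co$samples, co$promoters)
    norm_ids <- co$samples$sample_id[co$samples$tissue == "normal"]
    rates <- dplyr::bind_rows(
      dplyr::transmute(d, chrom, pos, sample_id, rate = m_t_hat),
      dplyr::select(dplyr::filter(co$methylation, sample_id %in% norm_ids),
                    chrom, pos, sample_id, rate)
    )
    list(co = co, d = d, ev = ev, onco = onco, pass = pass,
         meth_diff = promoter_meth_diff(rates, co$samples, co$promoters),
         histone = normalize_histone(co$histone, co$samples),
         pm = promoter_mean_meth(d, co$promoters))
  })
}

test_that("planted compensated passengers are flagged, scaling oncogenes are not", {
  f <- amplicon_fixture()
  dc <- dosage_compensation_scan(f$pm, f$co$expression, f$ev)
  planted <- dplyr::filter(dc, gene_id %in% f$pass)
  expect_gte(mean(planted$flagged), 0.8)
  expect_gte(mean(planted$expression_class == "buffered"), 0.6)
  onco <- dplyr::filter(dc, gene_id %in% f$onco)
  expect_true(all(!onco$flagged))
  expect_gte(mean(onco$expression_class == "scaling"), 0.8)
  nulls <- dplyr::filter(dc, !gene_id %in% c(f$pass, f$onco))
  expect_lte(mean(nulls$flagged), 0.05)
})

test_that("identical strata give zero delta and a buffered class", {
  pm <- tibble::tibble(gene_id = "g", sample_id = paste0("S", 1:8),
                       mean_meth = 0.3, n_cpgs = 10L)
  expr <- tibble::tibble(gene_id = "g", sample_id = paste0("S", 1:8),
                         value = 100)
  ev <- tibble::tibble(gene_id = "g", sample_id = paste0("S", 1:8),
                       amplification = rep(c(TRUE, FALSE), each = 4))
  dc <- dosage_compensation_scan(pm, expr, ev)
  expect_equal(dc$delta_median_meth, 0)
  expect_equal(dc$expression_class, "buffered")
  expect_false(dc$flagged)
  # too few regions in a stratum: call missing
  ev2 <- dplyr::mutate(ev, amplification = c(TRUE, TRUE, rep(FALSE, 6)))
  expect_equal(nrow(dosage_compensation_scan(pm, expr, ev2)), 0)
})

test_that("CNA size filtering keeps only large events classified vs ploidy", {
  samples <- tibble::tibble(sample_id = "S1", patient_id = "P", region_id = "R1",
                            tissue = "tumor", purity = 0.5, ploidy = 2)
  segs <- tibble::tibble(
    sample_id = "S1", chrom = c("chr1", "chr2", "chr3"),
    start = 1L, end = c(49900000L, 60000000L, 70000000L),
    n_t = c(4L, 4L, 1L), n_n = 2L
  )
  out <- filter_cnas_for_allchat(segs, samples)
  expect_false("chr1" %in% out$chrom)  # 49.9 Mb: below the 50 Mb floor
  expect_equal(out$cna_class[out$chrom == "chr2"], "gain")
  expect_equal(out$cna_class[out$chrom == "chr3"], "loss")
  empty <- filter_cnas_for_allchat(segs[0, ], samples)
  expect_equal(nrow(empty), 0)
})

test_that("candidate pairs respect the 20 Mb same-chromosome rule", {
  genes <- tibble::tibble(
    gene_id = c("onc", "near", "far", "other_chrom"),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    tss = c(1e6, 1e6 + 1.9e7, 1e6 + 2.5e7, 1e6)
  )
  p <- make_allchat_pairs("onc", genes)
  expect_equal(p$passenger_id, "near")
})

test_that("planted pairs are detected and identical profiles are not", {
  f <- amplicon_fixture()
  genes <- f$co$truth$genes
  pairs <- dplyr::bind_rows(
    tibble::tibble(oncogene_id = f$onco, passenger_id = f$pass),
    # partner with an oncogene-like (co-amplified, non-compensated) profile
    tibble::tibble(
      oncogene_id = f$onco,
      passenger_id = purrr::map_chr(seq_along(f$onco), function(i) {
        gg <- genes[genes$chrom == unique(genes$chrom)[i], ]
        setdiff(gg$gene_id[abs(gg$tss - gg$tss[gg$gene_id == f$onco[i]]) <= 2e7],
                c(f$onco[i], f$pass[i]))[1]
      })
    )
  )
  res <- detect_allchat(pairs, f$meth_diff, f$ev, f$histone)
  res$planted <- res$passenger_id %in% f$pass
  expect_gte(mean(res$verdict[res$planted]), 0.8)
  expect_lte(sum(res$verdict[!res$planted]), 1)
  expect_false(any(res$partial))
})

test_that("histone-free mode still decides on methylation and marks partial", {
  f <- amplicon_fixture()
  pairs <- tibble::tibble(oncogene_id = f$onco[1], passenger_id = f$pass[1])
  res <- detect_allchat(pairs, f$meth_diff, f$ev, histone = NULL)
  expect_true(res$partial)
  expect_true(res$verdict)
  expect_false("p_k4_gained" %in% names(res))
})

test_that("strengthening a planted effect never flips a true verdict", {
  cfg <- sim_config(n_patients = 6, regions_per_patient = 3, n_cpgs = 3000,
                    n_genes = 60, dmp_fraction = 0, seed = 137)
  verdicts <- purrr::map_lgl(c(0.25, 0.3, 0.4), function(eff) {
    truth <- simulate_truth(cfg)
    g <- truth$genes[truth$genes$chrom == "chr1", ]
    onco <- g$gene_id[5]
    pass <- g$gene_id[7]
    truth <- plant_amplicon_with_compensation(truth, onco, pass,
                                              meth_increase = eff)
    co <- draw_cohort(truth)
    d <- deconvolve_cohort(co$methylation, co$samples, co$segments)
    st <- promoter_methylation_status(call_dmrs(call_dmps(d)), co$promoters, d)
    ev <- classify_gene_events(st, co$segments, co$samples, co$promoters)
    norm_ids <- co$samples$sample_id[co$samples$tissue == "normal"]
    rates <- dplyr::bind_rows(
      dplyr::transmute(d, chrom, pos, sample_id, rate = m_t_hat),
      dplyr::select(dplyr::filter(co$methylation, sample_id %in% norm_ids),
                    chrom, pos, sample_id, rate)
    )
    md <- promoter_meth_diff(rates, co$samples, co$promoters)
    hn <- normalize_histone(co$histone, co$samples)
    detect_allchat(tibble::tibble(oncogene_id = onco, passenger_id = pass),
                   md, ev, hn)$verdict
  })
  expect_true(verdicts[1])
  expect_true(all(diff(as.integer(verdicts)) >= 0))
})
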