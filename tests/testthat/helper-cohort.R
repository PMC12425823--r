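# shared fixtures: small simulated cohorts, built once per test run

.cohort_cache <- new.env(parent = emptyenv())

cached <- function(name, maker) {
  if (!exists(name, envir = .cohort_cache)) {
    assign(name, maker(), envir = .cohort_cache)
  }
  get(name, envir = .cohort_cache)
}

base_cohort <- function() {
  cached("base", function() {
    simulate_cohort(sim_config(
      n_patients = 4, regions_per_patient = 3, n_cpgs = 4000, n_genes = 80,
      coverage_mean = 40, seed = 42
    ))
  })
}

base_deconv <- function() {
  cached("base_deconv", function() {
    co <- base_cohort()
    deconvolve_cohort(co$methylation, co$samples, co$segments)
  })
}

# brute-force DMR oracle: literal bin-and-scan over sorted positions
oracle_dmrs <- function(pos, status, gap = 100, min_run = 4, min_total = 5) {
  o <- order(pos)
  pos <- pos[o]
  status <- status[o]
  bin_id <- integer(length(pos))
  cur <- 1L
  bin_id[1] <- 1L
  for (i in seq_along(pos)[-1]) {
    if (pos[i] - pos[i - 1] > gap) cur <- cur + 1L
    bin_id[i] <- cur
  }
  longest_run <- function(x) {
    best <- 0L
    run <- 0L
    for (v in x) {
      run <- if (v) run + 1L else 0L
      best <- max(best, run)
    }
    best
  }
  purrr::map_dfr(split(seq_along(pos), bin_id), function(ix) {
    st <- status[ix]
    tibble::tibble(
      start = min(pos[ix]), end = max(pos[ix]), n_cpgs = length(ix),
      hyper = longest_run(st == "hyper") >= min_run &&
        sum(st == "hyper") >= min_total,
      hypo = longest_run(st == "hypo") >= min_run &&
        sum(st == "hypo") >= min_total
    )
  })
}

# deconvolution rows built directly from counts (purity 1, diploid) so that
# m_t_hat == m_b and the count test is transparent
manual_deconv_rows <- function(meth_b, total_b, meth_n, total_n,
                               sample_id = "S1", patient_id = "P1",
                               n_t = 2, purity = 1) {
  n <- length(meth_b)
  tibble::tibble(
    chrom = "chr1", pos = seq_len(n) * 1000L,
    sample_id = sample_id, patient_id = patient_id,
    meth_b = meth_b, total_b = total_b,
    meth_n = meth_n, total_n = total_n,
    m_b = meth_b / total_b, m_n = meth_n / total_n,
    n_t = n_t, n_n = 2, purity = purity
  ) |>
    dplyr::mutate(
      m_t_hat = deconvolve_methylation(m_b, m_n, n_t, n_n, purity),
      m_t_raw = (m_b * (n_t * purity + n_n * (1 - purity)) -
                   m_n * n_n * (1 - purity)) / (n_t * purity),
      clipped = FALSE, excluded = NA_character_
    )
}
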