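#' Forward purity/copy-number mixture of tumor and normal methylation
#'
#' The bulk methylation rate observed in an impure tumor sample is a
#' copy-number- and purity-weighted mixture of the cancer-cell rate `m_t`
#' and the normal-contaminant rate `m_n`:
#' \deqn{m_b = \frac{m_t n_t \rho + m_n n_n (1-\rho)}{n_t \rho + n_n (1-\rho)}}
#' where `n_t` and `n_n` are the tumor and normal total copy numbers at the
#' locus and `rho` is tumor purity. The same mixture holds for read-level
#' discordance (PDR). This forward form is the algebraic inverse of
#' [deconvolve_methylation()] and serves as its brute-force oracle.
#'
#' @param m_t,m_n Tumor and normal methylation rates in \[0, 1\].
#' @param n_t,n_n Tumor and normal total copy number (normal defaults to 2).
#' @param purity Tumor purity in (0, 1\].
#' @return Bulk methylation rate(s), vectorized over all arguments.
#' @export
mix_forward <- function(m_t, m_n, n_t, n_n = 2, purity = 1) {
  assert_probability(m_t, "m_t")
  assert_probability(m_n, "m_n")
  assert_probability(purity, "purity")
  denom <- n_t * purity + n_n * (1 - purity)
  if (any(denom <= 0)) {
    abort("mixture denominator n_t*purity + n_n*(1-purity) must be positive",
          class = "methevolve_range_error")
  }
  (m_t * n_t * purity + m_n * n_n * (1 - purity)) / denom
}

deconvolve_core <- function(x_b, x_n, n_t, n_n, purity) {
  tumor_mass <- n_t * purity
  if (any(tumor_mass <= 0)) {
    abort(
      "no tumor copies at this locus (n_t * purity = 0); the tumor rate is undefined",
      class = "methevolve_no_tumor_copies"
    )
  }
  (x_b * (n_t * purity + n_n * (1 - purity)) - x_n * n_n * (1 - purity)) /
    tumor_mass
}

#' Deconvolve bulk methylation into the cancer-cell-specific rate
#'
#' Inverts the purity/copy-number mixture of [mix_forward()], modeling the
#' pure tumor methylation rate as the difference between the bulk rate and
#' the normal contaminant weighted by copy number and purity:
#' \deqn{\hat m_t = \frac{m_b (n_t\rho + n_n(1-\rho)) - m_n n_n (1-\rho)}{n_t \rho}}
#' Sampling noise can push the raw estimate outside \[0, 1\]; such values are
#' clipped and flagged rather than dropped, so downstream site counts (for
#' example ubiquity denominators) are preserved.
#'
#' @param m_b Bulk tumor methylation rate(s).
#' @param m_n Matched-normal methylation rate(s).
#' @inheritParams mix_forward
#' @param details If `TRUE`, return a tibble with the raw estimate and a
#'   `clipped` flag; otherwise a numeric vector of clipped estimates.
#' @return Numeric vector, or tibble with columns `m_t_hat`, `raw`, `clipped`.
#' @export
deconvolve_methylation <- function(m_b, m_n, n_t, n_n = 2, purity = 1,
                                   details = FALSE) {
  assert_probability(m_b, "m_b")
  assert_probability(m_n, "m_n")
  assert_probability(purity, "purity")
  raw <- deconvolve_core(m_b, m_n, n_t, n_n, purity)
  eps <- 1e-9
  clipped <- raw < -eps | raw > 1 + eps
  est <- clamp01(raw)
  if (!details) return(est)
  tibble(m_t_hat = est, raw = raw, clipped = clipped)
}

#' Deconvolve bulk PDR into the cancer-cell-specific PDR
#'
#' Applies the identical purity/copy-number inversion to the proportion of
#' discordant reads:
#' \deqn{\mathrm{PDR}_t = \frac{\mathrm{PDR}_b(n_t\rho + n_n(1-\rho)) -
#'   \mathrm{PDR}_n n_n(1-\rho)}{n_t\rho}}
#'
#' @param pdr_b Bulk PDR value(s).
#' @param pdr_n Matched-normal PDR value(s).
#' @inheritParams deconvolve_methylation
#' @return Numeric vector, or tibble with `pdr_t_hat`, `raw`, `clipped`.
#' @export
deconvolve_pdr <- function(pdr_b, pdr_n, n_t, n_n = 2, purity = 1,
                           details = FALSE) {
  assert_probability(pdr_b, "pdr_b", allow_na = TRUE)
  assert_probability(pdr_n, "pdr_n", allow_na = TRUE)
  assert_probability(purity, "purity")
  raw <- deconvolve_core(pdr_b, pdr_n, n_t, n_n, purity)
  eps <- 1e-9
  clipped <- !is.na(raw) & (raw < -eps | raw > 1 + eps)
  est <- clamp01(raw)
  if (!details) return(est)
  tibble(pdr_t_hat = est, raw = raw, clipped = clipped)
}

# per-site copy number lookup: the segment covering each position
lookup_segment_cn <- function(sites, segments) {
  assert_columns(sites, c("chrom", "pos", "sample_id"))
  segments <- validate_segments(segments)
  left_join(
    sites,
    select(segments, dplyr::all_of(c("sample_id", "chrom", "start", "end", "n_t", "n_n"))),
    by = join_by(sample_id, chrom, between(pos, start, end))
  ) |>
    select(-dplyr::any_of(c("start", "end")))
}

#' Deconvolve a cohort methylation table against matched normals
#'
#' Joins each tumor CpG observation with its patient's matched-normal
#' observation, its covering copy-number segment and its sample purity, then
#' applies [deconvolve_methylation()] site by site. CpGs falling in segment
#' gaps are kept with `m_t_hat = NA` and `excluded = "no_segment"`; CpGs
#' missing from the matched normal are dropped and counted in the
#' `"skip_report"` attribute.
#'
#' @param meth Long methylation tibble (`chrom`, `pos`, `sample_id`, `meth`,
#'   `total`), containing tumor and normal samples.
#' @param samples Sample sheet (see [validate_samples()]).
#' @param segments Copy-number segments for the tumor samples.
#' @param min_total Minimum coverage required in both tumor and normal
#'   (default 10).
#' @return Tibble with one row per (CpG, tumor sample): bulk inputs
#'   (`meth_b`, `total_b`, `m_b`), normal inputs (`meth_n`, `total_n`, `m_n`),
#'   the context used (`n_t`, `n_n`, `purity`, `patient_id`) and the estimate
#'   (`m_t_hat`, `clipped`, `excluded`).
#' @export
deconvolve_cohort <- function(meth, samples, segments, min_total = 10) {
  assert_columns(meth, c("chrom", "pos", "sample_id", "meth", "total"))
  samples <- validate_samples(samples)

  tum_samples <- filter(samples, .data$tissue == "tumor")
  norm_samples <- filter(samples, .data$tissue == "normal")
  normals <- meth |>
    semi_join(norm_samples, by = "sample_id") |>
    left_join(select(norm_samples, dplyr::all_of(c("sample_id", "patient_id"))),
              by = "sample_id") |>
    select(dplyr::all_of(c("chrom", "pos", "patient_id")),
           meth_n = "meth", total_n = "total")

  tum <- meth |>
    semi_join(tum_samples, by = "sample_id") |>
    left_join(select(tum_samples,
                     dplyr::all_of(c("sample_id", "patient_id", "purity"))),
              by = "sample_id") |>
    rename(meth_b = "meth", total_b = "total")

  joined <- inner_join(tum, normals, by = c("chrom", "pos", "patient_id"))
  n_no_normal <- nrow(tum) - nrow(joined)
  joined <- filter(joined, .data$total_b >= min_total, .data$total_n >= min_total)
  n_low_cov <- nrow(tum) - n_no_normal - nrow(joined)

  joined <- lookup_segment_cn(joined, segments)
  no_seg <- is.na(joined$n_t)
  joined <- joined |>
    mutate(
      m_b = .data$meth_b / .data$total_b,
      m_n = .data$meth_n / .data$total_n
    )

  est <- rep(NA_real_, nrow(joined))
  raw <- rep(NA_real_, nrow(joined))
  clip <- rep(NA, nrow(joined))
  ok <- !no_seg & joined$n_t * joined$purity > 0
  d <- deconvolve_methylation(
    joined$m_b[ok], joined$m_n[ok], joined$n_t[ok], joined$n_n[ok],
    joined$purity[ok], details = TRUE
  )
  est[ok] <- d$m_t_hat
  raw[ok] <- d$raw
  clip[ok] <- d$clipped

  out <- joined |>
    mutate(
      m_t_hat = est,
      m_t_raw = raw,
      clipped = clip,
      excluded = dplyr::case_when(
        no_seg ~ "no_segment",
        !ok ~ "no_tumor_copies",
        TRUE ~ NA_character_
      )
    )
  attr(out, "skip_report") <- tibble(
    reason = c("missing_in_normal", "low_coverage"),
    n = c(n_no_normal, n_low_cov)
  )
  out
}

#' Compute the proportion of discordant reads (PDR) per locus
#'
#' A read is eligible if it reports at least `k` CpG states; it is discordant
#' if it carries both methylated and unmethylated CpGs. The PDR of a locus is
#' the fraction of eligible reads that are discordant. Loci with zero
#' eligible reads are reported as missing (`NA`), never as 0.
#'
#' @param epialleles Tibble with one row per read: `sample_id`, a locus
#'   column (default `gene_id`), and `states`, a string of `M`/`U` calls.
#' @param k Minimum CpG states per eligible read (default 4; must be >= 2).
#' @param locus Name of the locus column.
#' @return Tibble with `sample_id`, locus, `n_reads` (eligible),
#'   `n_discordant`, `pdr`.
#' @export
compute_pdr <- function(epialleles, k = 4, locus = "gene_id") {
  if (k < 2) {
    abort("reads with fewer than 2 CpGs cannot be discordant; k must be >= 2",
          class = "methevolve_range_error")
  }
  assert_columns(epialleles, c("sample_id", locus, "states"))
  n_cpg <- nchar(epialleles$states)
  n_m <- nchar(gsub("[^M]", "", epialleles$states))
  df <- epialleles |>
    mutate(
      eligible = n_cpg >= k,
      discordant = n_m > 0 & n_m < n_cpg
    ) |>
    filter(.data$eligible)
  out <- df |>
    group_by(.data$sample_id, .data[[locus]]) |>
    summarise(
      n_reads = n(),
      n_discordant = sum(.data$discordant),
      .groups = "drop"
    ) |>
    mutate(pdr = if_else(.data$n_reads > 0,
                         .data$n_discordant / .data$n_reads, NA_real_))
  out
}

#' Deconvolve per-locus PDR for a cohort
#'
#' Pairs each tumor locus PDR with the patient's matched-normal PDR and the
#' copy number at the locus TSS, then applies [deconvolve_pdr()].
#'
#' @param pdr Output of [compute_pdr()] covering tumor and normal samples.
#' @param samples Sample sheet.
#' @param segments Copy-number segments.
#' @param promoters Promoter tibble giving each locus a `chrom` and `tss`
#'   for copy-number lookup.
#' @param min_reads Minimum eligible reads per locus (default 10).
#' @return Tibble with `gene_id`, `sample_id`, `pdr_b`, `pdr_n`, `n_t`,
#'   `n_n`, `purity`, `pdr_t_hat`, `clipped`.
#' @export
deconvolve_pdr_cohort <- function(pdr, samples, segments, promoters,
                                  min_reads = 10) {
  samples <- validate_samples(samples)
  assert_columns(pdr, c("sample_id", "gene_id", "pdr", "n_reads"))
  pdr <- filter(pdr, .data$n_reads >= min_reads)
  norm <- samples |> filter(.data$tissue == "normal")
  pdr_n <- pdr |>
    semi_join(norm, by = "sample_id") |>
    left_join(select(norm, dplyr::all_of(c("sample_id", "patient_id"))), by = "sample_id") |>
    select(dplyr::all_of(c("gene_id", "patient_id")), pdr_n = "pdr")
  tum <- samples |> filter(.data$tissue == "tumor")
  out <- pdr |>
    semi_join(tum, by = "sample_id") |>
    left_join(select(tum, dplyr::all_of(c("sample_id", "patient_id", "purity"))),
              by = "sample_id") |>
    rename(pdr_b = "pdr") |>
    inner_join(pdr_n, by = c("gene_id", "patient_id")) |>
    left_join(select(promoters, dplyr::all_of(c("gene_id", "chrom", "tss"))),
              by = "gene_id") |>
    rename(pos = "tss") |>
    lookup_segment_cn(segments)
  ok <- !is.na(out$n_t) & out$n_t * out$purity > 0
  d <- deconvolve_pdr(out$pdr_b[ok], out$pdr_n[ok], out$n_t[ok], out$n_n[ok],
                      out$purity[ok], details = TRUE)
  out$pdr_t_hat <- NA_real_
  out$clipped <- NA
  out$pdr_t_hat[ok] <- d$pdr_t_hat
  out$clipped[ok] <- d$clipped
  select(out, -dplyr::any_of(c("eligible", "discordant")))
}
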