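#' Call tumor-normal differentially methylated positions (DMPs) per sample
#'
#' A CpG is a significant DMP in a tumor sample when the difference between
#' its deconvolved cancer-cell methylation rate and the matched-normal rate
#' exceeds 0.2 in absolute value at P < 0.01 (`hyper` when
#' `m_t_hat - m_n > 0.2`, `hypo` when `< -0.2`, otherwise `ns`).
#'
#' The p-value tests the null `m_t = m_n`. Because
#' `m_t_hat - m_n = (m_b - m_n) * (n_t*rho + n_n*(1-rho)) / (n_t*rho)`
#' is an exact rescaling of the bulk-normal difference, that null is
#' identical to `m_b = m_n` and is tested directly on the raw bulk and
#' normal read counts with a two-proportion z-test (no continuity
#' correction), switching to Fisher's exact test whenever any expected cell
#' of the 2x2 count table falls below 5. This keeps the test calibrated
#' without approximating deconvolution-inflated "effective" counts.
#'
#' @param deconv Output of [deconvolve_cohort()].
#' @param alpha Significance threshold (default 0.01).
#' @param delta Effect-size threshold on `m_t_hat - m_n` (default 0.2).
#' @param exact_threshold Expected-cell floor below which the exact test is
#'   used (default 5).
#' @return Tibble with `chrom`, `pos`, `sample_id`, `patient_id`, `m_t_hat`,
#'   `m_n`, `delta`, `p_value`, `status`. Sites excluded upstream (segment
#'   gaps, no tumor copies) are dropped and counted in the `"skip_report"`
#'   attribute.
#' @export
call_dmps <- function(deconv, alpha = 0.01, delta = 0.2, exact_threshold = 5) {
  assert_columns(deconv, c("chrom", "pos", "sample_id", "patient_id",
                           "meth_b", "total_b", "meth_n", "total_n",
                           "m_t_hat", "m_n"))
  excluded <- !is.na(deconv$excluded %||% rep(NA_character_, nrow(deconv)))
  skip <- tibble(reason = "excluded_from_deconvolution", n = sum(excluded))
  df <- deconv[!excluded, , drop = FALSE]
  p <- tumor_normal_count_p(df$meth_b, df$total_b, df$meth_n, df$total_n,
                            exact_threshold)
  d <- df$m_t_hat - df$m_n
  delta_thr <- delta
  out <- df |>
    select(dplyr::all_of(c("chrom", "pos", "sample_id", "patient_id",
                           "m_t_hat", "m_n"))) |>
    mutate(
      delta = d,
      p_value = p,
      status = dplyr::case_when(
        .data$delta > delta_thr & .data$p_value < alpha ~ "hyper",
        .data$delta < -delta_thr & .data$p_value < alpha ~ "hypo",
        TRUE ~ "ns"
      )
    )
  attr(out, "skip_report") <- skip
  out
}

#' Call cohort-level DMPs by pooling read counts across samples
#'
#' Aggregates evidence for a differential locus across the whole cohort:
#' tumor bulk counts are pooled over all tumor samples, normal counts over
#' each patient's matched normal (counted once per patient), and the same
#' two-proportion/exact test is applied to the pooled 2x2 table. The
#' cohort-level effect size is the coverage-weighted mean of the per-sample
#' deconvolved differences, and the same 0.2 / 0.01 thresholds decide
#' status. Individual tumor samples at 30x coverage and moderate purity
#' carry little power for a single CpG; pooling recovers loci that are
#' differential across the cohort.
#'
#' @inheritParams call_dmps
#' @return Tibble with one row per CpG: pooled counts, `delta` (weighted
#'   mean deconvolved difference), `p_value`, `status`, `n_samples`.
#' @export
call_dmps_cohort <- function(deconv, alpha = 0.01, delta = 0.2,
                             exact_threshold = 5) {
  assert_columns(deconv, c("chrom", "pos", "sample_id", "patient_id",
                           "meth_b", "total_b", "meth_n", "total_n",
                           "m_t_hat", "m_n"))
  df <- deconv
  if ("excluded" %in% names(df)) df <- filter(df, is.na(.data$excluded))
  # the cohort effect size averages the *raw* (unclipped) per-sample
  # estimates when available: clipping is unbiased only site-by-site in
  # expectation near mid-range rates, and averaging raw estimates removes
  # the truncation bias at near-0/near-1 baselines before one final clip
  if (!"m_t_raw" %in% names(df)) df$m_t_raw <- df$m_t_hat
  tum_pool <- df |>
    group_by(.data$chrom, .data$pos) |>
    summarise(
      # delta first: the count aggregates below mask the per-sample columns
      delta = clamp01(sum(.data$m_t_raw * .data$total_b) /
                        sum(.data$total_b)) -
        sum(.data$m_n * .data$total_b) / sum(.data$total_b),
      n_samples = n(),
      meth_b = sum(.data$meth_b), total_b = sum(.data$total_b),
      .groups = "drop"
    )
  norm_pool <- df |>
    distinct(.data$chrom, .data$pos, .data$patient_id,
             .data$meth_n, .data$total_n) |>
    group_by(.data$chrom, .data$pos) |>
    summarise(meth_n = sum(.data$meth_n), total_n = sum(.data$total_n),
              .groups = "drop")
  pooled <- inner_join(tum_pool, norm_pool, by = c("chrom", "pos"))
  p <- tumor_normal_count_p(pooled$meth_b, pooled$total_b,
                            pooled$meth_n, pooled$total_n, exact_threshold)
  delta_thr <- delta
  pooled |>
    mutate(
      p_value = p,
      status = dplyr::case_when(
        .data$delta > delta_thr & .data$p_value < alpha ~ "hyper",
        .data$delta < -delta_thr & .data$p_value < alpha ~ "hypo",
        TRUE ~ "ns"
      )
    )
}

#' Call per-sample hypermethylated DMPs with a chi-squared test at 15% FDR
#'
#' The DMP definition used by the driver-ranking stage differs from the
#' 0.2 / 0.01 rule: methylated and unmethylated read counts in tumor versus
#' normal are compared with a chi-squared test and calls are taken at a 15%
#' false discovery rate (Benjamini-Hochberg, within each sample), requiring
#' the deconvolved tumor rate to exceed the normal rate. Both callers are
#' kept as separately named functions so every consumer states which
#' definition it uses.
#'
#' @inheritParams call_dmps
#' @param fdr FDR threshold within each sample (default 0.15).
#' @return Tibble with `chrom`, `pos`, `sample_id`, `patient_id`, `m_t_hat`,
#'   `m_n`, `p_value`, `q_value` and logical `hyper`.
#' @export
call_dmps_methsig <- function(deconv, fdr = 0.15, exact_threshold = 5) {
  assert_columns(deconv, c("chrom", "pos", "sample_id", "patient_id",
                           "meth_b", "total_b", "meth_n", "total_n",
                           "m_t_hat", "m_n"))
  df <- deconv
  if ("excluded" %in% names(df)) df <- filter(df, is.na(.data$excluded))
  p <- tumor_normal_count_p(df$meth_b, df$total_b, df$meth_n, df$total_n,
                            exact_threshold)
  df |>
    select(dplyr::all_of(c("chrom", "pos", "sample_id", "patient_id",
                           "m_t_hat", "m_n"))) |>
    mutate(p_value = p) |>
    group_by(.data$sample_id) |>
    mutate(q_value = p.adjust(.data$p_value, "BH")) |>
    ungroup() |>
    mutate(hyper = .data$q_value <= fdr & .data$m_t_hat > .data$m_n)
}
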